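#' Driving-performance indicators for one participant-window
#'
#' Computes the seven driving-performance indicators over a set of annotated
#' trips (kinematics, events and speeding flags populated; see
#' [build_trips()]):
#' \describe{
#'   \item{nHardBrake, nSuddenAcc}{events per statute mile: total event count
#'     divided by total trip distance in miles (aggregate-mile
#'     normalisation)}
#'   \item{OverV, UnderV}{fraction of trips with defined speed-compliance
#'     flags that contain at least one over-/under-speed episode}
#'   \item{avgV}{mean over trips of each trip's mean sampled speed, m/s}
#'   \item{avgA}{mean over trips of each trip's mean absolute acceleration,
#'     m/s^2 (signed means would vanish over any closed trip)}
#'   \item{avgJ}{mean over trips of each trip's mean absolute jerk, m/s^3}
#' }
#'
#' @param trips A trip table for one participant-window with columns
#'   `distance_km`, `n_hard_brakes`, `n_sudden_accels`, `has_overspeed`,
#'   `has_underspeed`, `mean_speed`, `mean_abs_accel`, `mean_abs_jerk`.
#' @return A one-row `data.table` with columns `nHardBrake`, `nSuddenAcc`,
#'   `OverV`, `UnderV`, `avgV`, `avgA`, `avgJ` (rates/fractions `NA` when
#'   their denominator is empty) and `empty`.
#' @export
compute_performance_indicators <- function(trips) {
  if (nrow(trips) == 0L) {
    out <- data.table::as.data.table(
      as.list(setNames(rep(NA_real_, 7), performance_indicator_names())))
    out$empty <- TRUE
    return(out)
  }
  total_miles <- sum(trips$distance_km) / KM_PER_MILE
  n_defined <- sum(!is.na(trips$has_overspeed))
  data.table::data.table(
    nHardBrake = if (total_miles > 0) sum(trips$n_hard_brakes) / total_miles else NA_real_,
    nSuddenAcc = if (total_miles > 0) sum(trips$n_sudden_accels) / total_miles else NA_real_,
    OverV = if (n_defined > 0) mean(trips$has_overspeed, na.rm = TRUE) else NA_real_,
    UnderV = if (n_defined > 0) mean(trips$has_underspeed, na.rm = TRUE) else NA_real_,
    avgV = mean(trips$mean_speed, na.rm = TRUE),
    avgA = mean(trips$mean_abs_accel, na.rm = TRUE),
    avgJ = mean(trips$mean_abs_jerk, na.rm = TRUE),
    empty = FALSE
  )
}

performance_indicator_names <- function() {
  c("nHardBrake", "nSuddenAcc", "OverV", "UnderV", "avgV", "avgA", "avgJ")
}

#' Names of the 14 driving indicators
#'
#' The seven driving-space and seven driving-performance indicator names, in
#' canonical order (excluding the five trip-distance subgroup counts).
#'
#' @return Character vector of length 14.
#' @export
indicator_names <- function() {
  c("TripDist", "TotalDist", "nTrips", "Rg", "S", "nNightTrip", "nUniqDest",
    performance_indicator_names())
}
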