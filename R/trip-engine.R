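#' Segment a GPS log into trips
#'
#' Consecutive points of one participant whose inter-sample gap is at most
#' `gap_s` seconds belong to the same trip (a gap above the threshold is read
#' as an ignition-off interval at 30-s sampling). Trips with fewer than
#' `min_points` points or shorter than `min_km` are discarded (count reported
#' via `message`). Trip distance is the sum of great-circle distances over
#' consecutive points.
#'
#' @param log A `drv_log` table ([read_gps_log()]) or any data.table with the
#'   same columns, sorted by participant and timestamp.
#' @param gap_s Maximum within-trip gap between samples, seconds.
#' @param min_points Minimum points for a trip to be kept.
#' @param min_km Minimum trip distance, km.
#' @return An object of class `drv_trips`: a list with
#'   \describe{
#'     \item{points}{point table of retained trips, with `trip_id`}
#'     \item{trips}{one row per trip: `participant_id`, `trip_id`, `start`,
#'       `end`, `n_points`, `distance_km`, start/end coordinates}
#'     \item{n_discarded}{number of candidate trips dropped by the filters}
#'   }
#' @export
segment_trips <- function(log, gap_s = 300, min_points = 4, min_km = 0.1) {
  pts <- data.table::as.data.table(log)
  if (nrow(pts) == 0L)
    return(structure(list(points = pts, trips = empty_trip_table(),
                          n_discarded = 0L),
                     class = "drv_trips"))
  data.table::setorder(pts, participant_id, timestamp)
  new_participant <- c(TRUE, pts$participant_id[-1] != pts$participant_id[-nrow(pts)])
  dt_gap <- c(Inf, as.numeric(diff(pts$timestamp), units = "secs"))
  if (any(dt_gap <= 0 & !new_participant))
    stop("timestamps must be strictly increasing within a participant")
  pts[, trip_id := cumsum(new_participant | dt_gap > gap_s)]

  # consecutive-pair distances within trips
  n <- nrow(pts)
  same <- c(pts$trip_id[-1] == pts$trip_id[-n], FALSE)
  step <- rep(0, n)
  if (any(same))
    step[same] <- haversine_km(pts$lat[same], pts$lon[same],
                               pts$lat[which(same) + 1], pts$lon[which(same) + 1])
  pts[, step_km := step]

  trips <- pts[, .(
    participant_id = participant_id[1L],
    start = timestamp[1L], end = timestamp[.N],
    n_points = .N, distance_km = sum(step_km),
    start_lat = lat[1L], start_lon = lon[1L],
    end_lat = lat[.N], end_lon = lon[.N]
  ), by = trip_id]

  keep <- trips$n_points >= min_points & trips$distance_km >= min_km
  n_discarded <- sum(!keep)
  if (n_discarded > 0)
    message(n_discarded, " candidate trip(s) discarded (min_points/min_km filter)")
  trips <- trips[keep]
  pts <- pts[trip_id %in% trips$trip_id]
  structure(list(points = pts[], trips = trips[], n_discarded = n_discarded),
            class = "drv_trips")
}

empty_trip_table <- function() {
  data.table::data.table(
    trip_id = integer(), participant_id = character(),
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    n_points = integer(), distance_km = numeric(),
    start_lat = numeric(), start_lon = numeric(),
    end_lat = numeric(), end_lon = numeric()
  )
}

#' @export
print.drv_trips <- function(x, ...) {
  cat("<drv_trips> ", nrow(x$trips), " trips, ",
      length(unique(x$trips$participant_id)), " participant(s), ",
      nrow(x$points), " points\n", sep = "")
  invisible(x)
}

#' Finite-difference kinematics for segmented trips
#'
#' Populates per-trip acceleration and jerk series by finite differences at
#' the native sampling: acceleration over consecutive sample pairs,
#' `a_i = (v_{i+1} - v_i) / (t_{i+1} - t_i)` (m/s^2), and jerk over
#' consecutive acceleration pairs divided by the midpoint time step,
#' `j_k = (a_{k+1} - a_k) / ((t_{k+2} - t_k)/2)` (m/s^3). Adds per-trip
#' summaries `mean_speed`, `mean_abs_accel`, `mean_abs_jerk` to the trip
#' table.
#'
#' @param x A `drv_trips` object.
#' @return `x` with `pairs` (per-pair accelerations) and `jerks` tables and
#'   summary columns added.
#' @export
kinematics <- function(x) {
  stopifnot(inherits(x, "drv_trips"))
  pts <- x$points
  n <- nrow(pts)
  if (n == 0L) {
    x$pairs <- data.table::data.table(trip_id = integer(), dt = numeric(),
                                      accel = numeric())
    x$jerks <- data.table::data.table(trip_id = integer(), jerk = numeric())
    return(x)
  }
  same <- c(pts$trip_id[-1] == pts$trip_id[-n], FALSE)
  i <- which(same)
  tnum <- as.numeric(pts$timestamp)
  pairs <- data.table::data.table(
    trip_id = pts$trip_id[i],
    t0 = tnum[i], t1 = tnum[i + 1],
    dt = tnum[i + 1] - tnum[i],
    accel = (pts$speed[i + 1] - pts$speed[i]) / (tnum[i + 1] - tnum[i])
  )
  m <- nrow(pairs)
  same_a <- if (m > 1) pairs$trip_id[-1] == pairs$trip_id[-m] else logical(0)
  j <- which(same_a)
  jerks <- data.table::data.table(
    trip_id = pairs$trip_id[j],
    jerk = (pairs$accel[j + 1] - pairs$accel[j]) / ((pairs$t1[j + 1] - pairs$t0[j]) / 2)
  )
  x$pairs <- pairs
  x$jerks <- jerks
  sp <- pts[, .(mean_speed = mean(speed)), by = trip_id]
  ac <- pairs[, .(mean_abs_accel = mean(abs(accel))), by = trip_id]
  jk <- jerks[, .(mean_abs_jerk = mean(abs(jerk))), by = trip_id]
  tr <- x$trips
  for (col in intersect(c("mean_speed", "mean_abs_accel", "mean_abs_jerk"),
                        names(tr))) tr[[col]] <- NULL
  tr <- jk[ac[sp[tr, on = "trip_id"], on = "trip_id"], on = "trip_id"]
  data.table::setcolorder(tr, c("trip_id", "participant_id"))
  x$trips <- tr[]
  x
}

#' Count hard-brake and sudden-acceleration events per trip
#'
#' When the logging device reports kinematic events natively (any non-missing
#' `event_flag` in a participant's points), counts are taken from the flags
#' (device-authoritative mode): at 30-s sampling, finite differences cannot
#' literally observe an "8 mph in 1 s" event. Otherwise a kinematic fallback
#' counts each sample-pair acceleration at or below `-brake_thresh` as one
#' hard brake and at or above `accel_thresh` as one sudden acceleration.
#'
#' @param x A `drv_trips` object with kinematics populated (see [kinematics()]).
#' @param brake_thresh,accel_thresh Magnitude thresholds in m/s^2; the
#'   defaults are 8 mph per second.
#' @param source `"auto"` (flags when present for the participant),
#'   `"flags"`, or `"kinematic"`.
#' @return `x` with `n_hard_brakes` and `n_sudden_accels` trip columns.
#' @export
detect_events <- function(x, brake_thresh = 8 * MPH_TO_MPS,
                          accel_thresh = 8 * MPH_TO_MPS,
                          source = c("auto", "flags", "kinematic")) {
  stopifnot(inherits(x, "drv_trips"))
  source <- match.arg(source)
  pts <- x$points
  if (source == "auto") {
    has_flags <- pts[, .(flagged = any(!is.na(event_flag))), by = participant_id]
  } else {
    has_flags <- data.table::data.table(
      participant_id = unique(pts$participant_id),
      flagged = source == "flags")
  }
  flag_counts <- pts[, .(
    fb = sum(!is.na(event_flag) & event_flag == "hard_brake"),
    fa = sum(!is.na(event_flag) & event_flag == "sudden_accel")
  ), by = .(participant_id, trip_id)]
  if (is.null(x$pairs)) x <- kinematics(x)
  kin_counts <- x$pairs[, .(
    kb = sum(accel <= -brake_thresh),
    ka = sum(accel >= accel_thresh)
  ), by = trip_id]
  tr <- x$trips
  for (col in intersect(c("n_hard_brakes", "n_sudden_accels"), names(tr)))
    tr[[col]] <- NULL
  tr <- kin_counts[flag_counts[, !"participant_id"][tr, on = "trip_id"], on = "trip_id"]
  tr <- has_flags[tr, on = "participant_id"]
  tr[, n_hard_brakes := data.table::fifelse(flagged, as.integer(fb),
                                            as.integer(data.table::nafill(kb, fill = 0L)))]
  tr[, n_sudden_accels := data.table::fifelse(flagged, as.integer(fa),
                                              as.integer(data.table::nafill(ka, fill = 0L)))]
  tr[, c("fb", "fa", "kb", "ka", "flagged") := NULL]
  data.table::setcolorder(tr, c("trip_id", "participant_id"))
  x$trips <- tr[]
  x
}

#' Flag over- and under-speed trips against posted limits
#'
#' A trip has defined speed-compliance flags only when a posted limit is
#' present on at least half of its points; otherwise both flags are `NA` and
#' the trip is excluded from over/under-speed denominators. A trip is
#' overspeed if any point exceeds its limit by more than `margin` (default
#' 6 mph) and underspeed if any moving point (speed above `floor_mps`,
#' excluding stationary/queue samples) is below its limit by more than
#' `margin`.
#'
#' @param x A `drv_trips` object.
#' @param margin Margin in m/s (default 6 mph = 2.68224 m/s).
#' @param floor_mps Speed floor below which points are treated as stationary.
#' @return `x` with logical trip columns `has_overspeed`, `has_underspeed`.
#' @export
flag_speeding <- function(x, margin = 6 * MPH_TO_MPS, floor_mps = 0.5) {
  stopifnot(inherits(x, "drv_trips"))
  fl <- x$points[, .(
    coverage = mean(!is.na(posted_limit)),
    over = any(speed > posted_limit + margin, na.rm = TRUE),
    under = any(speed > floor_mps & speed < posted_limit - margin, na.rm = TRUE)
  ), by = trip_id]
  fl[coverage < 0.5, c("over", "under") := NA]
  tr <- x$trips
  for (col in intersect(c("has_overspeed", "has_underspeed"), names(tr)))
    tr[[col]] <- NULL
  tr <- fl[, .(trip_id, has_overspeed = over, has_underspeed = under)][tr, on = "trip_id"]
  data.table::setcolorder(tr, c("trip_id", "participant_id"))
  x$trips <- tr[]
  x
}

#' Run the full trip feature chain
#'
#' Convenience wrapper: [segment_trips()] then [kinematics()],
#' [detect_events()] and [flag_speeding()] with the supplied configuration.
#'
#' @param log A `drv_log` table.
#' @param config Named list overriding defaults: `gap_s`, `min_points`,
#'   `min_km`, `brake_mps2`, `accel_mps2`, `margin_mps`, `event_source`.
#' @return A fully annotated `drv_trips` object.
#' @export
build_trips <- function(log, config = list()) {
  x <- segment_trips(log,
                     gap_s = config$gap_s %||% 300,
                     min_points = config$min_points %||% 4,
                     min_km = config$min_km %||% 0.1)
  x <- kinematics(x)
  x <- detect_events(x,
                     brake_thresh = config$brake_mps2 %||% (8 * MPH_TO_MPS),
                     accel_thresh = config$accel_mps2 %||% (8 * MPH_TO_MPS),
                     source = config$event_source %||% "auto")
  flag_speeding(x, margin = config$margin_mps %||% (6 * MPH_TO_MPS))
}
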