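#' Cluster trip destinations
#'
#' Greedy chronological clustering of trip end-points: each endpoint, in
#' order of trip end time, joins the first existing destination whose running
#' centroid lies within `radius_m`; otherwise it founds a new destination.
#' Centroids are running visit-weighted means. Deterministic and order-stable.
#'
#' @param trips A trip table (the `trips` element of a `drv_trips` object, or
#'   any subset of it) with `end`, `end_lat`, `end_lon`.
#' @param radius_m Merge radius in metres.
#' @return An object of class `dest_set`: list with `destinations`
#'   (`lat`, `lon`, `n` visits), `visits` (per trip: destination index and
#'   arrival time), and `N` total visits.
#' @export
cluster_destinations <- function(trips, radius_m = 150) {
  if (nrow(trips) == 0L) stop("cannot cluster destinations of zero trips")
  ord <- order(trips$end)
  lat <- trips$end_lat[ord]; lon <- trips$end_lon[ord]
  k <- 0L
  c_lat <- numeric(0); c_lon <- numeric(0); c_n <- integer(0)
  assign <- integer(length(lat))
  for (i in seq_along(lat)) {
    hit <- 0L
    if (k > 0L) {
      d <- haversine_km(lat[i], lon[i], c_lat[1:k], c_lon[1:k]) * 1000
      w <- which(d <= radius_m)
      if (length(w)) hit <- w[1L]
    }
    if (hit > 0L) {
      c_lat[hit] <- (c_lat[hit] * c_n[hit] + lat[i]) / (c_n[hit] + 1L)
      c_lon[hit] <- (c_lon[hit] * c_n[hit] + lon[i]) / (c_n[hit] + 1L)
      c_n[hit] <- c_n[hit] + 1L
      assign[i] <- hit
    } else {
      k <- k + 1L
      c_lat[k] <- lat[i]; c_lon[k] <- lon[i]; c_n[k] <- 1L
      assign[i] <- k
    }
  }
  structure(list(
    destinations = data.table::data.table(lat = c_lat, lon = c_lon, n = c_n),
    visits = data.table::data.table(dest = assign, time = trips$end[ord]),
    N = length(lat)
  ), class = "dest_set")
}

#' @export
print.dest_set <- function(x, ...) {
  cat("<dest_set> ", nrow(x$destinations), " destination(s), ",
      x$N, " visit(s)\n", sep = "")
  invisible(x)
}

#' Radius of gyration of a destination set
#'
#' The visit-weighted root-mean-square distance of destinations from their
#' visit-weighted centre of mass:
#' \deqn{r_g = \sqrt{\frac{1}{N} \sum_{i \in L} n_i (r_i - r_{cm})^2}}
#' where \eqn{L} is the destination set, \eqn{n_i} the visitation frequency
#' of destination \eqn{i} and \eqn{N = \sum n_i}. Coordinates are evaluated
#' in a local east-north tangent plane centred on the unweighted midpoint of
#' the destinations (raw degree arithmetic would distort with latitude);
#' distances are Euclidean in that plane, in km.
#'
#' @param ds A `dest_set`.
#' @return Radius of gyration in km (0 for a single destination).
#' @export
radius_of_gyration <- function(ds) {
  d <- ds$destinations
  if (nrow(d) == 0L) stop("empty destination set")
  if (nrow(d) == 1L) return(0)
  en <- local_en_km(d$lat, d$lon, mean(d$lat), mean(d$lon))
  w <- d$n / sum(d$n)
  cm <- c(sum(w * en[, 1]), sum(w * en[, 2]))
  sqrt(sum(w * ((en[, 1] - cm[1])^2 + (en[, 2] - cm[2])^2)))
}

#' Spatiotemporal destination entropy
#'
#' Plug-in Shannon entropy (nats) of visits tabulated over states defined by
#' destination crossed with time-of-day bin: \eqn{S = -\sum_s p_s \ln p_s}
#' over non-empty states, \eqn{p_s} the fraction of visits in state \eqn{s}.
#' With the default 4 bins the local day is split into equal six-hour periods
#' (night 00-06, morning 06-12, afternoon 12-18, evening 18-24);
#' `time_bins = 1` degrades to purely spatial entropy.
#'
#' @param ds A `dest_set`.
#' @param time_bins Number of equal-width time-of-day bins.
#' @param tz IANA timezone used to localise visit times.
#' @return Entropy in nats.
#' @export
entropy <- function(ds, time_bins = 4, tz = "America/Chicago") {
  stopifnot(time_bins >= 1)
  if (ds$N == 0L) stop("empty destination set")
  if (time_bins == 1) {
    counts <- ds$destinations$n
  } else {
    hour <- as.numeric(format(ds$visits$time, "%H", tz = tz)) +
            as.numeric(format(ds$visits$time, "%M", tz = tz)) / 60
    bin <- pmin(floor(hour / (24 / time_bins)), time_bins - 1)
    counts <- table(paste(ds$visits$dest, bin))
  }
  p <- as.numeric(counts) / ds$N
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Driving-space indicators for one participant-window
#'
#' Computes the seven driving-space indicators over a set of trips belonging
#' to a single participant and aggregation window: mean trip distance
#' (`TripDist`, km), total distance (`TotalDist`, km), trip count (`nTrips`)
#' with five half-open distance subgroups in miles
#' (`[0,1) [1,5) [5,10) [10,20) [20,Inf)`), radius of gyration (`Rg`, km),
#' spatiotemporal destination entropy (`S`, nats), night trips
#' (`nNightTrip`: local start time after that date's sunset, or before
#' sunrise under the default extended rule) and unique destinations
#' (`nUniqDest`).
#'
#' @param trips A trip table for one participant-window.
#' @param ds Optional pre-computed `dest_set` for these trips (clustered at
#'   `radius_m` if omitted).
#' @param tz Study timezone for local-time logic.
#' @param radius_m Destination clustering radius, metres.
#' @param time_bins Time-of-day bins for the entropy.
#' @param night_mode `"extended"` (after sunset or before sunrise) or
#'   `"after_sunset"`.
#' @return A one-row `data.table` with columns `TripDist`, `TotalDist`,
#'   `nTrips`, `nTrips_0_1`, `nTrips_1_5`, `nTrips_5_10`, `nTrips_10_20`,
#'   `nTrips_20p`, `Rg`, `S`, `nNightTrip`, `nUniqDest`, `empty`.
#' @export
compute_space_indicators <- function(trips, ds = NULL, tz = "America/Chicago",
                                     radius_m = 150, time_bins = 4,
                                     night_mode = "extended") {
  if (nrow(trips) == 0L) {
    out <- data.table::as.data.table(
      as.list(setNames(rep(0, 12), space_indicator_names())))
    out$empty <- TRUE
    return(out)
  }
  if (is.null(ds)) ds <- cluster_destinations(trips, radius_m = radius_m)
  miles <- trips$distance_km / KM_PER_MILE
  bins <- tabulate(findInterval(miles, c(0, 1, 5, 10, 20)), nbins = 5)
  night <- is_night(trips$start, trips$start_lat, trips$start_lon, tz,
                    mode = night_mode)
  data.table::data.table(
    TripDist = mean(trips$distance_km),
    TotalDist = sum(trips$distance_km),
    nTrips = nrow(trips),
    nTrips_0_1 = bins[1], nTrips_1_5 = bins[2], nTrips_5_10 = bins[3],
    nTrips_10_20 = bins[4], nTrips_20p = bins[5],
    Rg = radius_of_gyration(ds),
    S = entropy(ds, time_bins = time_bins, tz = tz),
    nNightTrip = sum(night),
    nUniqDest = nrow(ds$destinations),
    empty = FALSE
  )
}

space_indicator_names <- function() {
  c("TripDist", "TotalDist", "nTrips", "nTrips_0_1", "nTrips_1_5",
    "nTrips_5_10", "nTrips_10_20", "nTrips_20p", "Rg", "S", "nNightTrip",
    "nUniqDest")
}
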