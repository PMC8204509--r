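# Build a drv_log-like data.table from vectors (speeds m/s, UTC timestamps).
make_log <- function(id = "P1", t, lat, lon, speed,
                     posted_limit = NA_real_, event_flag = NA_character_) {
  n <- length(t)
  out <- data.table::data.table(
    participant_id = rep_len(id, n),
    timestamp = as.POSIXct(t, tz = "UTC", origin = "1970-01-01"),
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    speed = rep_len(speed, n),
    posted_limit = rep_len(posted_limit, n),
    event_flag = rep_len(event_flag, n)
  )
  data.table::setattr(out, "class", c("drv_log", class(out)))
  out
}

# A straight eastbound log at constant speed: 30-s sampling from a start
# instant, point spacing consistent with the speed.
make_cruise_log <- function(id = "P1", n = 10, speed = 10,
                            t0 = as.POSIXct("2019-03-05 18:00:00", tz = "UTC"),
                            lat = 38.6, lon0 = -90.2, dt = 30,
                            posted_limit = NA_real_,
                            event_flag = NA_character_) {
  step_deg <- (speed * dt / 1000) / (111.195 * cos(lat * pi / 180))
  make_log(id, t = as.numeric(t0) + (0:(n - 1)) * dt, lat = lat,
           lon = lon0 + (0:(n - 1)) * step_deg, speed = speed,
           posted_limit = posted_limit, event_flag = event_flag)
}

# Trip table row(s) for indicator tests without running segmentation.
make_trip_table <- function(distance_km, start, end = start + 600,
                            end_lat = 38.6, end_lon = -90.2,
                            start_lat = 38.6, start_lon = -90.25,
                            n_hard_brakes = 0L, n_sudden_accels = 0L,
                            has_overspeed = FALSE, has_underspeed = FALSE,
                            mean_speed = 10, mean_abs_accel = 0,
                            mean_abs_jerk = 0) {
  n <- length(distance_km)
  data.table::data.table(
    trip_id = seq_len(n), participant_id = "P1",
    start = rep_len(as.POSIXct(start, tz = "UTC"), n),
    end = rep_len(as.POSIXct(end, tz = "UTC"), n),
    n_points = 10L, distance_km = distance_km,
    start_lat = rep_len(start_lat, n), start_lon = rep_len(start_lon, n),
    end_lat = rep_len(end_lat, n), end_lon = rep_len(end_lon, n),
    n_hard_brakes = rep_len(as.integer(n_hard_brakes), n),
    n_sudden_accels = rep_len(as.integer(n_sudden_accels), n),
    has_overspeed = rep_len(has_overspeed, n),
    has_underspeed = rep_len(has_underspeed, n),
    mean_speed = rep_len(mean_speed, n),
    mean_abs_accel = rep_len(mean_abs_accel, n),
    mean_abs_jerk = rep_len(mean_abs_jerk, n)
  )
}

# A dest_set built directly from coordinates and counts.
make_dest_set <- function(lat, lon, n,
                          times = as.POSIXct("2019-06-01 18:00:00", tz = "UTC") +
                            seq_len(sum(n)) * 3600) {
  structure(list(
    destinations = data.table::data.table(lat = lat, lon = lon, n = as.integer(n)),
    visits = data.table::data.table(dest = rep(seq_along(n), n),
                                    time = times[seq_len(sum(n))]),
    N = sum(n)
  ), class = "dest_set")
}

# Small labelled record set with separable driving features, for model tests.
make_records <- function(n_per_class = 40, seed = 1, separation = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- rep(c(0L, 1L), each = n_per_class)
  ids <- c(sprintf("A%02d", rep(seq_len(max(1, n_per_class %/% 4)),
                                length.out = n_per_class)),
           sprintf("B%02d", rep(seq_len(max(1, n_per_class %/% 4)),
                                length.out = n_per_class)))
  base <- data.table::data.table(
    participant_id = ids,
    label = lab, age = rnorm(n, 76, 4), apoe_e4 = runif(n) < 0.3
  )
  for (ind in c(indicator_names(), "nTrips_0_1", "nTrips_1_5", "nTrips_5_10",
                "nTrips_10_20", "nTrips_20p"))
    base[[ind]] <- rnorm(n) + separation * lab *
      (ind %in% c("TotalDist", "avgJ", "Rg"))
  base
}
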