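test_that("haversine distance matches analytic values and is symmetric", {
  expect_equal(haversine_km(0, 0, 0, 0), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 111.195, tolerance = 1e-5)
  expect_equal(haversine_km(0, 0, 1, 0), haversine_km(0, 0, 0, 1),
               tolerance = 1e-9)
  expect_equal(haversine_km(38.6, -90.2, 38.7, -90.1),
               haversine_km(38.7, -90.1, 38.6, -90.2))
})

test_that("gap-based segmentation splits and filters trips", {
  t0 <- as.numeric(as.POSIXct("2019-02-01 10:00:00", tz = "UTC"))
  t <- c(t0 + (0:19) * 30, t0 + 19 * 30 + 600 + (0:19) * 30)
  log <- make_log(t = t, lat = 38.6, lon = -90.2 + seq_along(t) * 0.001,
                  speed = 10)
  x <- segment_trips(log)
  expect_equal(nrow(x$trips), 2L)
  expect_equal(x$trips$n_points, c(20L, 20L))

  # empty input
  expect_equal(nrow(segment_trips(make_log(t = numeric(0), lat = numeric(0),
                                           lon = numeric(0), speed = numeric(0)))$trips), 0L)

  # three points with min_points = 4: discarded and logged
  short <- make_log(t = t0 + (0:2) * 30, lat = 38.6,
                    lon = -90.2 + (0:2) * 0.01, speed = 10)
  expect_message(x2 <- segment_trips(short), "discarded")
  expect_equal(nrow(x2$trips), 0L)
  expect_equal(x2$n_discarded, 1L)
})

test_that("segment distance never exceeds the full point-to-point path length", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 60
    t0 <- as.numeric(as.POSIXct("2019-02-01 08:00:00", tz = "UTC"))
    gaps <- sample(c(30, 30, 30, 600), n - 1, replace = TRUE)
    t <- t0 + cumsum(c(0, gaps))
    lat <- 38.6 + cumsum(rnorm(n, 0, 0.003))
    lon <- -90.2 + cumsum(rnorm(n, 0, 0.003))
    log <- make_log(t = t, lat = lat, lon = lon, speed = 10)
    path <- sum(haversine_km(lat[-n], lon[-n], lat[-1], lon[-1]))
    x <- suppressMessages(segment_trips(log, min_points = 2, min_km = 0))
    expect_lte(sum(x$trips$distance_km), path + 1e-9)
  }
})

test_that("finite-difference kinematics reproduces hand computations", {
  t0 <- as.numeric(as.POSIXct("2019-02-01 10:00:00", tz = "UTC"))
  log <- make_log(t = t0 + (0:2) * 30, lat = 38.6,
                  lon = -90.2 + (0:2) * 0.002, speed = c(0, 3, 6))
  x <- kinematics(segment_trips(log, min_points = 3, min_km = 0))
  expect_equal(x$pairs$accel, c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(x$jerks$jerk, 0, tolerance = 1e-12)

  log2 <- make_log(t = t0 + (0:2) * 30, lat = 38.6,
                   lon = -90.2 + (0:2) * 0.002, speed = c(0, 6, 6))
  x2 <- kinematics(segment_trips(log2, min_points = 3, min_km = 0))
  expect_equal(x2$pairs$accel, c(0.2, 0), tolerance = 1e-12)
  expect_equal(x2$jerks$jerk, -0.2 / 30, tolerance = 1e-12)

  # constant speed: zero everywhere
  x3 <- kinematics(segment_trips(make_cruise_log(n = 8), min_km = 0))
  expect_true(all(abs(x3$pairs$accel) < 1e-12))
  expect_true(all(abs(x3$jerks$jerk) < 1e-12))
})

test_that("kinematics agrees with a brute-force oracle on random small trips", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    t0 <- as.numeric(as.POSIXct("2019-02-01 10:00:00", tz = "UTC"))
    dts <- sample(c(1, 2, 29, 30, 31), n - 1, replace = TRUE)
    t <- t0 + cumsum(c(0, dts))
    v <- runif(n, 0, 30)
    log <- make_log(t = t, lat = 38.6, lon = -90.2 + (1:n) * 0.01, speed = v)
    x <- kinematics(segment_trips(log, gap_s = 40, min_points = 2, min_km = 0))
    # oracle: direct loops over the definition
    a <- numeric(n - 1); j <- numeric(max(0, n - 2))
    for (i in 1:(n - 1)) a[i] <- (v[i + 1] - v[i]) / (t[i + 1] - t[i])
    if (n >= 3) for (k in 1:(n - 2))
      j[k] <- (a[k + 1] - a[k]) / ((t[k + 2] - t[k]) / 2)
    expect_equal(x$pairs$accel, a, tolerance = 1e-12)
    expect_equal(x$jerks$jerk, j, tolerance = 1e-12)
  }
})

test_that("event detection thresholds and flag precedence behave as specified", {
  t0 <- as.numeric(as.POSIXct("2019-02-01 10:00:00", tz = "UTC"))
  # burst sample pair dropping 4 m/s in 1 s crosses the 8 mph/s threshold
  t <- t0 + c(0, 30, 60, 61, 90, 120)
  v <- c(10, 10, 10, 6, 10, 10)
  log <- make_log(t = t, lat = 38.6, lon = -90.2 + (1:6) * 0.003, speed = v)
  x <- detect_events(kinematics(segment_trips(log, min_km = 0)))
  expect_equal(x$trips$n_hard_brakes, 1L)
  expect_equal(x$trips$n_sudden_accels, 0L)

  # constant speed, no flags: zero counts
  x0 <- detect_events(kinematics(segment_trips(make_cruise_log(n = 8), min_km = 0)))
  expect_equal(x0$trips$n_hard_brakes, 0L)

  # device flags present: counts from flags even with smooth kinematics
  flags <- c("none", "hard_brake", "none", "hard_brake", "none", "none",
             "none", "none")
  logf <- make_cruise_log(n = 8, event_flag = NA)
  logf$event_flag <- flags
  xf <- detect_events(kinematics(segment_trips(logf, min_km = 0)))
  expect_equal(xf$trips$n_hard_brakes, 2L)
  expect_equal(xf$trips$n_sudden_accels, 0L)
})

test_that("event detection is invariant to stationary padding", {
  t0 <- as.numeric(as.POSIXct("2019-02-01 10:00:00", tz = "UTC"))
  t <- t0 + c(0, 30, 60, 61, 90, 120)
  v <- c(10, 10, 10, 14, 10, 10)
  log <- make_log(t = t, lat = 38.6, lon = -90.2 + (1:6) * 0.003, speed = v)
  core <- detect_events(kinematics(segment_trips(log, min_km = 0)))
  padded <- make_log(t = c(t0 - 60, t0 - 30, t, t0 + 150, t0 + 180),
                     lat = 38.6,
                     lon = c(-90.203, -90.203, -90.2 + (1:6) * 0.003,
                             -90.182, -90.182),
                     speed = c(0, 0, v, 0, 0))
  xp <- detect_events(kinematics(segment_trips(padded, min_km = 0)))
  expect_equal(xp$trips$n_sudden_accels, core$trips$n_sudden_accels)
  expect_equal(xp$trips$n_hard_brakes, core$trips$n_hard_brakes)
})

test_that("speeding flags honour the 6 mph margin and coverage rule", {
  # all speeds at the limit: neither flag
  log <- make_cruise_log(n = 8, speed = 13.4, posted_limit = 13.4)
  x <- flag_speeding(kinematics(segment_trips(log, min_km = 0)))
  expect_false(x$trips$has_overspeed); expect_false(x$trips$has_underspeed)

  # one point 3 m/s above the limit (> 2.68224 margin)
  log2 <- make_cruise_log(n = 8, speed = 13.4, posted_limit = 13.4)
  log2$speed[4] <- 13.4 + 3.0
  x2 <- flag_speeding(kinematics(segment_trips(log2, min_km = 0)))
  expect_true(x2$trips$has_overspeed)

  # no posted limits: flags undefined
  log3 <- make_cruise_log(n = 8, speed = 13.4)
  x3 <- flag_speeding(kinematics(segment_trips(log3, min_km = 0)))
  expect_true(is.na(x3$trips$has_overspeed))

  # slow-moving point below limit - margin counts; stationary does not
  log4 <- make_cruise_log(n = 8, speed = 13.4, posted_limit = 13.4)
  log4$speed[5] <- 0.3
  x4 <- flag_speeding(kinematics(segment_trips(log4, min_km = 0)))
  expect_false(x4$trips$has_underspeed)
  log4$speed[5] <- 2
  x5 <- flag_speeding(kinematics(segment_trips(log4, min_km = 0)))
  expect_true(x5$trips$has_underspeed)
})
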