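# move a point east by metres at given latitude
lon_shift <- function(lon, metres, lat = 38.6)
  lon + (metres / 1000) / (111.195 * cos(lat * pi / 180))

test_that("greedy chronological clustering merges endpoints within the radius", {
  base <- as.POSIXct("2019-04-01 10:00:00", tz = "UTC")
  tr <- make_trip_table(distance_km = rep(5, 5), start = base + (0:4) * 7200)
  tr$end <- base + (0:4) * 7200 + 600
  ds <- cluster_destinations(tr)
  expect_equal(nrow(ds$destinations), 1L)
  expect_equal(ds$destinations$n, 5L)

  # endpoints 0 and 100 m apart with radius 150 m merge
  tr2 <- make_trip_table(distance_km = rep(5, 2), start = base + (0:1) * 7200)
  tr2$end <- base + (0:1) * 7200 + 600
  tr2$end_lon <- c(-90.2, lon_shift(-90.2, 100))
  expect_equal(nrow(cluster_destinations(tr2)$destinations), 1L)

  # 0, 100, 300 m along a line: greedy chronological gives clusters (2, 1)
  tr3 <- make_trip_table(distance_km = rep(5, 3), start = base + (0:2) * 7200)
  tr3$end <- base + (0:2) * 7200 + 600
  tr3$end_lon <- c(-90.2, lon_shift(-90.2, 100), lon_shift(-90.2, 300))
  ds3 <- cluster_destinations(tr3)
  expect_equal(ds3$destinations$n, c(2L, 1L))
})

test_that("radius of gyration matches analytic limits", {
  expect_equal(radius_of_gyration(make_dest_set(38.6, -90.2, 5)), 0)
  # two destinations, equal visits, 10 km apart: d/2
  ds <- make_dest_set(c(38.6, 38.6), c(-90.2, lon_shift(-90.2, 10000)),
                      c(3, 3))
  expect_equal(radius_of_gyration(ds), 5, tolerance = 1e-2)
  expect_error(radius_of_gyration(make_dest_set(numeric(0), numeric(0),
                                                integer(0))), "empty")
})

test_that("radius of gyration matches the direct-formula oracle on random sets", {
  # oracle: the pairwise identity rg^2 = 1/2 sum_ij p_i p_j d_ij^2 evaluated
  # in the same tangent plane; an independent evaluation of the formula
  set.seed(11)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    lat <- 38.6 + runif(k, -0.05, 0.05)
    lon <- -90.2 + runif(k, -0.05, 0.05)
    n <- sample(1:5, k, replace = TRUE)
    ds <- make_dest_set(lat, lon, n)
    rg <- radius_of_gyration(ds)
    en <- drivemarkers:::local_en_km(lat, lon, mean(lat), mean(lon))
    p <- n / sum(n)
    d2 <- outer(en[, 1], en[, 1], "-")^2 + outer(en[, 2], en[, 2], "-")^2
    oracle <- sqrt(0.5 * sum(outer(p, p) * d2))
    expect_equal(rg, oracle, tolerance = 1e-9)
  }
})

test_that("radius of gyration is translation invariant", {
  set.seed(3)
  lat <- 38.6 + runif(4, -0.03, 0.03); lon <- -90.2 + runif(4, -0.03, 0.03)
  n <- c(2, 1, 1, 3)
  rg1 <- radius_of_gyration(make_dest_set(lat, lon, n))
  rg2 <- radius_of_gyration(make_dest_set(lat + 0.05, lon - 0.07, n))
  expect_lt(abs(rg2 - rg1) / rg1, 0.001)
})

test_that("entropy hits its analytic values and bounds", {
  # single destination, single time bin: zero
  ds1 <- make_dest_set(38.6, -90.2, 4,
                       times = rep(as.POSIXct("2019-06-01 15:00:00",
                                              tz = "UTC"), 4))
  expect_equal(entropy(ds1), 0)

  # uniform visits over 8 states (2 destinations x 4 bins): ln 8
  times <- as.POSIXct(paste0("2019-06-0", 1:8, " ",
                             rep(c("09", "15", "21", "03"), 2), ":00:00"),
                      tz = "America/Chicago")
  ds8 <- make_dest_set(c(38.6, 38.7), c(-90.2, -90.1), c(4, 4),
                       times = times)
  expect_equal(entropy(ds8), log(8), tolerance = 1e-12)

  # counts (2,1,1) over 3 states
  ds3 <- make_dest_set(c(38.6, 38.7, 38.8), c(-90.2, -90.1, -90.0),
                       c(2, 1, 1),
                       times = rep(as.POSIXct("2019-06-01 15:00:00",
                                              tz = "UTC"), 4))
  expect_equal(entropy(ds3), -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
  # spatial-only degradation and the ln(states) bound
  expect_equal(entropy(ds3, time_bins = 1), entropy(ds3))
  expect_lte(entropy(ds8), log(8) + 1e-12)
})

test_that("space indicators aggregate trips with half-open mile bins", {
  base <- as.POSIXct("2019-04-01 17:00:00", tz = "UTC")
  tr <- make_trip_table(distance_km = c(5, 15), start = base + c(0, 7200))
  tr$end <- tr$start + 600
  si <- compute_space_indicators(tr)
  expect_equal(si$TripDist, 10)
  expect_equal(si$TotalDist, 20)
  expect_equal(si$nTrips, 2L)

  # exactly one mile lands in [1, 5)
  tr1 <- make_trip_table(distance_km = 1.609344, start = base)
  tr1$end <- tr1$start + 600
  si1 <- compute_space_indicators(tr1)
  expect_equal(si1$nTrips_0_1, 0)
  expect_equal(si1$nTrips_1_5, 1)

  # a 22:00 local start is a night trip at this latitude in any season
  tz <- "America/Chicago"
  trn <- make_trip_table(distance_km = 5,
                         start = as.POSIXct("2019-07-10 22:00:00", tz = tz))
  trn$end <- trn$start + 600
  expect_equal(compute_space_indicators(trn, tz = tz)$nNightTrip, 1L)
  trd <- make_trip_table(distance_km = 5,
                         start = as.POSIXct("2019-07-10 12:00:00", tz = tz))
  trd$end <- trd$start + 600
  expect_equal(compute_space_indicators(trd, tz = tz)$nNightTrip, 0L)
})

test_that("distance-bin counts always sum to the trip count", {
  set.seed(5)
  base <- as.POSIXct("2019-04-01 12:00:00", tz = "UTC")
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    d <- exp(rnorm(n, 1.5, 1))
    tr <- make_trip_table(distance_km = d, start = base + (0:(n - 1)) * 3600)
    tr$end <- tr$start + 600
    si <- compute_space_indicators(tr)
    expect_equal(si$nTrips_0_1 + si$nTrips_1_5 + si$nTrips_5_10 +
                 si$nTrips_10_20 + si$nTrips_20p, si$nTrips)
  }
})
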