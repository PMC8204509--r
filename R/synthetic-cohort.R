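#' Specification of a synthetic driving cohort
#'
#' Defaults emulate the study conditions the package targets: a two-group
#' cohort of older drivers (75 without and 64 with preclinical AD), group
#' ages 75.7 +/- 4.8 vs 79.1 +/- 4.9 years, APOE e4 carrier probabilities
#' 0.30 vs 0.33, and per-group study-period indicator targets (mean and SD
#' for each of the 14 driving indicators) taken from the published group
#' descriptives. Participants' homes are scattered over the St. Louis area
#' and 12 months of 30-s GPS points are realised per participant.
#'
#' @param n_without,n_with Group sizes.
#' @param age_mean,age_sd Length-2 numeric (without, with), years.
#' @param apoe_p Length-2 carrier probabilities.
#' @param months Number of calendar months simulated, starting at
#'   `start_date`.
#' @param start_date First day of the study window.
#' @param home_box Named list `lat = c(min, max)`, `lon = c(min, max)`.
#' @param targets Data frame with columns `indicator`, `mean_noad`,
#'   `sd_noad`, `mean_ad`, `sd_ad`; defaults to
#'   [default_indicator_targets()]. Study-period scale (totals over
#'   `months = 12`).
#' @param rho Latent correlation among the distance/trip-count indicators
#'   (TripDist, TotalDist, nTrips, nNightTrip, nUniqDest).
#' @param csf_threshold Amyloid-positivity cutpoint for label assignment.
#' @param tz Study timezone.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_without = 75, n_with = 64,
                        age_mean = c(75.7, 79.1), age_sd = c(4.8, 4.9),
                        apoe_p = c(0.30, 0.33), months = 12,
                        start_date = "2019-01-01",
                        home_box = list(lat = c(38.45, 38.75),
                                        lon = c(-90.45, -90.15)),
                        targets = default_indicator_targets(),
                        rho = 0.5, csf_threshold = 0.0673,
                        tz = "America/Chicago") {
  stopifnot(n_without >= 1, n_with >= 1, months >= 1,
            all(apoe_p >= 0 & apoe_p <= 1))
  targets <- data.table::as.data.table(targets)
  bad <- targets$indicator[targets$mean_noad <= 0 | targets$mean_ad <= 0 |
                           targets$sd_noad <= 0 | targets$sd_ad <= 0]
  if (length(bad))
    stop("infeasible (non-positive) targets for indicator(s): ",
         paste(bad, collapse = ", "))
  structure(list(
    n_without = n_without, n_with = n_with, age_mean = age_mean,
    age_sd = age_sd, apoe_p = apoe_p, months = months,
    start_date = as.Date(start_date), home_box = home_box,
    targets = targets, rho = rho, csf_threshold = csf_threshold, tz = tz
  ), class = "cohort_spec")
}

#' Default study-period indicator targets
#'
#' Group means and SDs (without / with preclinical AD) of the 14 driving
#' indicators over a 12-month study period, used as simulator calibration
#' targets. Distances in km, speeds m/s, event rates per statute mile,
#' entropy in nats.
#'
#' @return A `data.table` with columns `indicator`, `mean_noad`, `sd_noad`,
#'   `mean_ad`, `sd_ad`.
#' @export
default_indicator_targets <- function() {
  data.table::fread(system.file("extdata", "indicator_group_stats.csv",
                                package = "drivemarkers"))[
    , .(indicator, mean_noad, sd_noad, mean_ad, sd_ad)]
}

# physical clipping bounds per indicator (study-period scale)
indicator_bounds <- function() {
  list(TripDist = c(0.5, 80), TotalDist = c(30, 6000), nTrips = c(6, 500),
       Rg = c(0.3, 1200), S = c(0.3, 5.5), nNightTrip = c(0, 500),
       nUniqDest = c(2, 150), nHardBrake = c(0, 0.6), nSuddenAcc = c(0, 0.6),
       OverV = c(0, 0.9), UnderV = c(0, 0.9), avgV = c(3, 38),
       avgA = c(0.3, 10), avgJ = c(0.15, 8))
}

# Draw one participant's latent indicator targets from a Gaussian copula.
# Marginals are moment-matched by coefficient of variation: gamma for the
# strongly skewed indicators (CV >= 0.8, e.g. Rg and the event rates, where
# a lognormal's tail would make cohort means erratic), lognormal for
# moderately skewed ones, near-normal with physical clipping otherwise.
draw_theta <- function(mu, sigma, rho_block, n) {
  k <- length(mu)
  corr <- diag(k)
  block <- match(c("TripDist", "TotalDist", "nTrips", "nNightTrip",
                   "nUniqDest"), names(mu))
  for (i in block) for (j in block) if (i != j) corr[i, j] <- rho_block
  z <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = corr)
  if (n == 1) z <- matrix(z, nrow = 1)
  # stratified (Latin-hypercube) uniforms: ranks keep the copula dependence
  # while each finite group's empirical marginal matches its distribution,
  # so group means are stable at realistic cohort sizes
  u <- apply(z, 2, function(col) (rank(col, ties.method = "first") - runif(n)) / n)
  if (n == 1) u <- matrix(u, nrow = 1)
  theta <- matrix(NA_real_, n, k, dimnames = list(NULL, names(mu)))
  bounds <- indicator_bounds()
  for (j in seq_len(k)) {
    cv <- sigma[j] / mu[j]
    if (cv >= 0.8) {
      v <- stats::qgamma(u[, j], shape = 1 / cv^2, scale = mu[j] * cv^2)
    } else if (cv >= 0.35) {
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(mu[j]) - sdlog^2 / 2
      v <- qlnorm(u[, j], meanlog, sdlog)
    } else {
      v <- qnorm(u[, j], mu[j], sigma[j])
    }
    b <- bounds[[names(mu)[j]]]
    theta[, j] <- pmin(pmax(v, b[1]), b[2])
  }
  theta
}

#' Sample a synthetic cohort
#'
#' Draws participant metadata (ages truncated at 65, APOE carrier flags, CSF
#' ratios strictly on the correct side of the positivity threshold) and
#' per-participant latent indicator targets from correlated group
#' distributions, then plans every trip of the study period (month, start
#' time, destination, distance, speed-compliance and event injections) and
#' calibrates each participant's destination pool (size and Zipf exponent
#' solved so expected unique destinations and spatiotemporal entropy match
#' the latent targets) and kinematic dither (burst amplitude and mix solved
#' so extracted mean |acceleration| and |jerk| match).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List with `profiles` (per-participant plan objects) and `meta`
#'   (metadata `data.table`).
#' @export
sample_cohort <- function(spec, seed = 1) {
  set.seed(seed)
  n <- spec$n_without + spec$n_with
  group <- c(rep(0L, spec$n_without), rep(1L, spec$n_with))
  ids <- sprintf("P%03d", seq_len(n))

  age <- numeric(n); csf <- numeric(n)
  for (i in seq_len(n)) {
    g <- group[i] + 1L
    repeat {
      a <- rnorm(1, spec$age_mean[g], spec$age_sd[g])
      if (a >= 65) break
    }
    age[i] <- round(a, 1)
    csf[i] <- if (group[i] == 1L)
      runif(1, 0.030, spec$csf_threshold - 1e-4)
    else runif(1, spec$csf_threshold + 1e-4, 0.120)
  }
  apoe <- rbinom(n, 1, spec$apoe_p[group + 1L]) == 1
  sex <- ifelse(runif(n) < 0.49, "F", "M")
  education <- round(pmax(8, rnorm(n, 16.4, 2.3)))

  meta <- data.table::data.table(
    participant_id = ids, age = age, apoe_e4 = apoe, csf_ratio = csf,
    sex = sex, education_years = education)

  tg <- spec$targets
  mu0 <- setNames(tg$mean_noad, tg$indicator); sd0 <- setNames(tg$sd_noad, tg$indicator)
  mu1 <- setNames(tg$mean_ad, tg$indicator); sd1 <- setNames(tg$sd_ad, tg$indicator)
  theta <- matrix(NA_real_, n, length(mu0), dimnames = list(NULL, names(mu0)))
  theta[group == 0L, ] <- draw_theta(mu0, sd0, spec$rho, sum(group == 0L))
  theta[group == 1L, ] <- draw_theta(mu1, sd1, spec$rho, sum(group == 1L))

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    home <- c(lat = runif(1, spec$home_box$lat[1], spec$home_box$lat[2]),
              lon = runif(1, spec$home_box$lon[1], spec$home_box$lon[2]))
    profiles[[i]] <- build_profile(ids[i], theta[i, ], home, spec)
  }
  names(profiles) <- ids
  list(profiles = profiles, meta = meta)
}

# ---- per-participant planning -------------------------------------------

build_profile <- function(id, theta, home, spec) {
  m <- spec$months
  scale_m <- m / 12  # targets are 12-month totals
  n_trips <- max(m, round(theta[["nTrips"]] * scale_m))
  total_km <- theta[["TotalDist"]] * scale_m
  p_night <- min(0.95, max(0, theta[["nNightTrip"]] / theta[["nTrips"]]))
  mu_trip <- total_km / n_trips

  # trip distances: lognormal shape, rescaled to the exact total
  d <- rlnorm(n_trips, log(mu_trip) - 0.85^2 / 2, 0.85)
  d <- d * total_km / sum(d)
  d <- pmin(pmax(d, 0.15), 150)

  # months and start times (schedule returns all per-trip vectors in
  # chronological order, correctly paired)
  month_of <- sort(c(rep(seq_len(m), n_trips %/% m),
                     sample(seq_len(m), n_trips %% m)))
  night <- runif(n_trips) < p_night
  sched <- schedule_trips(month_of, d, night, theta[["avgV"]], home, spec)
  d <- sched$d; month_of <- sched$month; night <- sched$night

  # destination pool calibrated to nUniqDest and S
  arrive_hour <- as.numeric(format(sched$start + sched$dur_est,
                                   tz = spec$tz, format = "%H"))
  pool <- solve_destination_pool(
    n_uniq = min(theta[["nUniqDest"]] * scale_m, 0.85 * n_trips),
    s_target = theta[["S"]], hours = arrive_hour, n_visits = n_trips)
  geom <- place_destinations(pool$K, pool$w, theta[["Rg"]], home)
  dest_idx <- sample.int(pool$K, n_trips, replace = TRUE, prob = pool$w)

  # kinematic dither calibrated against this participant's trip-length mix
  n_base_all <- pmax(6, round(d * 1000 / (30 * theta[["avgV"]])) + 2)
  kin <- calibrate_dither(n_base_all, theta[["avgV"]], theta[["avgA"]],
                          theta[["avgJ"]])

  miles <- d / KM_PER_MILE
  plan <- data.table::data.table(
    month = month_of, start = sched$start, distance_km = d,
    night = night, dest = dest_idx,
    over = runif(n_trips) < theta[["OverV"]],
    under = runif(n_trips) < theta[["UnderV"]],
    n_hb = rpois(n_trips, theta[["nHardBrake"]] * miles),
    n_sa = rpois(n_trips, theta[["nSuddenAcc"]] * miles)
  )
  list(participant_id = id, theta = theta, home = home, plan = plan,
       dest_lat = geom$lat, dest_lon = geom$lon, kin = kin,
       avg_v = theta[["avgV"]])
}

# Draw start instants: per trip a night start (sunset + 5 min .. 4 h) or a
# day start (sunrise + 1 h .. sunset - 1.5 h), then push overlapping trips
# forward so consecutive trips stay separated by an ignition-off gap.
# Returns every per-trip vector sorted chronologically and kept paired.
schedule_trips <- function(month_of, d_km, night, avg_v, home, spec) {
  m0 <- seq(spec$start_date, by = "month", length.out = max(month_of) + 1)
  dur_est <- (d_km * 1000 / avg_v) + 240
  start <- as.POSIXct(rep(NA_real_, length(month_of)), tz = "UTC",
                      origin = "1970-01-01")
  for (i in seq_along(month_of)) {
    ndays <- as.integer(m0[month_of[i] + 1] - m0[month_of[i]])
    day <- m0[month_of[i]] + sample.int(max(ndays - 1, 1), 1) - 1
    st <- sun_times_utc(day, home["lat"], home["lon"])
    start[i] <- if (night[i])
      st$sunset + runif(1, 300, 4 * 3600)
    else
      st$sunrise + 3600 + runif(1) *
        pmax(600, as.numeric(st$sunset - st$sunrise, units = "secs") - 9000)
  }
  ord <- order(start)
  start <- start[ord]; dur <- dur_est[ord]
  for (i in seq_along(start)[-1]) {
    min_start <- start[i - 1] + dur[i - 1] + 600
    if (start[i] < min_start) start[i] <- min_start + runif(1, 0, 600)
  }
  list(start = start, dur_est = dur, d = d_km[ord], month = month_of[ord],
       night = night[ord])
}

# Expected plug-in Shannon entropy (nats) of joint (destination x time-bin)
# visit counts: time-bin margins n_b are fixed by the schedule, destination
# draws are iid Zipf, so the count in state (i, b) is Binomial(n_b, w_i).
# Exact binomial expectation per state, truncated where mass is negligible.
expected_plugin_entropy <- function(w, n_bins, n_visits) {
  total <- 0
  for (b in seq_along(n_bins)) {
    nb <- n_bins[b]
    if (nb == 0) next
    cmax <- min(nb, max(stats::qbinom(1 - 1e-9, nb, max(w))) + 1)
    cc <- seq_len(cmax)
    # dbinom over the (count x state) grid in one vectorised call
    pr <- stats::dbinom(rep(cc, times = length(w)), nb,
                        rep(w, each = cmax))
    h <- -(cc / n_visits) * log(cc / n_visits)
    total <- total + sum(pr * rep(h, times = length(w)))
  }
  total
}

# Solve the Zipf destination pool: K destinations and exponent s such that
# the expected number of distinct destinations over n_visits matches n_uniq
# and the expected plug-in joint (destination x 6-h bin) entropy matches
# s_target. The two targets are not always jointly feasible (many distinct
# destinations force high plug-in entropy), so K is matched to the distinct
# count along a grid of exponents and the exponent minimising the combined
# squared relative error of both targets is taken, refined locally on the
# entropy residual where a root exists.
solve_destination_pool <- function(n_uniq, s_target, hours, n_visits) {
  n_uniq <- max(2, n_uniq)
  n_bins <- tabulate(pmin(floor(hours / 6), 3) + 1, nbins = 4)
  zipf_w <- function(K, s) { w <- (1:K)^(-s); w / sum(w) }
  e_distinct <- function(K, s) sum(1 - (1 - zipf_w(K, s))^n_visits)
  solve_K <- function(s) {
    K_hi <- 300
    if (e_distinct(K_hi, s) < n_uniq) return(K_hi)
    lo <- 2; hi <- K_hi
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (e_distinct(mid, s) >= n_uniq) hi <- mid else lo <- mid
    }
    hi
  }
  err <- function(s) {
    K <- solve_K(s)
    eH <- expected_plugin_entropy(zipf_w(K, s), n_bins, n_visits)
    eD <- e_distinct(K, s)
    (eH / s_target - 1)^2 + (eD / n_uniq - 1)^2
  }
  s_grid <- seq(0, 3, by = 0.2)
  errs <- vapply(s_grid, err, 0)
  s <- s_grid[which.min(errs)]
  # local refinement on the entropy residual, keeping K matched to s
  resid <- function(ss) expected_plugin_entropy(
    zipf_w(solve_K(ss), ss), n_bins, n_visits) - s_target
  lo <- max(0, s - 0.2); hi <- min(3, s + 0.2)
  if (resid(lo) > 0 && resid(hi) < 0)
    s <- uniroot(resid, c(lo, hi), tol = 1e-3)$root
  K <- solve_K(s)
  list(K = K, s = s, w = zipf_w(K, s))
}

# Place K destinations around home: uniform angles, Rayleigh radii, rescaled
# about the visit-weighted centre of mass so the expected-weight radius of
# gyration equals rg_km; a nudge pass keeps pairwise separation above 400 m
# so clustering at 150 m never merges distinct destinations.
place_destinations <- function(K, w, rg_km, home) {
  ang <- runif(K, 0, 2 * pi)
  r <- sqrt(-2 * log(runif(K)))
  x <- r * cos(ang); y <- r * sin(ang)
  cx <- sum(w * x); cy <- sum(w * y)
  rms <- sqrt(sum(w * ((x - cx)^2 + (y - cy)^2)))
  lambda <- rg_km / rms
  x <- cx + (x - cx) * lambda; y <- cy + (y - cy) * lambda
  if (K > 1) {
    for (pass in 1:3) {
      dmat <- as.matrix(stats::dist(cbind(x, y)))
      for (i in 1:(K - 1)) for (j in (i + 1):K) {
        if (dmat[i, j] < 0.4) {
          push <- (0.42 - dmat[i, j]) / 2
          dir <- atan2(y[j] - y[i], x[j] - x[i]) + runif(1, -0.3, 0.3)
          x[i] <- x[i] - push * cos(dir); y[i] <- y[i] - push * sin(dir)
          x[j] <- x[j] + push * cos(dir); y[j] <- y[j] + push * sin(dir)
        }
      }
    }
  }
  ll <- en_to_latlon(x, y, home["lat"], home["lon"])
  list(lat = ll$lat, lon = ll$lon)
}

# ---- kinematic dither ----------------------------------------------------

# Build one trip's speed/time series: zero boundary samples, a cruise at
# 30-s spacing, and 1-s dither bursts of amplitude delta. A fraction phi of
# the bursts are "double" (speed up at +1 s, back at +2 s: large jerk), the
# rest "single" (one elevated sample at +1 s: acceleration-dominated). Used
# by both calibration and realisation so the two cannot diverge.
dither_series <- function(n_base, cruise, delta, n_bt, phi, noise_sd = 0) {
  times <- seq(0, by = 30, length.out = n_base)
  noise <- if (noise_sd > 0) rnorm(n_base - 2, 0, noise_sd) else rep(0, n_base - 2)
  speeds <- c(0, pmax(cruise + noise, 0.6), 0)
  is_burst <- rep(FALSE, n_base)
  slots <- if (n_base >= 5) 3:(n_base - 2) else integer(0)
  n_b <- min(n_bt, length(slots))
  if (n_b > 0) {
    # floor of an evenly spaced sequence (spacing >= 1) is collision-free
    at <- slots[floor(seq(1, length(slots), length.out = n_b))]
    is_double <- rep(FALSE, length(at))
    n_y <- round(phi * length(at))
    if (n_y > 0)
      is_double[floor(seq(1, length(at), length.out = n_y))] <- TRUE
    ins_t <- c(); ins_v <- c()
    for (k in seq_along(at)) {
      t0 <- times[at[k]]; base_v <- speeds[at[k]]
      if (is_double[k]) {
        ins_t <- c(ins_t, t0 + 1, t0 + 2)
        ins_v <- c(ins_v, base_v + delta, base_v)
      } else {
        ins_t <- c(ins_t, t0 + 1)
        ins_v <- c(ins_v, base_v + delta)
      }
    }
    times <- c(times, ins_t); speeds <- c(speeds, ins_v)
    is_burst <- c(is_burst, rep(TRUE, length(ins_t)))
    ord <- order(times)
    times <- times[ord]; speeds <- speeds[ord]; is_burst <- is_burst[ord]
  }
  list(times = times, speeds = speeds, is_burst = is_burst,
       n_inserted = length(times) - n_base)
}

series_kin_means <- function(ser) {
  a <- diff(ser$speeds) / diff(ser$times)
  n <- length(ser$times)
  j <- if (n >= 3) diff(a) / ((ser$times[3:n] - ser$times[1:(n - 2)]) / 2) else 0
  c(mean_a = mean(abs(a)), mean_j = mean(abs(j)))
}

# Solve the dither mix (share of double bursts) and amplitude so that the
# mean-over-trips extracted |accel| and |jerk| hit the participant targets.
# The response in delta is affine (burst terms scale with delta, boundary
# ramps are constant), so each is characterised by a two-point evaluation,
# averaged over the participant's realised trip-length distribution.
calibrate_dither <- function(n_base_all, avg_v, avg_a, avg_j) {
  counts <- table(n_base_all)
  sizes <- as.integer(names(counts))
  wts <- as.numeric(counts) / sum(counts)
  if (length(sizes) > 12) {
    # bucket the size distribution to quantile representatives: the response
    # varies smoothly with trip length, so a coarse mix is sufficient
    qs <- quantile(n_base_all, probs = (seq_len(12) - 0.5) / 12, type = 1)
    sizes <- as.integer(qs)
    wts <- rep(1 / 12, 12)
  }
  rho_b <- 0.30
  for (attempt in 1:3) {
    resp <- function(phi, delta) {
      km <- vapply(sizes, function(nb)
        series_kin_means(dither_series(nb, avg_v, delta,
                                       max(0L, round(rho_b * (nb - 4))), phi)),
        c(mean_a = 0, mean_j = 0))
      c(a = sum(wts * km["mean_a", ]), j = sum(wts * km["mean_j", ]))
    }
    # for a given mix, the amplitude that delivers avg_a, and the jerk that
    # amplitude then produces
    solve_delta <- function(phi) {
      r1 <- resp(phi, 1); r2 <- resp(phi, 2)
      alpha <- r2[["a"]] - r1[["a"]]; a0 <- r1[["a"]] - alpha
      delta <- (avg_a - a0) / alpha
      delta <- min(max(delta, 0.5), 25)
      beta <- r2[["j"]] - r1[["j"]]; j0 <- r1[["j"]] - beta
      list(delta = delta, jerk = j0 + beta * delta)
    }
    g <- function(phi) solve_delta(phi)$jerk - avg_j
    phi <- if (g(0) >= 0) 0 else if (g(1) <= 0) 1
           else uniroot(g, c(0, 1), tol = 1e-3)$root
    sol <- solve_delta(phi)
    delta <- sol$delta
    if (delta < 25) break
    rho_b <- min(0.6, rho_b * 1.6)
  }
  list(delta = delta, phi = phi, rho_b = rho_b)
}

# ---- point-stream realisation -------------------------------------------

# Realise one trip as 30-s GPS samples (with 1-s dither bursts) ending
# exactly at the destination, with posted limits and device event flags.
build_trip_points <- function(start_time, dest_lat, dest_lon, d_km, prof,
                              over, under, n_hb, n_sa) {
  kin <- prof$kin
  avg_v <- prof$avg_v
  d_m <- d_km * 1000
  n_base <- max(6, round(d_m / (30 * avg_v)) + 2)
  n_bt <- max(0L, round(kin$rho_b * (n_base - 4)))
  slots_avail <- max(0, n_base - 4)
  n_ins <- min(n_bt, slots_avail)
  n_y <- round(kin$phi * n_ins)
  n_tot <- n_base + n_ins + n_y  # doubles insert two samples each

  # cruise level solved so the trip's mean sampled speed hits the target
  cruise <- (avg_v * n_tot - kin$delta * n_ins) / (n_tot - 2)
  cruise <- min(max(cruise, 1), 38)

  ser <- dither_series(n_base, cruise, kin$delta, n_bt, kin$phi, noise_sd = 0.15)
  times <- ser$times; speeds <- ser$speeds; is_burst <- ser$is_burst
  n <- length(times)

  # positions: steps proportional to leading speed, scaled to total d_m,
  # walked backwards along one geodesic so the last sample is the destination
  step <- speeds[-n] * diff(times)
  if (sum(step) <= 0) step <- rep(1, n - 1)
  cum <- c(0, cumsum(step)) * d_m / sum(step)
  bearing <- runif(1, 0, 360)
  pos <- dest_point(dest_lat, dest_lon, bearing, d_m - cum)

  # synthetic posted limits track each sample's own speed (no accidental
  # over/under-speed); one engineered episode per flagged trip
  limit <- speeds + 1.4
  cruise_idx <- which(!is_burst & speeds > 1)
  if (over && length(cruise_idx) >= 1) {
    i <- cruise_idx[1]
    if (speeds[i] - 6 * MPH_TO_MPS - 0.5 > 0.3)
      limit[i] <- speeds[i] - 6 * MPH_TO_MPS - 0.5
  }
  if (under && length(cruise_idx) >= 2) {
    i <- cruise_idx[2]
    limit[i] <- speeds[i] + 6 * MPH_TO_MPS + 0.6
  }

  flag <- rep("none", n)
  avail <- setdiff(which(!is_burst), c(1, n))
  n_hb <- min(n_hb, length(avail))
  if (n_hb > 0) {
    pick <- avail[seq_len(n_hb)]
    flag[pick] <- "hard_brake"
    avail <- setdiff(avail, pick)
  }
  n_sa <- min(n_sa, length(avail))
  if (n_sa > 0) flag[avail[seq_len(n_sa)]] <- "sudden_accel"

  list(timestamp = start_time + times, lat = pos$lat, lon = pos$lon,
       speed = speeds, posted_limit = limit, event_flag = flag)
}

#' Realise one participant-month as a GPS point stream
#'
#' Generates the 30-second GPS samples for every planned trip of `profile`
#' in calendar month index `month` (1-based within the study window).
#' Randomness is drawn from the current RNG stream; [simulate_study()] seeds
#' it once for the whole study.
#'
#' @param profile One element of `sample_cohort()$profiles`.
#' @param month Month index within the study window.
#' @return A `data.table` of GPS points (possibly empty), in the `drv_log`
#'   column layout.
#' @export
synthesize_month_log <- function(profile, month) {
  keep <- profile$plan$month == month  # plain vector: avoid column capture
  plan <- profile$plan[keep, ]
  if (nrow(plan) == 0L) return(empty_log()[, !"participant_id"])
  pieces <- lapply(seq_len(nrow(plan)), function(i)
    build_trip_points(plan$start[i],
                      profile$dest_lat[plan$dest[i]],
                      profile$dest_lon[plan$dest[i]],
                      plan$distance_km[i], profile,
                      plan$over[i], plan$under[i],
                      plan$n_hb[i], plan$n_sa[i]))
  data.table::data.table(
    timestamp = do.call(c, lapply(pieces, `[[`, "timestamp")),
    lat = unlist(lapply(pieces, `[[`, "lat")),
    lon = unlist(lapply(pieces, `[[`, "lon")),
    speed = unlist(lapply(pieces, `[[`, "speed")),
    posted_limit = unlist(lapply(pieces, `[[`, "posted_limit")),
    event_flag = unlist(lapply(pieces, `[[`, "event_flag"))
  )
}

#' Simulate a full study in memory
#'
#' Samples the cohort and realises every participant-month as GPS points.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed covering cohort sampling and point realisation.
#' @return List with `log` (a `drv_log` point table), `meta` (participant
#'   metadata) and `profiles`.
#' @export
simulate_study <- function(spec = cohort_spec(), seed = 1) {
  cohort <- sample_cohort(spec, seed = seed)
  logs <- lapply(cohort$profiles, function(prof) {
    months_present <- sort(unique(prof$plan$month))
    dt <- data.table::rbindlist(lapply(months_present, function(m)
      synthesize_month_log(prof, m)))
    dt[, participant_id := prof$participant_id]
    dt
  })
  log <- data.table::rbindlist(logs)
  data.table::setcolorder(log, c("participant_id", "timestamp"))
  data.table::setorder(log, participant_id, timestamp)
  data.table::setattr(log, "class", c("drv_log", class(log)))
  list(log = log[], meta = cohort$meta, profiles = cohort$profiles)
}

#' Generate a study directory on disk
#'
#' Writes `gps_log.csv` (canonical GPS schema, speeds m/s), `participants.csv`
#' and `manifest.json` (seed, spec echo, generator version). Byte-identical
#' for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return `out_dir`, invisibly.
#' @export
generate_study <- function(spec = cohort_spec(), out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(spec, seed = seed)
  write_gps_log(sim$log, file.path(out_dir, "gps_log.csv"), speed_unit = "mps")
  data.table::fwrite(sim$meta, file.path(out_dir, "participants.csv"))
  manifest <- list(
    generator = "drivemarkers",
    version = as.character(utils::packageVersion("drivemarkers")),
    seed = seed,
    n_without = spec$n_without, n_with = spec$n_with,
    months = spec$months, start_date = as.character(spec$start_date),
    tz = spec$tz, rho = spec$rho, csf_threshold = spec$csf_threshold,
    n_points = nrow(sim$log), n_participants = nrow(sim$meta),
    files = c("gps_log.csv", "participants.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
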