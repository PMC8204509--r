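#' Label preclinical Alzheimer disease from the CSF amyloid ratio
#'
#' A participant is labelled preclinical AD (1) when their CSF
#' A\eqn{\beta}42/A\eqn{\beta}40 ratio is strictly below the threshold, a
#' cutpoint highly concordant with amyloid-PET positivity; otherwise 0.
#' Missing ratios yield `NA` (unlabeled; excluded from modelling).
#'
#' @param csf_ratio Numeric vector of CSF A\eqn{\beta}42/A\eqn{\beta}40 ratios.
#' @param threshold Positivity cutpoint (default 0.0673), strict inequality.
#' @return Integer vector in `{0, 1, NA}`.
#' @export
label_preclinical <- function(csf_ratio, threshold = 0.0673) {
  out <- ifelse(csf_ratio < threshold, 1L, 0L)
  n_missing <- sum(is.na(csf_ratio))
  if (n_missing > 0)
    message(n_missing, " participant(s) unlabeled (missing csf_ratio)")
  out
}

#' Monthly driving feature records
#'
#' Segments and annotates the full log with [build_trips()], assigns every
#' trip to the local calendar month of its start time, and computes all
#' driving-space and driving-performance indicators per participant-month
#' (destination clustering and entropy within-month). These participant-month
#' records are the classification data points. Months with zero trips are
#' simply absent.
#'
#' @param log A `drv_log` table.
#' @param meta Participant metadata ([read_participant_meta()]); labels are
#'   derived from `csf_ratio` via [label_preclinical()].
#' @param config Named list of extraction settings: trip filters (see
#'   [build_trips()]) plus `tz` (default `"America/Chicago"`), `radius_m`,
#'   `time_bins`, `night_mode`, `csf_threshold`.
#' @return A `data.table` with one row per participant-month: `participant_id`,
#'   `month` ("YYYY-MM"), the 12 space columns, the 7 performance columns,
#'   `age`, `apoe_e4`, `label`.
#' @export
monthly_features <- function(log, meta, config = list()) {
  tz <- config$tz %||% "America/Chicago"
  x <- build_trips(log, config)
  tr <- x$trips
  if (nrow(tr) == 0L) stop("no trips after segmentation")
  tr$month <- format(tr$start, "%Y-%m", tz = tz)
  groups <- split(seq_len(nrow(tr)), paste(tr$participant_id, tr$month))
  rows <- lapply(groups, function(idx) {
    sub <- tr[idx]
    cbind(
      data.table::data.table(participant_id = sub$participant_id[1L],
                             month = sub$month[1L]),
      window_indicators(sub, config)
    )
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, participant_id, month)
  join_meta(out, meta, config)
}

#' Study-period driving feature records
#'
#' As [monthly_features()] but aggregated over the whole log per participant:
#' one row per participant, with destination clustering, radius of gyration
#' and entropy computed over the entire period. This is the aggregation at
#' which cohort descriptive statistics are reported.
#'
#' @inheritParams monthly_features
#' @return A `data.table`, one row per participant.
#' @export
period_features <- function(log, meta, config = list()) {
  x <- build_trips(log, config)
  tr <- x$trips
  if (nrow(tr) == 0L) stop("no trips after segmentation")
  groups <- split(seq_len(nrow(tr)), tr$participant_id)
  rows <- lapply(groups, function(idx) {
    sub <- tr[idx]
    cbind(data.table::data.table(participant_id = sub$participant_id[1L]),
          window_indicators(sub, config))
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, participant_id)
  join_meta(out, meta, config)
}

window_indicators <- function(sub, config) {
  cbind(
    compute_space_indicators(sub,
      tz = config$tz %||% "America/Chicago",
      radius_m = config$radius_m %||% 150,
      time_bins = config$time_bins %||% 4,
      night_mode = config$night_mode %||% "extended")[, !"empty"],
    compute_performance_indicators(sub)[, !"empty"]
  )
}

join_meta <- function(out, meta, config) {
  m <- data.table::as.data.table(meta)[, .(
    participant_id, age, apoe_e4,
    label = label_preclinical(csf_ratio, config$csf_threshold %||% 0.0673))]
  out <- m[out, on = "participant_id"]
  missing <- setdiff(m$participant_id, out$participant_id)
  if (length(missing))
    warning(length(missing), " participant(s) with no driving months excluded")
  out[]
}

#' Cohen's d with pooled standard deviation
#'
#' \deqn{d = \frac{\bar x_1 - \bar x_2}
#'   {\sqrt{((n_1 - 1) s_1^2 + (n_2 - 1) s_2^2) / (n_1 + n_2 - 2)}}}
#' Group 1 is conventionally the group without preclinical AD, so positive
#' values mean larger indicator values in unaffected drivers. Antisymmetric
#' under group swap. Vectorised.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Effect size(s) d (dimensionless).
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(n1 < 2 | n2 < 2)) stop("both groups need n >= 2")
  if (any(sd1 <= 0 | sd2 <= 0)) stop("both group SDs must be positive")
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / pooled
}

#' Per-indicator group descriptives and effect sizes
#'
#' For each of the 14 driving indicators, the mean, SD and n per label group
#' over per-participant study-period values, plus Cohen's d with the
#' convention d = (without - with preclinical AD) / pooled SD.
#'
#' @param features Per-participant feature table ([period_features()]) with a
#'   `label` column in `{0, 1}` (NA labels are dropped).
#' @return A `data.table` with one row per indicator: `indicator`,
#'   `mean_noad`, `sd_noad`, `n_noad`, `mean_ad`, `sd_ad`, `n_ad`, `cohens_d`.
#' @export
indicator_group_stats <- function(features) {
  f <- data.table::as.data.table(features)[!is.na(label)]
  if (length(unique(f$label)) < 2L) stop("both label groups must be non-empty")
  rows <- lapply(indicator_names(), function(ind) {
    v0 <- f[label == 0L][[ind]]; v1 <- f[label == 1L][[ind]]
    v0 <- v0[!is.na(v0)]; v1 <- v1[!is.na(v1)]
    data.table::data.table(
      indicator = ind,
      mean_noad = mean(v0), sd_noad = sd(v0), n_noad = length(v0),
      mean_ad = mean(v1), sd_ad = sd(v1), n_ad = length(v1),
      cohens_d = cohens_d(mean(v0), sd(v0), length(v0),
                          mean(v1), sd(v1), length(v1))
    )
  })
  data.table::rbindlist(rows)
}
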