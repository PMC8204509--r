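#' Published per-group indicator descriptive statistics
#'
#' The shipped table of group means, SDs, group sizes and printed Cohen's d
#' values for the 14 driving indicators (without vs with preclinical AD),
#' used both as simulator calibration targets and as inputs for effect-size
#' reproduction.
#'
#' @return A `data.table` with columns `indicator`, `mean_noad`, `sd_noad`,
#'   `n_noad`, `mean_ad`, `sd_ad`, `n_ad`, `printed_d`.
#' @export
published_group_stats <- function() {
  data.table::fread(system.file("extdata", "indicator_group_stats.csv",
                                package = "drivemarkers"))
}

#' Pipeline stage: simulate a study to disk
#'
#' Thin orchestration wrapper over [generate_study()].
#'
#' @param out_dir Output directory.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return `out_dir`, invisibly.
#' @export
pipeline_simulate <- function(out_dir, spec = cohort_spec(), seed = 1) {
  generate_study(spec, out_dir, seed = seed)
}

#' Pipeline stage: extract monthly feature records
#'
#' Reads a GPS log and participant metadata, extracts participant-month
#' indicator records and writes them as `monthly_features.csv`.
#'
#' @param log_path,meta_path Input CSVs (canonical schemas).
#' @param out_dir Output directory.
#' @param config Extraction configuration ([monthly_features()]); may include
#'   `speed_unit` for the log and `window` (`c(from, to)` dates, trips
#'   starting outside are dropped).
#' @return The feature `data.table`, invisibly.
#' @export
pipeline_extract <- function(log_path, meta_path, out_dir, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- read_gps_log(log_path, speed_unit = config$speed_unit %||% "mps")
  meta <- read_participant_meta(meta_path)
  if (!is.null(config$window)) {
    w <- as.POSIXct(paste(config$window, c("00:00:00", "23:59:59")),
                    tz = config$tz %||% "America/Chicago")
    attr(w, "tzone") <- "UTC"  # compare on the absolute timeline, quietly
    log <- log[log$timestamp >= w[1] & log$timestamp <= w[2], ]
  }
  feats <- monthly_features(log, meta, config)
  data.table::fwrite(feats, file.path(out_dir, "monthly_features.csv"))
  invisible(feats)
}

#' Pipeline stage: cohort descriptives
#'
#' Computes per-participant study-period indicators and the per-indicator
#' group descriptives / Cohen's d table; writes `group_stats.csv`.
#'
#' @inheritParams pipeline_extract
#' @return The group-statistics `data.table`, invisibly.
#' @export
pipeline_describe <- function(log_path, meta_path, out_dir, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- read_gps_log(log_path, speed_unit = config$speed_unit %||% "mps")
  meta <- read_participant_meta(meta_path)
  feats <- period_features(log, meta, config)
  stats <- indicator_group_stats(feats)
  data.table::fwrite(stats, file.path(out_dir, "group_stats.csv"))
  invisible(stats)
}

#' Pipeline stage: fit and evaluate the four models
#'
#' Reads a monthly feature CSV, fits the four input-variable-set models on a
#' shared split ([run_four_models()]), and writes the JSON evaluation report,
#' per-model ROC point CSVs and the ranked importance table of the full
#' model.
#'
#' @param features_path Monthly feature CSV (from [pipeline_extract()]).
#' @param out_dir Output directory.
#' @param seed,split_mode,n_boot,tuning_grid Passed to [run_four_models()].
#' @return The `drf_suite`, invisibly.
#' @export
pipeline_model <- function(features_path, out_dir, seed = 1,
                           split_mode = "record", n_boot = 1000,
                           tuning_grid = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- data.table::fread(features_path)
  suite <- run_four_models(records, base_seed = seed, split_mode = split_mode,
                           n_boot = n_boot, tuning_grid = tuning_grid)
  write_eval_json(suite, file.path(out_dir, "model_reports.json"))
  for (nm in names(suite))
    data.table::fwrite(suite[[nm]]$eval$roc,
                       file.path(out_dir, paste0("roc_", nm, ".csv")))
  data.table::fwrite(suite$driving_age_apoe$importance,
                     file.path(out_dir, "importance_driving_age_apoe.csv"))
  invisible(suite)
}
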