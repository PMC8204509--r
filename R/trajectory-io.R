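#' Read a GPS driving log
#'
#' Parses the canonical CSV schema for 30-second in-vehicle GPS logs:
#' required columns `participant_id`, `timestamp_utc` (ISO-8601, UTC),
#' `lat`, `lon`, `speed`; optional `posted_limit` and `event_flag`
#' (`none` / `hard_brake` / `sudden_accel`). Speeds (and posted limits) are
#' converted to the internal unit, metres per second, according to
#' `speed_unit`. Rows are sorted by participant and timestamp; duplicate
#' `(participant, timestamp)` rows are collapsed to the first occurrence with
#' a warning.
#'
#' @param path Path to the CSV file.
#' @param speed_unit Unit the file's `speed`/`posted_limit` columns are
#'   recorded in: `"mps"`, `"mph"` or `"kph"`.
#' @return A `data.table` of class `drv_log` with one row per GPS point:
#'   `participant_id` (character), `timestamp` (POSIXct, UTC), `lat`, `lon`,
#'   `speed` (m/s), `posted_limit` (m/s or `NA`), `event_flag` (character or
#'   `NA`).
#' @export
read_gps_log <- function(path, speed_unit = c("mps", "mph", "kph")) {
  speed_unit <- match.arg(speed_unit)
  if (!file.exists(path)) stop("GPS log not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"),
                          na.strings = c("", "NA"))
  required <- c("participant_id", "timestamp_utc", "lat", "lon", "speed")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("GPS log is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(dt) == 0L) return(empty_log())

  ts <- as.POSIXct(dt$timestamp_utc, tz = "UTC", optional = TRUE,
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  bad <- which(is.na(ts))
  if (length(bad))
    stop("unparseable timestamp at data row(s): ",
         paste(head(bad, 5), collapse = ", "))
  lat <- as.numeric(dt$lat); lon <- as.numeric(dt$lon)
  bad <- which(is.na(lat) | is.na(lon))
  if (length(bad))
    stop("unparseable coordinate at data row(s): ",
         paste(head(bad, 5), collapse = ", "))
  oob <- which(abs(lat) > 90 | abs(lon) > 180)
  if (length(oob))
    stop("latitude/longitude out of bounds at data row(s): ",
         paste(head(oob, 5), collapse = ", "))
  speed <- as.numeric(dt$speed)
  if (any(is.na(speed) | speed < 0))
    stop("speed must be present and non-negative for every row")

  conv <- switch(speed_unit, mps = 1, mph = MPH_TO_MPS, kph = 1 / 3.6)
  out <- data.table::data.table(
    participant_id = as.character(dt$participant_id),
    timestamp = ts, lat = lat, lon = lon, speed = speed * conv,
    posted_limit = if ("posted_limit" %in% names(dt))
      as.numeric(dt$posted_limit) * conv else NA_real_,
    event_flag = if ("event_flag" %in% names(dt))
      as.character(dt$event_flag) else NA_character_
  )
  flags <- out$event_flag
  bad_flag <- !is.na(flags) & !flags %in% c("none", "hard_brake", "sudden_accel")
  if (any(bad_flag))
    stop("invalid event_flag value(s): ",
         paste(unique(flags[bad_flag]), collapse = ", "))

  data.table::setorder(out, participant_id, timestamp)
  dup <- duplicated(out, by = c("participant_id", "timestamp"))
  if (any(dup)) {
    warning(sum(dup), " duplicate (participant, timestamp) row(s) collapsed",
            " to first occurrence")
    out <- out[!dup]
  }
  data.table::setattr(out, "class", c("drv_log", class(out)))
  out[]
}

empty_log <- function() {
  out <- data.table::data.table(
    participant_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    lat = numeric(), lon = numeric(), speed = numeric(),
    posted_limit = numeric(), event_flag = character()
  )
  data.table::setattr(out, "class", c("drv_log", class(out)))
  out
}

#' Write a GPS driving log
#'
#' Inverse of [read_gps_log()]: writes the canonical CSV schema with speeds in
#' the requested unit and ISO-8601 UTC timestamps. A read of the written file
#' reproduces every field (timestamps exactly, to 1-second resolution).
#'
#' @param log A `drv_log` table as returned by [read_gps_log()] (speeds m/s).
#' @param path Output CSV path.
#' @param speed_unit Unit to write speeds in (declared back to [read_gps_log()]).
#' @return `path`, invisibly.
#' @export
write_gps_log <- function(log, path, speed_unit = c("mps", "mph", "kph")) {
  speed_unit <- match.arg(speed_unit)
  conv <- switch(speed_unit, mps = 1, mph = MPH_TO_MPS, kph = 1 / 3.6)
  out <- data.table::data.table(
    participant_id = log$participant_id,
    timestamp_utc = format(log$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lat = log$lat, lon = log$lon,
    speed = log$speed / conv,
    posted_limit = log$posted_limit / conv,
    event_flag = log$event_flag
  )
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read participant metadata
#'
#' Parses the participant table: required columns `participant_id`, `age`,
#' `apoe_e4`; optional `csf_ratio` (CSF A\eqn{\beta}42/A\eqn{\beta}40),
#' `sex`, `race`, `education_years`. APOE carrier status is normalised from
#' `{0, 1, true, false, yes, no}`. Participants without a CSF ratio are
#' retained but flagged `unlabeled` (they are excluded from modelling).
#'
#' @param path Path to the CSV file.
#' @return A `data.table`, one row per participant, with `unlabeled` logical
#'   column.
#' @export
read_participant_meta <- function(path) {
  if (!file.exists(path)) stop("participant metadata not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"),
                          na.strings = c("", "NA"))
  required <- c("participant_id", "age", "apoe_e4")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(dt$participant_id))
    stop("duplicate participant_id in metadata")
  age <- as.numeric(dt$age)
  if (any(is.na(age))) stop("unparseable age")
  if (any(age < 65))
    stop("age below 65 violates the cohort inclusion criterion (age >= 65): ",
         paste(dt$participant_id[age < 65], collapse = ", "))
  out <- data.table::data.table(
    participant_id = as.character(dt$participant_id),
    age = age,
    apoe_e4 = normalize_bool(dt$apoe_e4),
    csf_ratio = if ("csf_ratio" %in% names(dt)) as.numeric(dt$csf_ratio)
                else NA_real_
  )
  if (any(!is.na(out$csf_ratio) & out$csf_ratio <= 0))
    stop("csf_ratio must be positive")
  for (col in c("sex", "race", "education_years"))
    if (col %in% names(dt)) out[[col]] <- dt[[col]]
  out$unlabeled <- is.na(out$csf_ratio)
  if (any(out$unlabeled))
    message(sum(out$unlabeled), " participant(s) without csf_ratio retained as unlabeled")
  out[]
}

normalize_bool <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "yes", "t")] <- TRUE
  out[x %in% c("0", "false", "no", "f")] <- FALSE
  if (any(is.na(out) & !x %in% c("na", "")))
    stop("unrecognised boolean value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}
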