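#' Sunrise and sunset times (NOAA solar position algorithm)
#'
#' Computes apparent sunrise and sunset (solar zenith 90.833 degrees, i.e.
#' refraction-corrected upper-limb crossing) for a calendar date and location,
#' using the NOAA low-accuracy solar equations (Fourier expansion of the
#' equation of time and solar declination in the fractional year). Accuracy is
#' within a few minutes of published almanac values for mid-latitudes, which
#' is ample for classifying trips as night driving.
#'
#' @param date A `Date` (or string coercible to one); vectorised.
#' @param lat,lon Location in decimal degrees; `|lat|` must be below 66.5
#'   (polar day/night is not handled).
#' @return A list with POSIXct elements `sunrise` and `sunset` in UTC.
#'   Sunset may fall on the following UTC day for western longitudes.
#' @examples
#' sun_times_utc(as.Date("2019-06-21"), 38.627, -90.199)$sunset # ~01:29 UTC
#' @export
sun_times_utc <- function(date, lat, lon) {
  date <- as.Date(date)
  if (any(abs(lat) >= 66.5))
    stop("polar latitudes (|lat| >= 66.5) are unsupported")
  n <- max(length(date), length(lat), length(lon))
  date <- rep_len(date, n); lat <- rep_len(lat, n); lon <- rep_len(lon, n)

  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  yr <- as.integer(strftime(date, "%Y", tz = "UTC"))
  ydays <- ifelse((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0, 366, 365)
  g <- 2 * pi / ydays * (doy - 1 + 0.5)  # fractional year, radians, at solar noon

  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                      0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
          0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
          0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)

  rad <- pi / 180
  cos_ha <- cos(90.833 * rad) / (cos(lat * rad) * cos(decl)) -
            tan(lat * rad) * tan(decl)
  cos_ha <- pmin(1, pmax(-1, cos_ha))
  ha_deg <- acos(cos_ha) / rad

  # minutes after 00:00 UTC
  sunrise_min <- 720 - 4 * (lon + ha_deg) - eqtime
  sunset_min <- 720 - 4 * (lon - ha_deg) - eqtime

  day0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  list(sunrise = day0 + sunrise_min * 60, sunset = day0 + sunset_min * 60)
}

#' Classify instants as night driving times
#'
#' `TRUE` when the instant falls after its local date's sunset or before its
#' sunrise (the default "extended" night rule), or strictly after sunset only
#' (`mode = "after_sunset"`). Vectorised.
#'
#' @param time_utc POSIXct instants (UTC).
#' @param lat,lon Location in decimal degrees.
#' @param tz IANA timezone that defines the local date.
#' @param mode Night rule.
#' @return Logical vector.
#' @export
is_night <- function(time_utc, lat, lon, tz, mode = c("extended", "after_sunset")) {
  mode <- match.arg(mode)
  local_date <- as.Date(format(time_utc, tz = tz, format = "%Y-%m-%d"))
  attr(time_utc, "tzone") <- "UTC"  # compare absolute instants quietly
  st <- sun_times_utc(local_date, lat, lon)
  after_sunset <- time_utc > st$sunset
  # western longitudes: this local date's sunset can land on the next UTC day;
  # the comparison in UTC is still correct because both instants are absolute
  if (mode == "extended") after_sunset | (time_utc < st$sunrise) else after_sunset
}
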