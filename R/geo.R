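#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorised over coordinates; inputs are recycled.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1) # ~111.195 km along the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE))
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

# Project lat/lon (degrees) to a local east-north tangent plane (km) centred
# at (lat0, lon0). Equirectangular with cos(lat0) scaling: adequate for the
# metro-scale extents this package handles.
local_en_km <- function(lat, lon, lat0, lon0) {
  rad <- pi / 180
  cbind(
    x = EARTH_RADIUS_KM * cos(lat0 * rad) * (lon - lon0) * rad,
    y = EARTH_RADIUS_KM * (lat - lat0) * rad
  )
}

# Inverse of local_en_km
en_to_latlon <- function(x, y, lat0, lon0) {
  rad <- pi / 180
  list(
    lat = lat0 + (y / EARTH_RADIUS_KM) / rad,
    lon = lon0 + (x / (EARTH_RADIUS_KM * cos(lat0 * rad))) / rad
  )
}

# Point at distance_m metres from (lat, lon) along bearing (deg clockwise from
# north), on the same sphere used by haversine_km.
dest_point <- function(lat, lon, bearing, distance_m) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing, distance_m,
                            r = EARTH_RADIUS_KM * 1000)
  list(lat = p[, 2], lon = p[, 1])
}
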