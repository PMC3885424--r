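#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km, the convention used for
#' all "linear distance" summaries in the package. Vectorised and recycled
#' over its arguments.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (WGS84).
#' @return numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1)  # one degree of arc, ~111.19 km
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  if (any(abs(p1[, 2]) > 90, na.rm = TRUE) || any(abs(p2[, 2]) > 90, na.rm = TRUE))
    stop_ct("latitude out of range in haversine_km")
  geosphere::distHaversine(p1, p2, r = 6371) # r in km -> km out
}

# Local tangent-plane (equirectangular) conversion used by the simulator and
# the 3D KUD projection. Exact inverse of km_to_lonlat at any distance; the
# small-angle distortion relative to the sphere is what limits accuracy, and
# stays below 0.1% within a few hundred km of the origin at tropical
# latitudes.
lonlat_to_km <- function(lon, lat, origin) {
  cbind(x = (lon - origin[1]) * KM_PER_DEG * cos(origin[2] * pi / 180),
        y = (lat - origin[2]) * KM_PER_DEG)
}

km_to_lonlat <- function(x, y, origin) {
  cbind(lon = origin[1] + x / (KM_PER_DEG * cos(origin[2] * pi / 180)),
        lat = origin[2] + y / KM_PER_DEG)
}
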