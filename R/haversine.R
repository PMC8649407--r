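#' Great-circle distance between coordinate pairs (haversine formula)
#'
#' Computes the haversine great-circle distance on a sphere of radius
#' `earth_radius_km`. The haversine form is numerically stable for the
#' short distances typical of cell-to-cell geometry, where the spherical
#' law of cosines loses precision. All arguments are vectorized and
#' recycled.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees; latitudes in
#'   \[-90, 90\], longitudes in \[-180, 180\].
#' @param earth_radius_km Sphere radius in kilometres (default 6371.0).
#' @return Numeric vector of distances in kilometres.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 90)              # quarter great circle
#' haversine_km(48.2, 16.37, 48.21, 16.4) # a short hop in Vienna
haversine_km <- function(lat1, lon1, lat2, lon2, earth_radius_km = 6371.0) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  if (!is.numeric(earth_radius_km) || length(earth_radius_km) != 1L ||
      is.na(earth_radius_km) || earth_radius_km <= 0) {
    stop("earth_radius_km must be a single positive number", call. = FALSE)
  }
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * earth_radius_km * asin(pmin(1, sqrt(a)))
}

check_coords <- function(lat, lon) {
  if (anyNA(lat) || anyNA(lon)) {
    stop("coordinates must not contain NA", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude out of [-90, 90]", call. = FALSE)
  }
  if (any(lon < -180 | lon > 180)) {
    stop("longitude out of [-180, 180]", call. = FALSE)
  }
  invisible(TRUE)
}
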