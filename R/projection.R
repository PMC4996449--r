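#' Azimuthal equidistant projection for a radar case
#'
#' All field reconstruction, particle tracing and lattice construction in
#' radarflow happen in a planar coordinate system measured in kilometres.
#' The plane is an azimuthal equidistant projection on a sphere
#' (radius 6371.0088 km), centred by default on the centroid of the case's
#' radar sites, so distances from the centre are true great-circle distances
#' and the layout is resolution independent. Conversion to screen pixels, if
#' any, happens only at render time.
#'
#' @param lon,lat Numeric vectors of geographic coordinates, degrees.
#' @param center Length-2 numeric `c(lon, lat)` of the projection origin.
#' @return For `project_aeqd()`, a tibble with columns `x`, `y` (km east and
#'   north of the origin). For `unproject_aeqd()`, a tibble with columns
#'   `lon`, `lat` (degrees).
#' @examples
#' project_aeqd(5, 52.5, center = c(5, 51.5)) # ~111.2 km due north
#' @export
project_aeqd <- function(lon, lat, center) {
  stopifnot(length(center) == 2, is.finite(center))
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  # k -> 1 as c -> 0
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- .earth_radius_km * k * cos(phi) * sin(lam - lam0)
  y <- .earth_radius_km * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  tibble::tibble(x = x, y = y)
}

#' @rdname project_aeqd
#' @param x,y Numeric vectors of projected coordinates, km.
#' @export
unproject_aeqd <- function(x, y, center) {
  stopifnot(length(center) == 2, is.finite(center))
  lam0 <- center[1] * pi / 180
  phi0 <- center[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / .earth_radius_km
  sinc <- sin(c_ang)
  cosc <- cos(c_ang)
  phi <- ifelse(
    rho < 1e-12, phi0,
    asin(pmin(1, pmax(-1, cosc * sin(phi0) + y * sinc * cos(phi0) / rho)))
  )
  lam <- ifelse(
    rho < 1e-12, lam0,
    lam0 + atan2(x * sinc, rho * cos(phi0) * cosc - y * sin(phi0) * sinc)
  )
  tibble::tibble(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

.earth_radius_km <- 6371.0088

#' Centroid of a set of radar sites
#'
#' The default projection origin of a case: the arithmetic mean of the site
#' longitudes and latitudes. Adequate for the sub-continental extents of
#' weather-radar networks.
#'
#' @param sites Tibble with `lon` and `lat` columns (degrees), e.g. from
#'   [read_radar_sites()].
#' @return Length-2 numeric `c(lon, lat)`.
#' @export
site_centroid <- function(sites) {
  stopifnot(all(c("lon", "lat") %in% names(sites)), nrow(sites) >= 1)
  c(mean(sites$lon), mean(sites$lat))
}

#' Project radar sites into the case plane
#'
#' @param sites Tibble of radar sites (`radar_id`, `name`, `lon`, `lat`).
#' @param center Projection origin `c(lon, lat)`; defaults to the site
#'   centroid.
#' @return The input tibble with `x` and `y` columns (km) appended.
#' @export
project_sites <- function(sites, center = site_centroid(sites)) {
  xy <- project_aeqd(sites$lon, sites$lat, center)
  out <- dplyr::mutate(sites, x = xy$x, y = xy$y)
  attr(out, "center") <- center
  out
}
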