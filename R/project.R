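# Transverse-Mercator (UTM) projection on the WGS84 ellipsoid, implemented
# with the Krueger series in the transformed (Karney) form: forward/inverse
# accurate to well below a millimetre within a UTM zone, ample for
# walking-scale grids. Series coefficients in the third flattening n.

.wgs84 <- local({
  a <- 6378137
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  list(
    a = a, f = f, n = n,
    e = sqrt(f * (2 - f)),
    A = a / (1 + n) * (1 + n^2 / 4 + n^4 / 64 + n^6 / 256),
    alpha = c(
      n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180 -
        127 * n^5 / 288 + 7891 * n^6 / 37800,
      13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440 + 281 * n^5 / 630 -
        1983433 * n^6 / 1935360,
      61 * n^3 / 240 - 103 * n^4 / 140 + 15061 * n^5 / 26880 +
        167603 * n^6 / 181440,
      49561 * n^4 / 161280 - 179 * n^5 / 168 + 6601661 * n^6 / 7257600,
      34729 * n^5 / 80640 - 3418889 * n^6 / 1995840,
      212378941 * n^6 / 319334400),
    beta = c(
      n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360 - 81 * n^5 / 512 +
        96199 * n^6 / 604800,
      n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440 + 46 * n^5 / 105 -
        1118711 * n^6 / 3870720,
      17 * n^3 / 480 - 37 * n^4 / 840 - 209 * n^5 / 4480 +
        5569 * n^6 / 90720,
      4397 * n^4 / 161280 - 11 * n^5 / 504 - 830251 * n^6 / 7257600,
      4583 * n^5 / 161280 - 108847 * n^6 / 3991680,
      20648693 * n^6 / 638668800),
    k0 = 0.9996)
})

#' UTM zone of a point
#'
#' @param lon,lat Coordinates in degrees.
#' @return List with `zone` (1--60), `hemisphere` (`"N"`/`"S"`) and the
#'   `epsg` code of the zone CRS.
#' @export
utm_zone <- function(lon, lat) {
  zone <- floor((lon + 180) / 6) %% 60 + 1
  hemi <- ifelse(lat >= 0, "N", "S")
  list(zone = as.integer(zone), hemisphere = hemi,
       epsg = as.integer(ifelse(lat >= 0, 32600, 32700) + zone))
}

# conformal-latitude tangent
.tau_conf <- function(phi) {
  e <- .wgs84$e
  sinh(asinh(tan(phi)) - e * atanh(e * sin(phi)))
}

#' Project geographic coordinates to UTM
#'
#' Forward transverse-Mercator projection (WGS84) into the given UTM zone:
#' easting/northing in metres with the standard 500 km false easting,
#' 10,000 km false northing in the southern hemisphere, and central scale
#' factor 0.9996.
#'
#' @param lon,lat Coordinates in degrees (vectors).
#' @param zone UTM zone number (default: zone of the centroid).
#' @param hemisphere `"N"` or `"S"` (default: from the centroid latitude).
#' @return Data frame with `x` (easting), `y` (northing), and attributes
#'   `zone`, `hemisphere`.
#' @export
project_utm <- function(lon, lat, zone = NULL, hemisphere = NULL) {
  if (is.null(zone) || is.null(hemisphere)) {
    z <- utm_zone(mean(lon), mean(lat))
    if (is.null(zone)) zone <- z$zone
    if (is.null(hemisphere)) hemisphere <- z$hemisphere
  }
  lon0 <- (zone - 1) * 6 - 180 + 3
  phi <- lat * pi / 180
  lam <- (lon - lon0) * pi / 180
  tau <- .tau_conf(phi)
  xi_p <- atan2(tau, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(tau^2 + cos(lam)^2))
  xi <- xi_p; eta <- eta_p
  for (j in 1:6) {
    xi <- xi + .wgs84$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + .wgs84$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  x <- 500000 + .wgs84$k0 * .wgs84$A * eta
  y <- .wgs84$k0 * .wgs84$A * xi
  if (identical(hemisphere, "S")) y <- y + 1e7
  out <- data.frame(x = x, y = y)
  attr(out, "zone") <- zone
  attr(out, "hemisphere") <- hemisphere
  out
}

#' Inverse UTM projection
#'
#' @param x,y Easting/northing in metres.
#' @param zone UTM zone number.
#' @param hemisphere `"N"` or `"S"`.
#' @return Data frame with `lon`, `lat` in degrees.
#' @export
unproject_utm <- function(x, y, zone, hemisphere = "N") {
  lon0 <- (zone - 1) * 6 - 180 + 3
  if (identical(hemisphere, "S")) y <- y - 1e7
  xi <- y / (.wgs84$k0 * .wgs84$A)
  eta <- (x - 500000) / (.wgs84$k0 * .wgs84$A)
  xi_p <- xi; eta_p <- eta
  for (j in 1:6) {
    xi_p <- xi_p - .wgs84$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - .wgs84$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  tau_p <- sin(xi_p) / sqrt(sinh(eta_p)^2 + cos(xi_p)^2)
  lam <- atan2(sinh(eta_p), cos(xi_p))
  # invert the conformal latitude by Newton iteration on tan(phi)
  phi <- atan(tau_p)
  for (k in 1:8) {
    tc <- .tau_conf(phi)
    # derivative d tau_conf / d phi via small central difference
    h <- 1e-7
    dtc <- (.tau_conf(phi + h) - .tau_conf(phi - h)) / (2 * h)
    phi <- phi - (tc - tau_p) / dtc
  }
  data.frame(lon = lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}
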