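# Analytic wind-stress fields and Ekman vertical velocity from the curl of
# the wind stress on a regular latitude-longitude grid.

EARTH_RADIUS_M <- 6.371e6
EARTH_OMEGA <- 7.2921e-5   # s-1
SEC_PER_DAY <- 86400

new_wind_field <- function(lat, lon, tau_x, tau_y, pattern = "custom",
                           amplitude = NA_real_, wavenumber = NA_integer_) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (any(abs(lat) >= 90)) stop("|lat| must be < 90", call. = FALSE)
  for (v in list(lat, lon)) {
    d <- diff(v)
    if (length(d) && (any(d <= 0) || any(abs(d - d[1]) > 1e-8)))
      stop("grid axes must be strictly increasing and uniform", call. = FALSE)
  }
  stopifnot(identical(dim(tau_x), c(length(lat), length(lon))),
            identical(dim(tau_y), c(length(lat), length(lon))))
  structure(list(lat = lat, lon = lon, tau_x = tau_x, tau_y = tau_y,
                 pattern = pattern, amplitude = amplitude,
                 wavenumber = wavenumber),
            class = "wind_field")
}

#' Generate an analytic wind-stress field
#'
#' `"uniform"` sets constant `(tau_x, tau_y) = (amplitude, 0)`, whose curl
#' is exactly zero. `"sinusoidal_curl"` sets `tau_x = 0` and
#' `tau_y = amplitude * sin(m * lon_rad)`, for which the Ekman vertical
#' velocity has the closed form returned by [analytic_ekman()]; it is the
#' oracle input for [ekman_vertical_velocity()].
#'
#' @param lat,lon Grid axes in degrees; uniform spacing, `|lat| < 90`.
#' @param pattern `"uniform"` or `"sinusoidal_curl"`.
#' @param amplitude Wind-stress amplitude, N m-2.
#' @param wavenumber Integer zonal wavenumber `m` of the sinusoidal pattern.
#' @return A `wind_field` object with matrices `tau_x`, `tau_y` of
#'   dimension `length(lat) x length(lon)`.
#' @export
make_analytic_wind <- function(lat, lon,
                               pattern = c("uniform", "sinusoidal_curl"),
                               amplitude = 0.1, wavenumber = 3L) {
  pattern <- match.arg(pattern)
  nlat <- length(lat); nlon <- length(lon)
  if (pattern == "uniform") {
    tx <- matrix(amplitude, nlat, nlon)
    ty <- matrix(0, nlat, nlon)
  } else {
    lam <- matrix(lon * pi / 180, nlat, nlon, byrow = TRUE)
    tx <- matrix(0, nlat, nlon)
    ty <- amplitude * sin(wavenumber * lam)
  }
  new_wind_field(lat, lon, tx, ty, pattern, amplitude, wavenumber)
}

#' Closed-form Ekman vertical velocity of an analytic wind field
#'
#' For the `"sinusoidal_curl"` pattern,
#' `w_E = A * m * cos(m * lon_rad) / (rho0 * f * R * cos(lat_rad))` with
#' `f = 2 * Omega * sin(lat_rad)`; for `"uniform"`, zero. Used as the
#' independent oracle for the finite-difference operator.
#'
#' @param wind A [make_analytic_wind()] output.
#' @param rho0 Reference seawater density, kg m-3.
#' @param lat_min Equatorial mask half-width in degrees; `|lat| < lat_min`
#'   is returned as `NA` (f vanishes at the equator).
#' @return Matrix of w_E in cm/day, `length(lat) x length(lon)`.
#' @export
analytic_ekman <- function(wind, rho0 = 1025, lat_min = 5) {
  stopifnot(inherits(wind, "wind_field"))
  if (wind$pattern == "custom")
    stop("no closed form recorded for a custom wind field", call. = FALSE)
  nlat <- length(wind$lat); nlon <- length(wind$lon)
  if (wind$pattern == "uniform") {
    we <- matrix(0, nlat, nlon)
  } else {
    phi <- matrix(wind$lat * pi / 180, nlat, nlon)
    lam <- matrix(wind$lon * pi / 180, nlat, nlon, byrow = TRUE)
    f <- 2 * EARTH_OMEGA * sin(phi)
    we <- wind$amplitude * wind$wavenumber * cos(wind$wavenumber * lam) /
      (rho0 * f * EARTH_RADIUS_M * cos(phi))
    we <- we * 100 * SEC_PER_DAY   # m/s -> cm/day
  }
  we[abs(wind$lat) < lat_min, ] <- NA_real_
  we
}

#' Ekman vertical velocity from the wind-stress curl
#'
#' Computes `w_E = d/dx (tau_y / (rho0 f)) - d/dy (tau_x / (rho0 f))` with
#' centered finite differences on the sphere (`dx = R cos(lat) dlon`,
#' `dy = R dlat`, `f = 2 Omega sin(lat)`). Grid edges, where a centered
#' difference is unavailable, and the equatorial band `|lat| < lat_min`,
#' where f vanishes, are returned as `NA`. Positive values are upwelling.
#'
#' @param wind A `wind_field`.
#' @param rho0 Reference seawater density, kg m-3.
#' @param lat_min Equatorial mask half-width in degrees.
#' @return Matrix of w_E in cm/day, `length(lat) x length(lon)`.
#' @export
ekman_vertical_velocity <- function(wind, rho0 = 1025, lat_min = 5) {
  stopifnot(inherits(wind, "wind_field"))
  lat <- wind$lat; lon <- wind$lon
  nlat <- length(lat); nlon <- length(lon)
  if (nlat < 3 || nlon < 3)
    stop("grid too small for centered differences (need >= 3 points per axis)",
         call. = FALSE)
  phi <- lat * pi / 180
  f <- 2 * EARTH_OMEGA * sin(phi)
  f[abs(lat) < lat_min] <- NA_real_          # masked: curl/f undefined
  mx <- wind$tau_x / (rho0 * f)              # recycles f along rows (lat)
  my <- wind$tau_y / (rho0 * f)
  dlam <- (lon[2] - lon[1]) * pi / 180
  dphi <- (lat[2] - lat[1]) * pi / 180
  we <- matrix(NA_real_, nlat, nlon)
  i <- 2:(nlat - 1); j <- 2:(nlon - 1)
  dx_term <- (my[i, j + 1] - my[i, j - 1]) /
    (2 * dlam * EARTH_RADIUS_M * cos(phi[i]))
  dy_term <- (mx[i + 1, j] - mx[i - 1, j]) / (2 * dphi * EARTH_RADIUS_M)
  we[i, j] <- dx_term - dy_term
  we * 100 * SEC_PER_DAY
}

#' Write / read a wind field as plain CSV
#'
#' Long format with columns `lat`, `lon`, `tau_x`, `tau_y` (N m-2).
#' @param wind A `wind_field`.
#' @param path Output path.
#' @return `read_wind_csv()` returns a `wind_field`.
#' @export
write_wind_csv <- function(wind, path) {
  stopifnot(inherits(wind, "wind_field"))
  df <- expand.grid(lat = wind$lat, lon = wind$lon)
  df$tau_x <- as.vector(wind$tau_x)
  df$tau_y <- as.vector(wind$tau_y)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wind_csv
#' @export
read_wind_csv <- function(path) {
  df <- utils::read.csv(path)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  o <- order(df$lon, df$lat)
  new_wind_field(lat, lon,
                 matrix(df$tau_x[o], length(lat), length(lon)),
                 matrix(df$tau_y[o], length(lat), length(lon)))
}
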