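# Solar geometry: NOAA low-accuracy equations (fractional-year Fourier fits
# for declination and the equation of time). Accuracy ~0.1-0.2 deg in
# declination and <0.5 min in the equation of time -- far below light-level
# geolocation error scales.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Fractional year angle
#'
#' @param date Date (UTC).
#' @param hour_utc decimal hour of day, default 12 (solar quantities vary
#'   slowly; noon is used throughout).
#' @return angle in radians in [0, 2*pi).
#' @keywords internal
.frac_year <- function(date, hour_utc = 12) {
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  # evaluated at the day centre; this phase keeps the Fourier fit within
  # ~0.12 deg of a Meeus-style ephemeris across the year
  2 * pi / 365 * (doy - 1 + hour_utc / 24)
}

#' Solar declination
#'
#' Declination of the sun on a given date (NOAA low-accuracy Fourier fit).
#'
#' @param date a `Date` (or coercible) in UTC.
#' @return declination in degrees, within \[-23.45, 23.45\].
#' @examples
#' solar_declination(as.Date("2017-06-21"))
#' @export
solar_declination <- function(date) {
  g <- .frac_year(as.Date(date))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  .rad2deg(decl)
}

#' Equation of time
#'
#' Difference between apparent and mean solar time (NOAA fit).
#'
#' @inheritParams solar_declination
#' @return minutes (apparent minus mean solar time).
#' @export
equation_of_time <- function(date) {
  g <- .frac_year(as.Date(date))
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

#' Predicted day length
#'
#' Day length (time the sun is above `solar_angle`) for a latitude and date.
#'
#' @param lat latitude, degrees.
#' @param date Date (UTC).
#' @param solar_angle sun elevation angle defining "twilight", degrees
#'   (negative below the horizon).
#' @return day length in hours; 0 for polar night, 24 for polar day.
#' @export
day_length <- function(lat, date, solar_angle = -0.833) {
  decl <- .deg2rad(solar_declination(date))
  phi <- .deg2rad(lat)
  a <- .deg2rad(solar_angle)
  cosH <- (sin(a) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  cosH <- pmin(1, pmax(-1, cosH))
  2 * .rad2deg(acos(cosH)) / 15
}

#' Twilight (sunrise/sunset) times at a position
#'
#' Forward solar model: UTC times at which the sun crosses `solar_angle`
#' at the given position and date.
#'
#' @param lat,lon position in decimal degrees (lon east-positive).
#' @inheritParams day_length
#' @return list with `sunrise_utc`, `sunset_utc` (decimal hours UTC) or
#'   both `NA` when the sun never crosses the angle (polar day/night).
#' @export
twilight_times <- function(lat, lon, date, solar_angle = -0.833) {
  date <- as.Date(date)
  decl <- .deg2rad(solar_declination(date))
  phi <- .deg2rad(lat)
  a <- .deg2rad(solar_angle)
  cosH <- (sin(a) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  if (any(abs(cosH) > 1)) {
    bad <- abs(cosH) > 1
    cosH[bad] <- NA_real_
  }
  H <- .rad2deg(acos(cosH))                   # degrees
  noon_min <- 720 - 4 * lon - equation_of_time(date)  # minutes UTC
  list(sunrise_utc = (noon_min - 4 * H) / 60,
       sunset_utc  = (noon_min + 4 * H) / 60)
}

# Latitudes at which (date, solar_angle) predicts the observed day length.
# Sign-change scan + uniroot; the day-length curve is monotone in latitude
# away from the equinoxes, so at most one root is expected.
.solve_latitude <- function(day_len_h, date, solar_angle,
                            lat_range = c(-70, 70)) {
  f <- function(phi) day_length(phi, date, solar_angle) - day_len_h
  grid <- seq(lat_range[1], lat_range[2], by = 1)
  vals <- vapply(grid, f, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (is.na(vals[i]) || is.na(vals[i + 1])) next
    if (vals[i] == 0) roots <- c(roots, grid[i])
    if (vals[i] * vals[i + 1] < 0) {
      r <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-7)
      roots <- c(roots, r$root)
    }
  }
  unique(roots)
}

#' Invert a twilight pair to coordinates
#'
#' Longitude follows from the UTC time of local solar midday (midpoint of
#' sunrise and sunset, corrected by the equation of time); latitude solves
#' the sunrise hour-angle equation for the observed day length at the given
#' twilight sun-elevation angle. Near the equinoxes day length is ~12 h at
#' every latitude, so the latitude solution is ill-conditioned and flagged
#' degenerate while the longitude remains valid.
#'
#' @param date Date (UTC) of the twilight pair.
#' @param sunrise_utc,sunset_utc decimal hours UTC; `sunset_utc` may exceed
#'   24 when sunset falls on the next UTC day.
#' @param solar_angle sun elevation angle of the tag's twilight definition,
#'   degrees; must satisfy `abs(solar_angle) < 18`.
#' @param declination_degenerate absolute solar declination (degrees) below
#'   which latitude is declared unidentifiable (default 1.5).
#' @return list with `lon`, `lat` (NA when degenerate), `degenerate_lat`
#'   logical, and `day_length_h`.
#' @export
twilight_to_coords <- function(date, sunrise_utc, sunset_utc,
                               solar_angle = -3.44,
                               declination_degenerate = 1.5) {
  stopifnot(abs(solar_angle) < 18)
  date <- as.Date(date)
  if (is.na(sunrise_utc) || is.na(sunset_utc))
    return(list(lon = NA_real_, lat = NA_real_, degenerate_lat = NA,
                day_length_h = NA_real_))
  if (sunset_utc <= sunrise_utc)
    stop("sunset must follow sunrise within the local day")
  midday <- (sunrise_utc + sunset_utc) / 2
  lon <- (720 - midday * 60 - equation_of_time(date)) / 4
  lon <- ((lon + 180) %% 360) - 180
  if (lon == -180) lon <- 180
  dl <- sunset_utc - sunrise_utc

  decl <- solar_declination(date)
  if (abs(decl) < declination_degenerate) {
    return(list(lon = lon, lat = NA_real_, degenerate_lat = TRUE,
                day_length_h = dl))
  }
  roots <- .solve_latitude(dl, date, solar_angle)
  if (length(roots) == 0) {
    # check whether any latitude can produce this day length at all
    grid <- seq(-89, 89, by = 0.5)
    dls <- day_length(grid, date, solar_angle)
    if (dl < min(dls) - 0.25 || dl > max(dls) + 0.25)
      stop("no latitude reproduces the observed day length on ", date)
    return(list(lon = lon, lat = NA_real_, degenerate_lat = TRUE,
                day_length_h = dl))
  }
  # monotone regime: single root expected; otherwise take the equator-nearest
  lat <- roots[which.min(abs(roots))]
  list(lon = lon, lat = lat, degenerate_lat = FALSE, day_length_h = dl)
}

#' Is a date within the equinox window?
#'
#' @param date Date.
#' @param window_days half-width of the window around 20 March and
#'   22 September (default 12).
#' @return logical.
#' @export
in_equinox_window <- function(date, window_days = 12) {
  date <- as.Date(date)
  yr <- as.integer(strftime(date, "%Y", tz = "UTC"))
  out <- logical(length(date))
  for (i in seq_along(date)) {
    eq <- as.Date(c(paste0(yr[i], "-03-20"), paste0(yr[i], "-09-22")))
    out[i] <- any(abs(as.numeric(date[i] - eq)) <= window_days)
  }
  out
}
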