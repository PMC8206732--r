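#' Astronomical daylength
#'
#' Standard sunrise-equation geometry: solar declination from day-of-year,
#' sunset hour angle from declination and latitude.
#'
#' @param latitude Degrees north, |latitude| < 66.5.
#' @param doy Day-of-year (1..365); vectorized.
#' @return Daylength in hours, in (0, 24).
#' @examples
#' daylength(51.8, 172) # close to the summer solstice at Rothamsted's latitude
#' @export
daylength <- function(latitude, doy) {
  if (abs(latitude) >= 66.5) abort("polar latitudes (|lat| >= 66.5) are not supported")
  decl <- solar_declination(doy)
  lat <- latitude * pi / 180
  cos_ws <- -tan(lat) * tan(decl)
  cos_ws <- pmin(1, pmax(-1, cos_ws))
  ws <- acos(cos_ws) # sunset hour angle, radians
  24 / pi * ws
}

# Solar declination (radians) for a 365-day year.
solar_declination <- function(doy) {
  0.409 * sin(2 * pi / 365 * doy - 1.39)
}

#' Extraterrestrial (top-of-atmosphere) solar radiation
#'
#' Daily total on a horizontal surface, from solar geometry alone
#' (solar constant 0.0820 MJ m-2 min-1, eccentricity correction).
#'
#' @inheritParams daylength
#' @return Radiation in MJ m-2 d-1; vectorized over `doy`.
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  if (abs(latitude) >= 66.5) abort("polar latitudes (|lat| >= 66.5) are not supported")
  gsc <- 0.0820 # MJ m-2 min-1
  lat <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  decl <- solar_declination(doy)
  cos_ws <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  ws <- acos(cos_ws)
  ra <- 24 * 60 / pi * gsc * dr *
    (ws * sin(lat) * sin(decl) + cos(lat) * cos(decl) * sin(ws))
  pmax(0, ra)
}
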