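#' Solar position
#'
#' Astronomical solar zenith and azimuth from standard equation-of-time and
#' declination formulas (Spencer series). Accuracy is a few tenths of a
#' degree, sufficient for canopy radiation geometry.
#'
#' @param time A `POSIXct` instant (any time zone; converted internally to
#'   UTC). Vectorized.
#' @param lat,lon Site latitude and longitude in decimal degrees (south and
#'   west negative). Defaults are the whole-tree-chamber site
#'   (33.62 S, 150.74 E).
#' @return A data.frame with `zenith` and `azimuth` (degrees, azimuth
#'   clockwise from north) and logical `above_horizon`.
#' @export
solar_position <- function(time, lat = -33.62, lon = 150.74) {
  tu <- as.POSIXlt(time, tz = "UTC")
  doy <- tu$yday + 1
  hour_utc <- tu$hour + tu$min / 60 + tu$sec / 3600
  g <- 2 * pi * (doy - 1 + (hour_utc - 12) / 24) / 365
  # declination (radians), Spencer (1971)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  # equation of time, minutes
  eqt <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  solar_time <- hour_utc + lon / 15 + eqt / 60     # hours, local solar
  ha <- (solar_time - 12) * 15 * pi / 180          # hour angle, radians
  latr <- lat * pi / 180
  cosz <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  cosz <- pmin(pmax(cosz, -1), 1)
  zen <- acos(cosz)
  # azimuth clockwise from north
  az <- atan2(sin(ha), cos(ha) * sin(latr) - tan(decl) * cos(latr))
  az <- (az * 180 / pi + 180) %% 360
  data.frame(zenith = zen * 180 / pi, azimuth = az,
             above_horizon = cosz > 0)
}

#' Diffuse fraction of incident PAR
#'
#' A simple irradiance-keyed split of measured incident PAR into diffuse and
#' direct beam: fully diffuse below 100 umol m-2 s-1, 30% diffuse above
#' 800 umol m-2 s-1, linear in between.
#'
#' @param PAR Incident PAR (umol m-2 s-1). Vectorized.
#' @param low,high PAR breakpoints (umol m-2 s-1).
#' @param fmin Diffuse fraction under bright conditions.
#' @return Diffuse fraction in (0, 1].
#' @export
diffuse_fraction <- function(PAR, low = 100, high = 800, fmin = 0.3) {
  f <- 1 - (1 - fmin) * (PAR - low) / (high - low)
  pmin(pmax(f, fmin), 1)
}

# Zenith-adjusted beam extinction coefficient for a spherical leaf angle
# distribution: kb' = 0.5 / cos(zenith), clipped at zenith 85 degrees.
beam_extinction <- function(zenith_deg, kb_nominal = 0.5) {
  z <- pmin(zenith_deg, 85) * pi / 180
  (kb_nominal / 0.5) * 0.5 / cos(z)
}
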