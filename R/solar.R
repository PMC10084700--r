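# NOAA-style low-precision solar position (General Solar Position
# Calculations, NOAA Global Monitoring Division). Accuracy well within the
# +-0.5 deg needed to evaluate the civil-twilight night flag.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Sun elevation above the horizon
#'
#' Apparent solar elevation (including the standard atmospheric-refraction
#' correction) for UTC timestamps at a given site.
#'
#' @param utc `POSIXct` timestamp(s), UTC.
#' @param lat,lon Site coordinates in decimal degrees (east positive).
#' @return Elevation in degrees, in `[-90, 90]`; vectorised over `utc`.
#' @export
#'
#' @examples
#' sun_elevation(as.POSIXct("2019-06-21 12:00", tz = "UTC"), 48.99, 14.38)
sun_elevation <- function(utc, lat, lon) {
  stopifnot(abs(lat) <= 90)
  jd <- as.numeric(utc) / 86400 + 2440587.5
  tc <- (jd - 2451545) / 36525  # Julian centuries since J2000.0

  L0 <- (280.46646 + tc * (36000.76983 + 0.0003032 * tc)) %% 360
  M <- 357.52911 + tc * (35999.05029 - 0.0001537 * tc)
  e <- 0.016708634 - tc * (0.000042037 + 0.0000001267 * tc)
  Mr <- deg2rad(M)
  C <- sin(Mr) * (1.914602 - tc * (0.004817 + 0.000014 * tc)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * tc) +
    sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- deg2rad(125.04 - 1934.136 * tc)
  lambda <- deg2rad(true_long - 0.00569 - 0.00478 * sin(omega))

  eps0 <- 23 + (26 + (21.448 - tc * (46.815 + tc * (0.00059 - tc * 0.001813))) / 60) / 60
  eps <- deg2rad(eps0 + 0.00256 * cos(omega))

  decl <- asin(sin(eps) * sin(lambda))

  y <- tan(eps / 2)^2
  L0r <- deg2rad(L0)
  eot <- 4 * rad2deg(y * sin(2 * L0r) - 2 * e * sin(Mr) +
                       4 * e * y * sin(Mr) * cos(2 * L0r) -
                       0.5 * y^2 * sin(4 * L0r) -
                       1.25 * e^2 * sin(2 * Mr))  # minutes

  mins_utc <- (as.numeric(utc) %% 86400) / 60
  tst <- (mins_utc + eot + 4 * lon) %% 1440  # true solar time, minutes
  ha <- tst / 4 - 180                        # hour angle, degrees

  latr <- deg2rad(lat)
  cos_zen <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(deg2rad(ha))
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  elev <- 90 - rad2deg(acos(cos_zen))

  pmin(90, pmax(-90, elev + refraction_deg(elev)))
}

# standard NOAA refraction correction, degrees, as a function of the
# geometric elevation in degrees
refraction_deg <- function(elev) {
  er <- deg2rad(elev)
  out <- numeric(length(elev))
  hi <- elev > 5 & elev <= 85
  te <- tan(er[hi])
  out[hi] <- (58.1 / te - 0.07 / te^3 + 0.000086 / te^5) / 3600
  mid <- elev > -0.575 & elev <= 5
  e <- elev[mid]
  out[mid] <- (1735 + e * (-518.2 + e * (103.4 + e * (-12.79 + e * 0.711)))) / 3600
  lo <- elev <= -0.575
  out[lo] <- -20.772 / tan(er[lo]) / 3600
  out
}

#' Civil-twilight night flag
#'
#' Night is defined as the sun being more than 6 degrees below the horizon;
#' an elevation of exactly -6 degrees still counts as (twi)light.
#'
#' @param elevation Sun elevation in degrees.
#' @return Logical vector: `TRUE` when `elevation < -6`.
#' @export
night_flag <- function(elevation) {
  elevation < -6.0
}
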