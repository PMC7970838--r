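## Solar geometry used to decide "night" for diel vertical migration.
## Fourier-series declination and equation of time (Spencer-type
## coefficients, as in the NOAA solar calculator); accuracy is a few
## hundredths of a degree in declination, well within the 0.5 degree
## target for elevation.

solarPieces <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  N <- lt$yday + 1L
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi / 365 * (N - 1 + (hour - 12) / 24)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  list(decl = decl, eqtime = eqtime, hour = hour)
}

#' Solar elevation angle
#'
#' Elevation of the sun above the horizon (no atmospheric refraction),
#' accurate to well within half a degree. Vectorized over positions;
#' \code{time} is recycled if scalar.
#'
#' @param time POSIXct in UTC.
#' @param lon,lat position in degrees east / north.
#' @return elevation in degrees; positive above the horizon.
#' @examples
#' solarElevation(as.POSIXct("2017-06-21 00:00", tz = "UTC"), 15, 70)
#' @export
solarElevation <- function(time, lon, lat) {
  sp <- solarPieces(time)
  tst <- (sp$hour * 60 + sp$eqtime + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180
  latr <- lat * pi / 180
  sinel <- sin(latr) * sin(sp$decl) + cos(latr) * cos(sp$decl) * cos(ha)
  asin(pmin(pmax(sinel, -1), 1)) * 180 / pi
}

## UTC time of local solar midnight (true solar time 00:00) for the date
## of `time` at longitude `lon`. Vectorized.
solarMidnightUTC <- function(time, lon) {
  sp <- solarPieces(time)
  day0 <- as.POSIXct(trunc(as.POSIXlt(time, tz = "UTC"), "days"), tz = "UTC")
  minutes <- (-sp$eqtime - 4 * lon) %% 1440
  day0 + minutes * 60
}

#' Diel target depth for migrating larvae
#'
#' Larvae migrate between a shallow night depth and a deep day depth
#' (default band 5-40 m): shallow when it is "night", deep during the day.
#' Night is defined as solar elevation below 0 degrees. At high latitudes
#' in summer the sun may never set; the fallback then treats the 3 hours
#' either side of local solar midnight (the daily elevation minimum) as
#' night, so the migration rhythm persists under the midnight sun.
#'
#' @param time POSIXct in UTC.
#' @param lon,lat position in degrees (vectorized).
#' @param dvm numeric length-2 band \code{c(shallow, deep)} in metres,
#'   default \code{c(5, 40)}.
#' @param fallbackHours half-width of the midnight-sun night window, hours.
#' @return target depth in metres (positive down) per position.
#' @examples
#' noon <- as.POSIXct("2017-04-01 12:00", tz = "UTC")
#' dielTargetDepth(noon, 0, 45)   # day -> 40 m
#' @export
dielTargetDepth <- function(time, lon, lat, dvm = c(5, 40),
                            fallbackHours = 3) {
  elev <- solarElevation(time, lon, lat)
  night <- elev < 0
  ## midnight-sun fallback: where elevation at solar midnight stays above
  ## the horizon, use a fixed window around solar midnight instead
  mid <- solarMidnightUTC(time, lon)
  minElev <- solarElevation(mid, lon, lat)
  polarDay <- minElev > 0
  if (any(polarDay)) {
    dh <- abs(as.numeric(difftime(rep(as.POSIXct(time, tz = "UTC"),
                                      length.out = length(lon)),
                                  mid, units = "hours")))
    dh <- pmin(dh, 24 - dh)
    night[polarDay] <- dh[polarDay] <= fallbackHours
  }
  ifelse(night, dvm[1], dvm[2])
}
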