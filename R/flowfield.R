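#' Construct a FlowField
#'
#' Builds a validated [FlowField-class] from axes and velocity arrays.
#' Velocities on masked (land) cells are zeroed so the mask-consistency
#' invariant holds by construction.
#'
#' @param lon,lat strictly increasing axes, degrees east / north.
#' @param depth strictly increasing depth axis, metres positive down.
#' @param dates Date vector of the daily means (consecutive days).
#' @param u,v numeric arrays \code{[lon, lat, depth, time]} in m/s.
#' @param w optional vertical velocity array of the same shape.
#' @param mask optional logical \code{[lon, lat]} land mask (TRUE = land);
#'   defaults to all-water.
#' @param maxSpeed horizontal speed cap in m/s (default 1.0); construction
#'   fails if any wet cell exceeds it.
#' @return a [FlowField-class] object.
#' @examples
#' ff <- FlowField(lon = 0:2, lat = 60:62, depth = c(0, 50),
#'                 dates = as.Date("2017-06-01"),
#'                 u = array(0, c(3, 3, 2, 1)), v = array(0.2, c(3, 3, 2, 1)))
#' ff
#' @export
FlowField <- function(lon, lat, depth, dates, u, v, w = NULL, mask = NULL,
                      maxSpeed = 1.0) {
  dates <- as.Date(dates)
  if (is.null(mask))
    mask <- matrix(FALSE, length(lon), length(lat))
  if (anyNA(u) || anyNA(v))
    stopBadVelocity(u, v, lon, lat)
  if (any(mask)) {
    zero <- function(a) {
      m4 <- array(rep(mask, times = length(depth) * length(dates)),
                  dim = dim(a))
      a[m4] <- 0
      a
    }
    u <- zero(u); v <- zero(v)
    if (!is.null(w)) w <- zero(w)
  }
  new("FlowField", lon = as.numeric(lon), lat = as.numeric(lat),
      depth = as.numeric(depth), dates = dates,
      u = u, v = v, w = w, mask = mask, maxSpeed = maxSpeed)
}

stopBadVelocity <- function(u, v, lon, lat) {
  bad <- which(is.na(u) | is.na(v), arr.ind = TRUE)
  b <- bad[1, ]
  stop(sprintf(
    "non-finite velocity at cell [lon=%g, lat=%g, depth index %d, time index %d]",
    lon[b[1]], lat[b[2]], b[3], b[4]), call. = FALSE)
}

## Fractional (index, weight) position of x along a strictly increasing
## axis; clamps outside-range points to the boundary when clamp = TRUE,
## else returns NA index.
axisLocate <- function(x, axis, clamp = FALSE) {
  n <- length(axis)
  if (n == 1)
    return(list(i = rep(1L, length(x)), w = rep(0, length(x)),
                inside = rep(TRUE, length(x))))
  inside <- x >= axis[1] & x <= axis[n]
  xc <- pmin(pmax(x, axis[1]), axis[n])
  i <- findInterval(xc, axis, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  w <- (xc - axis[i]) / (axis[i + 1] - axis[i])
  if (!clamp) i[!inside] <- NA_integer_
  list(i = i, w = w, inside = inside)
}

## Trilinear interpolation of one [lon, lat, depth, time] array at a single
## time index, vectorized over points. lx/ly/lz are axisLocate() results.
interpSlice <- function(a, lx, ly, lz, ti, nlon, nlat, ndep) {
  base <- (ti - 1L) * nlon * nlat * ndep
  idx <- function(di, dj, dk)
    base + (lx$i + di) + (ly$i + dj - 1L) * nlon + (lz$i + dk - 1L) * nlon * nlat
  wx <- lx$w; wy <- ly$w; wz <- lz$w
  a[idx(0L, 0L, 0L)] * (1 - wx) * (1 - wy) * (1 - wz) +
  a[idx(1L, 0L, 0L)] * wx       * (1 - wy) * (1 - wz) +
  a[idx(0L, 1L, 0L)] * (1 - wx) * wy       * (1 - wz) +
  a[idx(1L, 1L, 0L)] * wx       * wy       * (1 - wz) +
  a[idx(0L, 0L, 1L)] * (1 - wx) * (1 - wy) * wz +
  a[idx(1L, 0L, 1L)] * wx       * (1 - wy) * wz +
  a[idx(0L, 1L, 1L)] * (1 - wx) * wy       * wz +
  a[idx(1L, 1L, 1L)] * wx       * wy       * wz
}

#' Interpolate velocities at particle positions
#'
#' Trilinear interpolation in (lon, lat, depth) and linear interpolation in
#' time between daily means. Each daily mean is anchored at 00:00 UTC of
#' its date. Points outside the horizontal domain return NA velocities;
#' depths are clamped to the depth axis (velocities treated as constant
#' above the first and below the last level).
#'
#' @param field a [FlowField-class].
#' @param lon,lat,depth numeric vectors of positions (depth m, positive
#'   down).
#' @param time a single POSIXct (UTC) within the field's time span.
#' @return list with numeric vectors \code{u} and \code{v} (m/s).
#' @export
interpVelocity <- function(field, lon, lat, depth, time) {
  dates <- field@dates
  t0 <- as.POSIXct(paste(dates[1], "00:00:00"), tz = "UTC")
  td <- as.numeric(difftime(time, t0, units = "days"))
  nt <- length(dates)
  if (td < -1e-9 || td > (nt - 1) + 1 + 1e-9)
    stop("time ", format(time), " outside the flow-field span")
  ti <- min(max(floor(td) + 1, 1), nt)
  ti2 <- min(ti + 1L, nt)
  wt <- td - (ti - 1)
  wt <- min(max(wt, 0), 1)

  lx <- axisLocate(lon, field@lon)
  ly <- axisLocate(lat, field@lat)
  lz <- axisLocate(depth, field@depth, clamp = TRUE)
  ok <- lx$inside & ly$inside
  nlon <- length(field@lon); nlat <- length(field@lat)
  ndep <- length(field@depth)
  u <- v <- rep(NA_real_, length(lon))
  if (any(ok)) {
    lxo <- lapply(lx, `[`, ok); lyo <- lapply(ly, `[`, ok)
    lzo <- lapply(lz, `[`, ok)
    u1 <- interpSlice(field@u, lxo, lyo, lzo, ti, nlon, nlat, ndep)
    v1 <- interpSlice(field@v, lxo, lyo, lzo, ti, nlon, nlat, ndep)
    if (ti2 != ti && wt > 0) {
      u2 <- interpSlice(field@u, lxo, lyo, lzo, ti2, nlon, nlat, ndep)
      v2 <- interpSlice(field@v, lxo, lyo, lzo, ti2, nlon, nlat, ndep)
      u[ok] <- (1 - wt) * u1 + wt * u2
      v[ok] <- (1 - wt) * v1 + wt * v2
    } else {
      u[ok] <- u1
      v[ok] <- v1
    }
  }
  list(u = u, v = v)
}

## TRUE where the nearest grid cell to (lon, lat) is land.
onLand <- function(field, lon, lat) {
  if (!any(field@mask)) return(rep(FALSE, length(lon)))
  i <- pmin(pmax(round(approx(field@lon, seq_along(field@lon), xout = lon,
                              rule = 2)$y), 1), length(field@lon))
  j <- pmin(pmax(round(approx(field@lat, seq_along(field@lat), xout = lat,
                              rule = 2)$y), 1), length(field@lat))
  field@mask[cbind(i, j)]
}

inDomain <- function(field, lon, lat) {
  lon >= field@lon[1] & lon <= field@lon[length(field@lon)] &
    lat >= field@lat[1] & lat <= field@lat[length(field@lat)]
}
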