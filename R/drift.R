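## Lagrangian individual-based drift model: release scheduling, RK4
## advection with diel vertical migration, linear growth, and gridded
## density output.

HATCH_LENGTH_MM <- 9     # length at hatch
GROWTH_MM_DAY <- 0.4     # linear growth rate
SWIM_BL_S <- 0.1         # vertical swim speed, body lengths per second
EARTH_RADIUS_M <- 6371000

#' Default spawning grounds along the Norwegian coast
#'
#' Release points for Norwegian spring-spawning herring at Møre,
#' Haltenbanken, Sklinna and Røst (from about 63 to 68 degrees N) with
#' release fractions 0.5, 0.2, 0.1 and 0.2.
#'
#' @return data.frame with columns name, lon, lat, fraction.
#' @export
defaultSpawningGrounds <- function() {
  data.frame(
    name = c("More", "Haltenbanken", "Sklinna", "Rost"),
    lon = c(6.2, 9.0, 10.8, 11.9),
    lat = c(62.8, 64.3, 65.2, 67.5),
    fraction = c(0.5, 0.2, 0.1, 0.2),
    stringsAsFactors = FALSE
  )
}

#' Construct a ReleaseConfig
#'
#' The hatching intensity is Gaussian in time, truncated to the hatch
#' window. When \code{hatchMean}/\code{hatchSD} are not given they default
#' to the window midpoint and one sixth of the window length, so the
#' window covers about +/- 3 sd of the intensity.
#'
#' @param totalParticles total release size (default 198580).
#' @param hatchStart,hatchEnd hatch window Dates (default 15 March to
#'   20 April 2017).
#' @param hatchMean,hatchSD Gaussian parameters in days since
#'   \code{hatchStart}; see Details for defaults.
#' @param grounds spawning-ground table (name, lon, lat, fraction);
#'   fractions must sum to 1.
#' @param seed RNG seed for hatch-time draws.
#' @return a [ReleaseConfig-class].
#' @examples
#' ReleaseConfig(totalParticles = 1000)
#' @export
ReleaseConfig <- function(totalParticles = 198580,
                          hatchStart = as.Date("2017-03-15"),
                          hatchEnd = as.Date("2017-04-20"),
                          hatchMean = NULL, hatchSD = NULL,
                          grounds = defaultSpawningGrounds(),
                          seed = 1L) {
  hatchStart <- as.Date(hatchStart); hatchEnd <- as.Date(hatchEnd)
  len <- as.numeric(hatchEnd - hatchStart)
  if (is.null(hatchMean)) hatchMean <- len / 2
  if (is.null(hatchSD)) hatchSD <- len / 6
  new("ReleaseConfig", totalParticles = totalParticles,
      hatchStart = hatchStart, hatchEnd = hatchEnd,
      hatchMean = hatchMean, hatchSD = hatchSD,
      grounds = grounds, seed = seed)
}

## Integer allocation of `total` across `fractions` by largest remainder,
## so the grand total is exact.
largestRemainder <- function(total, fractions) {
  exact <- total * fractions
  base <- floor(exact)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## Exact inverse-CDF draws from a Gaussian truncated to [0, len] days.
rtruncGauss <- function(n, mean, sd, len) {
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(len, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Release particles at the spawning grounds
#'
#' Allocates the total release across grounds by their fractions
#' (largest-remainder rounding, so per-ground counts sum exactly to the
#' total) and draws each particle's hatch time from the truncated-Gaussian
#' hatching intensity. Particles start at 9 mm length, age 0, status
#' "active", at the mid-depth of the migration band.
#'
#' @param config a [ReleaseConfig-class].
#' @param startDepth initial depth in metres (default 20, the middle of
#'   the 5-40 m migration band).
#' @return particle data.frame with columns id, lon, lat, depth, length,
#'   hatch_time (POSIXct UTC), age, ground, status. Deterministic for a
#'   given \code{config@seed}.
#' @examples
#' p <- releaseParticles(ReleaseConfig(totalParticles = 10))
#' table(p$ground)
#' @export
releaseParticles <- function(config, startDepth = 20) {
  validObject(config)
  g <- config@grounds
  total <- config@totalParticles
  if (total == 0) {
    return(data.frame(id = integer(), lon = numeric(), lat = numeric(),
                      depth = numeric(), length = numeric(),
                      hatch_time = as.POSIXct(character(), tz = "UTC"),
                      age = numeric(), ground = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  counts <- largestRemainder(total, g$fraction)
  len <- as.numeric(config@hatchEnd - config@hatchStart)
  t0 <- as.POSIXct(paste(config@hatchStart, "00:00:00"), tz = "UTC")
  withr::with_seed(config@seed, {
    days <- rtruncGauss(total, config@hatchMean, config@hatchSD, len)
  })
  data.frame(
    id = seq_len(total),
    lon = rep(g$lon, counts),
    lat = rep(g$lat, counts),
    depth = startDepth,
    length = HATCH_LENGTH_MM,
    hatch_time = t0 + days * 86400,
    age = 0,
    ground = rep(g$name, counts),
    status = "active",
    stringsAsFactors = FALSE
  )
}

## m/s -> degrees/s at latitude phi (east-positive, north-positive).
degPerSec <- function(u, v, lat) {
  list(dlon = u / (EARTH_RADIUS_M * cos(lat * pi / 180)) * 180 / pi,
       dlat = v / EARTH_RADIUS_M * 180 / pi)
}

#' Advance particles one time step
#'
#' Horizontal positions are advanced with a 4th-order Runge-Kutta step
#' over velocities interpolated trilinearly in space and linearly in time
#' between daily means, with the cos(lat) metric converting metres to
#' degrees. Vertically, each particle swims toward its diel target depth
#' (see [dielTargetDepth()]) at 0.1 body lengths per second, clamped to
#' the migration band and to the deepest model level. Length grows
#' linearly at 0.4 mm per day (length = 9 + 0.4 age exactly). Particles
#' whose new position falls on a land cell revert to their last wet
#' position and become "beached"; particles leaving the domain become
#' "exited" with their position frozen. Only "active" rows are moved.
#'
#' @param particles particle data.frame as from [releaseParticles()].
#' @param field a [FlowField-class].
#' @param t POSIXct (UTC) at the start of the step.
#' @param dt step length in seconds (> 0).
#' @param dvm migration band \code{c(shallow, deep)} in metres, or NULL to
#'   disable vertical behaviour.
#' @return the updated particle data.frame.
#' @export
advectStep <- function(particles, field, t, dt, dvm = c(5, 40)) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number of seconds")
  act <- which(particles$status == "active")
  if (!length(act)) return(particles)
  lon0 <- particles$lon[act]; lat0 <- particles$lat[act]
  dep <- particles$depth[act]

  vel <- function(lon, lat, tm) {
    vv <- interpVelocity(field, lon, lat, dep, tm)
    vv$u[is.na(vv$u)] <- 0; vv$v[is.na(vv$v)] <- 0
    degPerSec(vv$u, vv$v, lat)
  }
  k1 <- vel(lon0, lat0, t)
  k2 <- vel(lon0 + dt / 2 * k1$dlon, lat0 + dt / 2 * k1$dlat, t + dt / 2)
  k3 <- vel(lon0 + dt / 2 * k2$dlon, lat0 + dt / 2 * k2$dlat, t + dt / 2)
  k4 <- vel(lon0 + dt * k3$dlon, lat0 + dt * k3$dlat, t + dt)
  lon1 <- lon0 + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
  lat1 <- lat0 + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)

  exited <- !inDomain(field, lon1, lat1)
  beached <- !exited & onLand(field, lon1, lat1)
  moved <- !exited & !beached
  particles$lon[act[moved]] <- lon1[moved]
  particles$lat[act[moved]] <- lat1[moved]
  particles$status[act[exited]] <- "exited"
  particles$status[act[beached]] <- "beached"

  ## vertical migration toward the diel target, growth, ageing (only rows
  ## still active after the horizontal update keep migrating)
  still <- act[moved]
  if (!is.null(dvm) && length(still)) {
    target <- dielTargetDepth(t, particles$lon[still], particles$lat[still],
                              dvm = dvm)
    speed <- SWIM_BL_S * particles$length[still] / 1000  # m/s
    dz <- target - particles$depth[still]
    step <- pmin(abs(dz), speed * dt) * sign(dz)
    newDepth <- particles$depth[still] + step
    seabed <- max(field@depth)
    particles$depth[still] <- pmin(pmax(newDepth, dvm[1]), min(dvm[2], seabed))
  }
  particles$age[act] <- particles$age[act] + dt / 86400
  particles$length[act] <- HATCH_LENGTH_MM + GROWTH_MM_DAY * particles$age[act]
  particles
}

#' Run the drift simulation
#'
#' Particles enter the simulation at their hatch time and are then stepped
#' with [advectStep()] until \code{endDate}. Snapshots of all hatched
#' particles are stored at a configurable cadence (default daily at 00:00
#' UTC). The run is reproducible given the release seed.
#'
#' @param config a [ReleaseConfig-class].
#' @param field a [FlowField-class] spanning at least the hatch window
#'   through \code{endDate}.
#' @param dt integration step in seconds (default 3600).
#' @param endDate last simulated Date.
#' @param snapshotEvery snapshot cadence in seconds (default 86400).
#' @param dvm migration band passed to [advectStep()].
#' @return a [SimulationResult-class].
#' @export
runSimulation <- function(config, field, dt = 3600,
                          endDate = max(fieldDates(field)),
                          snapshotEvery = 86400, dvm = c(5, 40)) {
  validObject(config); validObject(field)
  endDate <- as.Date(endDate)
  if (min(field@dates) > config@hatchStart || max(field@dates) < endDate)
    stop("flow field does not span the hatch window through endDate")
  particles <- releaseParticles(config)
  hatched <- rep(FALSE, nrow(particles))
  t0 <- as.POSIXct(paste(config@hatchStart, "00:00:00"), tz = "UTC")
  tEnd <- as.POSIXct(paste(endDate, "00:00:00"), tz = "UTC")
  nSteps <- max(0, ceiling(as.numeric(difftime(tEnd, t0, units = "secs")) / dt))
  snapshots <- list()

  takeSnap <- function(tm) {
    snap <- particles[hatched, , drop = FALSE]
    rownames(snap) <- NULL
    snapshots[[format(as.Date(tm, tz = "UTC"))]] <<- snap
  }
  t <- t0
  hatched <- particles$hatch_time <= t
  takeSnap(t)
  if (nSteps > 0) {
    for (s in seq_len(nSteps)) {
      newly <- !hatched & particles$hatch_time <= t + dt
      hatched <- hatched | newly
      idx <- which(hatched)
      if (length(idx)) {
        sub <- advectStep(particles[idx, , drop = FALSE], field, t, dt,
                          dvm = dvm)
        particles[idx, ] <- sub
      }
      t <- t + dt
      if (as.numeric(difftime(t, t0, units = "secs")) %% snapshotEvery == 0 ||
          s == nSteps)
        takeSnap(t)
    }
  }
  new("SimulationResult",
      snapshots = snapshots,
      finalState = particles[hatched, , drop = FALSE],
      dt = dt, seed = config@seed,
      released = config@totalParticles,
      configDigest = objectDigest(config))
}

objectDigest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Bin a snapshot onto a density grid
#'
#' Counts particles into half-open lon/lat cells (lower edge inclusive)
#' and applies the requested transform: "raw" counts, "log_n" for
#' log(n + 1), or "sqrt_n" for the square root of n.
#'
#' @param result a [SimulationResult-class].
#' @param date snapshot date to bin.
#' @param lonEdges,latEdges cell edge vectors.
#' @param transform one of "raw", "log_n", "sqrt_n".
#' @return a [DensityGrid-class]; the raw counts sum to the number of
#'   particles inside the grid at that snapshot.
#' @export
densityGrid <- function(result, date, lonEdges, latEdges,
                        transform = c("raw", "log_n", "sqrt_n")) {
  if (length(transform) == 1 && !transform %in% c("raw", "log_n", "sqrt_n"))
    stop("unknown transform: ", transform)
  transform <- match.arg(transform)
  snap <- snapshotAt(result, date)
  nx <- length(lonEdges) - 1L; ny <- length(latEdges) - 1L
  i <- findInterval(snap$lon, lonEdges)
  j <- findInterval(snap$lat, latEdges)
  ok <- i >= 1 & i <= nx & j >= 1 & j <= ny &
    snap$lon < lonEdges[nx + 1] & snap$lat < latEdges[ny + 1]
  counts <- matrix(0L, nx, ny)
  if (any(ok)) {
    tab <- table(factor(i[ok], levels = seq_len(nx)),
                 factor(j[ok], levels = seq_len(ny)))
    counts <- matrix(as.integer(tab), nx, ny)
  }
  values <- switch(transform,
    raw = counts * 1.0,
    log_n = log(counts + 1),
    sqrt_n = sqrt(counts))
  new("DensityGrid", lonEdges = as.numeric(lonEdges),
      latEdges = as.numeric(latEdges), counts = counts,
      values = values, transform = transform)
}
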