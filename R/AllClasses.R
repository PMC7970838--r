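## Central S4 containers. Velocity arrays are dimensioned
## [lon, lat, depth, time]; the land mask is [lon, lat]; depth is metres
## positive down; dates are calendar days (daily-mean forcing) in UTC.

#' FlowField: gridded daily-mean ocean currents
#'
#' Holds horizontal (and optionally vertical) velocities on a regular
#' lon/lat/depth grid over a sequence of calendar days, together with a
#' land mask. Velocities on masked (land) cells are zero by construction;
#' the horizontal speed never exceeds \code{maxSpeed} (default 1 m/s, the
#' maximum speed of the Norwegian Coastal Current that transports herring
#' larvae northward).
#'
#' @slot lon,lat strictly increasing axes in degrees east / north.
#' @slot depth strictly increasing depth axis, metres positive down.
#' @slot dates consecutive calendar days the daily means are valid for.
#' @slot u,v numeric arrays \code{[lon, lat, depth, time]}, m/s.
#' @slot w optional vertical velocity array of the same shape (or NULL).
#' @slot mask logical \code{[lon, lat]} matrix; TRUE marks land.
#' @slot maxSpeed speed cap in m/s used by the validity check.
#'
#' @seealso [FlowField()] for the user constructor,
#'   [interpVelocity()] for space-time interpolation.
#' @exportClass FlowField
setClass("FlowField",
  slots = c(
    lon = "numeric", lat = "numeric", depth = "numeric", dates = "Date",
    u = "array", v = "array", w = "ANY",
    mask = "matrix", maxSpeed = "numeric"
  )
)

setValidity("FlowField", function(object) {
  msg <- character()
  dims <- c(length(object@lon), length(object@lat),
            length(object@depth), length(object@dates))
  for (ax in c("lon", "lat", "depth")) {
    v <- slot(object, ax)
    if (length(v) < 1 || any(!is.finite(v)) || is.unsorted(v, strictly = TRUE))
      msg <- c(msg, sprintf("axis '%s' must be finite and strictly increasing", ax))
  }
  if (!identical(dim(object@u), dims) || !identical(dim(object@v), dims))
    msg <- c(msg, "u and v must be arrays of dim [lon, lat, depth, time]")
  if (!is.null(object@w) && !identical(dim(object@w), dims))
    msg <- c(msg, "w, when present, must match the dim of u and v")
  if (anyNA(object@u) || anyNA(object@v) ||
      any(!is.finite(object@u)) || any(!is.finite(object@v)))
    msg <- c(msg, "all velocities must be finite")
  if (!identical(dim(object@mask), dims[1:2]) || !is.logical(object@mask))
    msg <- c(msg, "mask must be a logical [lon, lat] matrix")
  if (length(msg) == 0) {
    spd <- sqrt(object@u^2 + object@v^2)
    if (max(spd) > object@maxSpeed + 1e-9)
      msg <- c(msg, sprintf("horizontal speed %.3f m/s exceeds maxSpeed %.3f",
                            max(spd), object@maxSpeed))
    if (any(object@mask)) {
      land <- which(object@mask, arr.ind = TRUE)
      for (k in seq_len(nrow(land))) {
        if (any(object@u[land[k, 1], land[k, 2], , ] != 0) ||
            any(object@v[land[k, 1], land[k, 2], , ] != 0)) {
          msg <- c(msg, "masked (land) cells must have zero velocity")
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ReleaseConfig: particle release schedule for the drift model
#'
#' Describes how simulated larvae are released: the total particle count,
#' a Gaussian-shaped hatching intensity truncated to a hatch window, and a
#' table of spawning grounds with release fractions. Defaults follow the
#' Norwegian spring-spawning herring setting: 198,580 particles, hatch
#' window 15 March to 20 April, grounds at Møre, Haltenbanken, Sklinna
#' and Røst with fractions 0.5 / 0.2 / 0.1 / 0.2.
#'
#' @slot totalParticles total number of particles released.
#' @slot hatchStart,hatchEnd hatch window (Dates, UTC).
#' @slot hatchMean,hatchSD Gaussian hatching-intensity parameters in days
#'   since \code{hatchStart}.
#' @slot grounds data.frame with columns \code{name}, \code{lon},
#'   \code{lat}, \code{fraction} (fractions sum to 1).
#' @slot seed integer RNG seed making the release deterministic.
#' @seealso [ReleaseConfig()], [releaseParticles()]
#' @exportClass ReleaseConfig
setClass("ReleaseConfig",
  slots = c(
    totalParticles = "numeric",
    hatchStart = "Date", hatchEnd = "Date",
    hatchMean = "numeric", hatchSD = "numeric",
    grounds = "data.frame", seed = "numeric"
  )
)

setValidity("ReleaseConfig", function(object) {
  msg <- character()
  if (length(object@totalParticles) != 1 || object@totalParticles < 0 ||
      object@totalParticles != round(object@totalParticles))
    msg <- c(msg, "totalParticles must be a single non-negative integer")
  if (!(object@hatchStart < object@hatchEnd))
    msg <- c(msg, "hatch window start must precede its end")
  if (object@hatchSD <= 0)
    msg <- c(msg, "hatchSD must be > 0")
  g <- object@grounds
  need <- c("name", "lon", "lat", "fraction")
  if (!all(need %in% names(g)) || nrow(g) == 0)
    msg <- c(msg, "grounds must be a non-empty data.frame with name/lon/lat/fraction")
  else {
    if (any(g$fraction < 0))
      msg <- c(msg, "ground fractions must be >= 0")
    if (abs(sum(g$fraction) - 1) > 1e-9)
      msg <- c(msg, sprintf("ground fractions must sum to 1 (got %.12f)",
                            sum(g$fraction)))
  }
  if (length(msg)) msg else TRUE
})

#' SimulationResult: snapshots of a drift run
#'
#' @slot snapshots named list (one element per snapshot date, "YYYY-MM-DD")
#'   of particle data.frames with columns id, lon, lat, depth, length,
#'   hatch_time, age, ground, status.
#' @slot finalState particle data.frame at the last time step.
#' @slot dt integration step in seconds.
#' @slot seed RNG seed of the release.
#' @slot released total number of particles in the release.
#' @slot configDigest md5 digest of the serialized configuration.
#' @seealso [runSimulation()], [densityGrid()]
#' @exportClass SimulationResult
setClass("SimulationResult",
  slots = c(
    snapshots = "list", finalState = "data.frame",
    dt = "numeric", seed = "numeric", released = "numeric",
    configDigest = "character"
  )
)

setValidity("SimulationResult", function(object) {
  msg <- character()
  for (snap in object@snapshots) {
    if (!all(snap$status %in% c("active", "beached", "exited")))
      msg <- c(msg, "snapshot statuses must be active/beached/exited")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' DensityGrid: binned particle counts on a lon/lat grid
#'
#' @slot lonEdges,latEdges cell edges (half-open cells, lower edge
#'   inclusive).
#' @slot counts raw particle counts per cell, \code{[lon, lat]}.
#' @slot values transformed counts per the \code{transform} tag.
#' @slot transform one of "raw", "log_n" (log(n + 1)) or "sqrt_n".
#' @seealso [densityGrid()]
#' @exportClass DensityGrid
setClass("DensityGrid",
  slots = c(
    lonEdges = "numeric", latEdges = "numeric",
    counts = "matrix", values = "matrix", transform = "character"
  )
)

setValidity("DensityGrid", function(object) {
  msg <- character()
  if (is.unsorted(object@lonEdges, strictly = TRUE) ||
      is.unsorted(object@latEdges, strictly = TRUE))
    msg <- c(msg, "cell edges must be strictly increasing")
  if (!identical(dim(object@counts),
                 c(length(object@lonEdges) - 1L, length(object@latEdges) - 1L)))
    msg <- c(msg, "counts must be [nlon-1, nlat-1]")
  if (!object@transform %in% c("raw", "log_n", "sqrt_n"))
    msg <- c(msg, "transform must be raw, log_n or sqrt_n")
  if (length(msg)) msg else TRUE
})

#' PrimerAssay: a primer pair for in-silico PCR
#'
#' Defaults to the herring-specific mt16S pair used for quantitative
#' detection of herring larvae in predator stomachs (forward
#' CGCCCACCAATCACGAA, reverse ACGTTTGTGCCAGTATCACGTT, amplifying a 69 bp
#' fragment of the mitochondrial 16S rRNA gene).
#'
#' @slot forward,reverse primer sequences, 5'->3', IUPAC alphabet.
#' @slot maxMismatches mismatches tolerated per primer site (default 0).
#' @seealso [PrimerAssay()], [inSilicoPCR()]
#' @exportClass PrimerAssay
setClass("PrimerAssay",
  slots = c(forward = "character", reverse = "character",
            maxMismatches = "numeric")
)

setValidity("PrimerAssay", function(object) {
  msg <- character()
  iupac <- "^[ACGTUMRWSYKVHDBN]+$"
  for (side in c("forward", "reverse")) {
    s <- slot(object, side)
    if (length(s) != 1 || nchar(s) == 0 || !grepl(iupac, toupper(s)))
      msg <- c(msg, sprintf("%s primer must be a non-empty IUPAC nucleotide string", side))
  }
  if (object@maxMismatches < 0)
    msg <- c(msg, "maxMismatches must be >= 0")
  if (length(msg)) msg else TRUE
})

#' StationTestResult: one-way ANOVA with Tukey HSD across stations
#'
#' @slot year survey year the test refers to (NA if unspecified).
#' @slot F,p F statistic and p-value of the one-way ANOVA on
#'   log10(copies + 1).
#' @slot dfBetween,dfWithin degrees of freedom (k - 1, n - k).
#' @slot tukey data.frame of pairwise Tukey HSD comparisons
#'   (station1, station2, diff, lwr, upr, p_adj).
#' @slot diagnostics list with residual normality (Shapiro-Wilk) and
#'   homoscedasticity (Bartlett) summaries.
#' @slot excluded station labels dropped for having < 2 observations.
#' @seealso [stationAnova()]
#' @exportClass StationTestResult
setClass("StationTestResult",
  slots = c(
    year = "numeric", F = "numeric", dfBetween = "numeric",
    dfWithin = "numeric", p = "numeric", tukey = "data.frame",
    diagnostics = "list", excluded = "character"
  )
)

#' CorrelationResult: Pearson correlation with a predictor
#'
#' @slot r,t,df,p Pearson correlation coefficient, t statistic,
#'   degrees of freedom (n - 2) and two-sided p-value.
#' @slot label the predictor tested (e.g. "fish_weight").
#' @slot n number of complete observation pairs.
#' @seealso [pearsonPredictorCor()]
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  slots = c(r = "numeric", t = "numeric", df = "numeric", p = "numeric",
            label = "character", n = "numeric")
)

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (abs(object@r) > 1 + 1e-12) msg <- c(msg, "|r| must be <= 1")
  if (object@df != object@n - 2) msg <- c(msg, "df must equal n - 2")
  if (length(msg)) msg else TRUE
})
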