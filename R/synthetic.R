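## Synthetic-data generators: an idealized northward coastal-jet flow
## field, droplet partition data at known concentration, and a two-year
## multi-station stomach survey with lognormal station effects. Every
## generator is deterministic under its seed.

#' Default scenario configuration
#'
#' Bundles the tunable parameters of the synthetic study. Flow: a
#' northward coastal jet (core speed within the 0.15-0.40 m/s band
#' typical of the Norwegian Coastal Current, capped at 1 m/s) with
#' optional rotational eddies. Survey: two years, 11 and 9 stations, 8
#' fish per station, 5 replicate subsamples per stomach; station effects
#' lognormal on the log10 scale with fish-level sigma 0.5 and
#' replicate-level sigma 0.2; 7% empty stomachs retaining a weak residual
#' DNA signal. Droplets: ~20,000 droplets of 0.85 nL per well.
#'
#' @param seed RNG seed.
#' @param ... overrides for any listed element.
#' @return a named list (class "scenarioConfig").
#' @export
scenarioConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    ## flow field
    jet_speed = 0.35,       # core speed, m/s
    jet_width = 1.5,        # cross-shore Gaussian width, degrees lon
    jet_offset = 3.0,       # core distance west of the coast, degrees
    eddy_amplitude = 0,     # streamfunction amplitude, m^2/s
    n_eddies = 2,
    coast_lon = 13,         # idealized meridional coastline
    max_speed = 1.0,        # NCC maximum speed cap
    lon = seq(0, 16, by = 0.25),
    lat = seq(61, 74, by = 0.2),
    depth = c(0, 50),
    ## survey
    years = c(2017, 2018),
    stations_per_year = c(11, 9),
    fish_per_station = 8,
    replicates = 5,
    base_log10_copies = 7.3,   # median copies/g across stations
    station_sd_log10 = 0.6,    # between-station effect size
    fish_sd_log10 = 0.5,
    replicate_sd_log10 = 0.2,
    empty_prob = 0.07,
    empty_residual_factor = 1e-3,  # residual signal in empty stomachs
    ## droplet wells
    droplets_per_well = 20000,
    v_droplet_nl = DDPCR_DEFAULTS$v_droplet_nl,
    dilutions = c(1, 10, 40, 100),
    ## visual detection (saturating in true copies)
    visual_max_mean = 4,
    visual_half_sat = 5e7,
    ## plankton / trawl scenario
    patch_density = 60,        # per 10 m^3, the high-density patch
    background_density = 3,    # median background, per 10 m^3
    trawl_median_density = 1000,  # kg/NM^2
    trawl_sd_log10 = 0.7,
    tow_distance = 2.2,        # NM (~30 min at 4.5 knots)
    effective_width = 0.012    # NM, per-gear configuration
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown scenario parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$station_sd_log10 >= 0, cfg$fish_sd_log10 >= 0,
            cfg$replicate_sd_log10 >= 0,
            cfg$empty_prob >= 0, cfg$empty_prob <= 1)
  structure(cfg, class = "scenarioConfig")
}

#' Generate an idealized coastal-jet flow field
#'
#' A northward jet with a cross-shore Gaussian profile west of an
#' idealized meridional coastline, with optional superposed rotational
#' eddies. The jet (v depends on longitude only, u = 0) is exactly
#' non-divergent; eddy velocities are derived from a streamfunction by
#' central differences, so the discrete horizontal divergence vanishes to
#' rounding in the interior. Land cells (east of the coastline) are
#' masked with zero velocity.
#'
#' @param cfg a [scenarioConfig()] (flow parameters and seed are used).
#' @param dates Date vector of daily means (default 90 days from
#'   2017-03-15).
#' @return a [FlowField-class].
#' @export
genFlowField <- function(cfg = scenarioConfig(),
                         dates = seq(as.Date("2017-03-15"),
                                     by = "day", length.out = 90)) {
  if (cfg$jet_speed > cfg$max_speed)
    stop(sprintf("jet core speed %.2f m/s exceeds the %.2f m/s cap",
                 cfg$jet_speed, cfg$max_speed))
  lon <- cfg$lon; lat <- cfg$lat; depth <- cfg$depth
  nlon <- length(lon); nlat <- length(lat)
  core <- cfg$coast_lon - cfg$jet_offset
  vJet <- cfg$jet_speed * exp(-((lon - core) / cfg$jet_width)^2)
  v2d <- matrix(vJet, nlon, nlat)
  u2d <- matrix(0, nlon, nlat)

  if (cfg$eddy_amplitude > 0 && cfg$n_eddies > 0) {
    ## streamfunction on the grid; u = -dpsi/dy, v = +dpsi/dx by central
    ## differences (one-sided at the edges)
    psi <- matrix(0, nlon, nlat)
    centers <- withr::with_seed(cfg$seed, data.frame(
      lon = runif(cfg$n_eddies, core - 2, core + 1),
      lat = runif(cfg$n_eddies, min(lat) + 2, max(lat) - 2),
      sgn = sample(c(-1, 1), cfg$n_eddies, replace = TRUE)
    ))
    for (e in seq_len(cfg$n_eddies)) {
      d2 <- outer((lon - centers$lon[e])^2, (lat - centers$lat[e])^2, "+")
      psi <- psi + centers$sgn[e] * cfg$eddy_amplitude * exp(-d2 / 0.8^2)
    }
    mPerLat <- EARTH_RADIUS_M * pi / 180
    dy <- diff(lat[1:2]) * mPerLat
    dxRow <- diff(lon[1:2]) * mPerLat * cos(lat * pi / 180)
    dPsiDx <- psi * 0; dPsiDy <- psi * 0
    dPsiDx[2:(nlon - 1), ] <- (psi[3:nlon, ] - psi[1:(nlon - 2), ]) / 2
    dPsiDx <- sweep(dPsiDx, 2, dxRow, "/")
    dPsiDy[, 2:(nlat - 1)] <- (psi[, 3:nlat] - psi[, 1:(nlat - 2)]) / (2 * dy)
    u2d <- u2d - dPsiDy
    v2d <- v2d + dPsiDx
  }
  spd <- sqrt(u2d^2 + v2d^2)
  if (max(spd) > cfg$max_speed) {
    scale <- cfg$max_speed / max(spd)
    u2d <- u2d * scale; v2d <- v2d * scale
  }
  mask <- matrix(rep(lon >= cfg$coast_lon, nlat), nlon, nlat)
  dims <- c(nlon, nlat, length(depth), length(dates))
  u <- array(rep(u2d, length(depth) * length(dates)), dims)
  v <- array(rep(v2d, length(depth) * length(dates)), dims)
  FlowField(lon, lat, depth, dates, u, v, mask = mask,
            maxSpeed = cfg$max_speed)
}

#' Generate one droplet reaction at known concentration
#'
#' In "poisson" mode each droplet is positive independently with
#' probability \code{1 - exp(-lambda)} where \code{lambda} is the mean
#' copies per droplet. In "multinomial" mode individual molecules (their
#' number drawn Poisson with mean \code{lambda * nDroplets}) are dropped
#' uniformly into droplets and a droplet is positive when it holds at
#' least one molecule: the brute-force partitioning oracle the Poisson
#' estimator is validated against. The two modes agree in distribution.
#'
#' @param trueConc true concentration, copies per ul of reaction.
#' @param nDroplets droplets in the well (default 20000).
#' @param vDropletNl droplet volume in nL (default 0.85).
#' @param mode "poisson" or "multinomial".
#' @param seed optional RNG seed.
#' @return one-row data.frame: n_total, n_positive, true_conc, lambda.
#' @export
genDropletData <- function(trueConc, nDroplets = 20000,
                           vDropletNl = DDPCR_DEFAULTS$v_droplet_nl,
                           mode = c("poisson", "multinomial"),
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(trueConc >= 0, nDroplets > 0, vDropletNl > 0)
  lambda <- trueConc * vDropletNl / 1000
  draw <- function() {
    if (mode == "poisson") {
      rbinom(1, nDroplets, 1 - exp(-lambda))
    } else {
      m <- rpois(1, lambda * nDroplets)
      if (m == 0) 0L else {
        occupied <- tabulate(sample.int(nDroplets, m, replace = TRUE),
                             nbins = nDroplets)
        sum(occupied > 0)
      }
    }
  }
  nPos <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data.frame(n_total = nDroplets, n_positive = nPos,
             true_conc = trueConc, lambda = lambda)
}

## Pick the smallest printed dilution keeping the well out of saturation
## (target < ~0.8 positive fraction); returns the largest dilution if
## even that saturates.
chooseDilution <- function(concUndiluted, dilutions, vDropletNl) {
  for (d in sort(dilutions)) {
    lambda <- concUndiluted / d * vDropletNl / 1000
    if (1 - exp(-lambda) < 0.8) return(d)
  }
  max(dilutions)
}

#' Generate a complete synthetic stomach survey
#'
#' Emulates the study layout: two survey years with 11 and 9 trawl
#' stations, up to ten fish per station (default 8), five replicate
#' subsamples per stomach. Per-station true copies per gram are drawn
#' lognormal with the configured between-station effect; fish-level and
#' replicate-level lognormal noise is added; droplet counts are produced
#' by inverting the ddPCR normalization chain (auto-selecting the
#' template dilution from the printed 1/10/40/100 series); empty stomachs
#' occur at the configured probability and keep a weak residual DNA
#' signal (their tissue weight is set to 0.01 g downstream). Visual
#' counts are Poisson with a detection mean saturating in true copies.
#' Plankton and trawl tables share the station set; one station per year
#' carries a high-density larval patch, and trawl densities are lognormal
#' around the configured median.
#'
#' @param cfg a [scenarioConfig()].
#' @return list of data.frames: stomachs, subsamples, droplets, visual,
#'   plankton, trawl, and truth tables (stations, fish, replicates).
#' @export
genStomachSurvey <- function(cfg = scenarioConfig()) {
  withr::with_seed(cfg$seed, genStomachSurveyImpl(cfg))
}

genStomachSurveyImpl <- function(cfg) {
  stomachs <- subsamples <- droplets <- visual <- list()
  plankton <- trawl <- list()
  truthStations <- truthFish <- truthReps <- list()
  stationLetters <- LETTERS
  sIdx <- 0
  for (yi in seq_along(cfg$years)) {
    year <- cfg$years[yi]
    nSt <- cfg$stations_per_year[yi]
    ids <- stationLetters[sIdx + seq_len(nSt)]
    sIdx <- sIdx + nSt
    stLog10 <- cfg$base_log10_copies +
      rnorm(nSt, 0, cfg$station_sd_log10)
    stLat <- sort(runif(nSt, 66, 72), decreasing = TRUE)
    stLon <- runif(nSt, 8, 11.5)
    patchStation <- which.max(stLog10)
    for (si in seq_len(nSt)) {
      st <- ids[si]
      ## plankton + trawl station records
      dens <- if (si == patchStation) cfg$patch_density else
        cfg$background_density * 10^rnorm(1, 0, 0.5)
      vol <- runif(1, 120, 400)
      plankton[[length(plankton) + 1]] <- data.frame(
        station_id = st, year = year, lon = stLon[si], lat = stLat[si],
        larval_count = rpois(1, dens * vol / 10),
        filtered_volume = vol, stringsAsFactors = FALSE)
      sweptDens <- cfg$trawl_median_density * 10^rnorm(1, 0, cfg$trawl_sd_log10)
      trawl[[length(trawl) + 1]] <- data.frame(
        station_id = st, year = year, lon = stLon[si], lat = stLat[si],
        catch_weight = sweptDens * cfg$tow_distance * cfg$effective_width,
        tow_distance = cfg$tow_distance,
        effective_width = cfg$effective_width, stringsAsFactors = FALSE)

      fishLog10 <- stLog10[si] + rnorm(cfg$fish_per_station, 0,
                                       cfg$fish_sd_log10)
      empty <- runif(cfg$fish_per_station) < cfg$empty_prob
      fishTrueCpg <- numeric(cfg$fish_per_station)
      for (fi in seq_len(cfg$fish_per_station)) {
        sid <- sprintf("%s%d-%02d", st, year %% 100, fi)
        fishWeight <- rlnorm(1, log(400), 0.2)
        contentWeight <- if (empty[fi]) 0.01 else rlnorm(1, log(4), 0.7)
        cpgFish <- 10^fishLog10[fi] *
          if (empty[fi]) cfg$empty_residual_factor else 1
        repCpg <- cpgFish * 10^rnorm(cfg$replicates, 0,
                                     cfg$replicate_sd_log10)
        fishTrueCpg[fi] <- mean(repCpg)
        stomachs[[length(stomachs) + 1]] <- data.frame(
          stomach_id = sid, station_id = st, year = year,
          fish_weight = fishWeight, content_weight = contentWeight,
          empty = empty[fi], stringsAsFactors = FALSE)
        for (ri in seq_len(cfg$replicates)) {
          wet <- max(rnorm(1, 0.2, 0.02), 0.05)
          tg <- if (empty[fi]) DDPCR_DEFAULTS$empty_tissue_g else
            tissueWeight(wet)
          subsamples[[length(subsamples) + 1]] <- data.frame(
            stomach_id = sid, replicate = ri, wet_weight = wet,
            pbs_ratio = DDPCR_DEFAULTS$pbs_ratio,
            v_elution = DDPCR_DEFAULTS$v_elution, stringsAsFactors = FALSE)
          ## invert the normalization chain: copies/g -> copies/ul rxn
          perUlExtract <- repCpg[ri] * tg / DDPCR_DEFAULTS$v_elution
          concUndiluted <- perUlExtract *
            DDPCR_DEFAULTS$v_template / DDPCR_DEFAULTS$v_reaction
          dil <- chooseDilution(concUndiluted, cfg$dilutions,
                                cfg$v_droplet_nl)
          concRxn <- concUndiluted / dil
          nDrop <- round(rnorm(1, cfg$droplets_per_well, 800))
          nDrop <- min(max(nDrop, 14000), 20500)
          well <- genDropletData(concRxn, nDrop, cfg$v_droplet_nl)
          droplets[[length(droplets) + 1]] <- data.frame(
            well_id = sprintf("%s-r%d", sid, ri), stomach_id = sid,
            replicate = ri, n_total = well$n_total,
            n_positive = well$n_positive, dilution = dil,
            stringsAsFactors = FALSE)
          truthReps[[length(truthReps) + 1]] <- data.frame(
            stomach_id = sid, replicate = ri, true_copies_per_g = repCpg[ri],
            true_conc_reaction = concRxn, dilution = dil,
            stringsAsFactors = FALSE)
        }
        detMean <- cfg$visual_max_mean * cpgFish /
          (cpgFish + cfg$visual_half_sat)
        visual[[length(visual) + 1]] <- data.frame(
          stomach_id = sid, station_id = st, year = year,
          larvae_seen = rpois(1, detMean),
          otoliths_seen = rpois(1, 0.4 * detMean), stringsAsFactors = FALSE)
        truthFish[[length(truthFish) + 1]] <- data.frame(
          stomach_id = sid, station_id = st, year = year,
          true_copies_per_g = fishTrueCpg[fi], empty = empty[fi],
          stringsAsFactors = FALSE)
      }
      truthStations[[length(truthStations) + 1]] <- data.frame(
        station_id = st, year = year,
        configured_log10_mean = stLog10[si],
        ## geometric mean over fish of per-fish mean replicate copies:
        ## the quantity the estimation chain can recover
        true_geomean_copies_per_g = exp(mean(log(fishTrueCpg))),
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(l) {
    out <- do.call(rbind, l); rownames(out) <- NULL; out
  }
  list(stomachs = bind(stomachs), subsamples = bind(subsamples),
       droplets = bind(droplets), visual = bind(visual),
       plankton = bind(plankton), trawl = bind(trawl),
       truth = list(stations = bind(truthStations), fish = bind(truthFish),
                    replicates = bind(truthReps)))
}
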