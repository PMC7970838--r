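## Survey statistics: larval densities, swept-area predator biomass,
## station-effect ANOVA with Tukey HSD on log-transformed gene copies,
## predictor correlations, leverage diagnostics and overlap summaries.

#' Larval density from a plankton haul
#'
#' @param count larvae counted in the haul (vectorized).
#' @param filteredVolume water volume filtered, m^3 (from flowmeter
#'   readings).
#' @return density in individuals per 10 m^3.
#' @examples
#' larvalDensity(50, 100)  # 5 per 10 m^3
#' @export
larvalDensity <- function(count, filteredVolume) {
  if (any(filteredVolume <= 0))
    stop("filtered volume must be positive")
  if (any(count < 0)) stop("larval counts must be non-negative")
  10 * count / filteredVolume
}

#' Swept-area biomass density from a trawl haul
#'
#' @param catchWeight catch in kg (vectorized).
#' @param towDistance tow distance in nautical miles.
#' @param effectiveWidth effective gear width in nautical miles (a
#'   per-gear configuration value).
#' @return biomass density in kg per square nautical mile.
#' @examples
#' sweptAreaDensity(100, 1, 0.01)  # 10000 kg/NM^2
#' @export
sweptAreaDensity <- function(catchWeight, towDistance, effectiveWidth) {
  if (any(towDistance <= 0) || any(effectiveWidth <= 0))
    stop("tow distance and effective width must be positive")
  catchWeight / (towDistance * effectiveWidth)
}

#' One-way station ANOVA with Tukey HSD on gene copies
#'
#' Tests for differences in mt16S gene copies per gram between sampling
#' stations. The response is log10(copies + 1) (the raw copies violate
#' normality; +1 keeps below-detection stomachs defined). Stations with
#' fewer than two stomachs are excluded with a warning. Residual
#' diagnostics (Shapiro-Wilk normality, Bartlett homoscedasticity) are
#' attached.
#'
#' @param copies numeric vector of copies per gram (one value per
#'   stomach, the replicate mean).
#' @param station station labels, same length.
#' @param year optional survey year recorded in the result.
#' @return a [StationTestResult-class].
#' @export
stationAnova <- function(copies, station, year = NA) {
  stopifnot(length(copies) == length(station))
  station <- as.character(station)
  tab <- table(station)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding station(s) with < 2 stomachs: ",
            paste(small, collapse = ", "))
    keep <- !station %in% small
    copies <- copies[keep]; station <- station[keep]
  }
  if (length(unique(station)) < 2)
    stop("need at least 2 stations with >= 2 stomachs each")
  y <- log10(copies + 1)
  if (sd(y) == 0)
    stop("all responses identical; F is undefined")
  df <- data.frame(y = y, station = factor(station))
  fit <- aov(y ~ station, data = df)
  an <- anova(fit)
  tk <- TukeyHSD(fit)$station
  tukey <- data.frame(
    station1 = sub("-.*", "", rownames(tk)),
    station2 = sub(".*-", "", rownames(tk)),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"], stringsAsFactors = FALSE, row.names = NULL)
  res <- residuals(fit)
  diag <- list(
    shapiro_p = if (length(res) >= 3 && length(res) <= 5000)
      shapiro.test(res)$p.value else NA_real_,
    bartlett_p = tryCatch(bartlett.test(y ~ station, data = df)$p.value,
                          error = function(e) NA_real_),
    residual_sd = sd(res)
  )
  new("StationTestResult",
      year = as.numeric(year),
      F = unname(an$`F value`[1]),
      dfBetween = an$Df[1], dfWithin = an$Df[2],
      p = unname(an$`Pr(>F)`[1]),
      tukey = tukey, diagnostics = diag,
      excluded = as.character(small))
}

#' Pearson correlation between gene copies and a predator parameter
#'
#' @param copies copies per gram per stomach.
#' @param predictor predictor values (e.g. fish weight or stomach content
#'   weight), same length; pairs with missing values are dropped.
#' @param label predictor label recorded in the result.
#' @return a [CorrelationResult-class] with r, t, df = n - 2 and the
#'   two-sided p-value.
#' @export
pearsonPredictorCor <- function(copies, predictor, label = "predictor") {
  stopifnot(length(copies) == length(predictor))
  ok <- complete.cases(copies, predictor)
  copies <- copies[ok]; predictor <- predictor[ok]
  n <- length(copies)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(predictor) == 0) stop("predictor is constant")
  if (sd(copies) == 0) stop("response is constant")
  ct <- suppressWarnings(cor.test(predictor, copies, method = "pearson"))
  new("CorrelationResult",
      r = unname(ct$estimate), t = unname(ct$statistic),
      df = unname(ct$parameter), p = ct$p.value,
      label = label, n = n)
}

#' Leverage of each point in a simple linear regression
#'
#' Hat-matrix diagonal \code{h_i = 1/n + (x_i - xbar)^2 / sum((x - xbar)^2)};
#' the leverages always sum to 2 (intercept + slope).
#'
#' @param x predictor values.
#' @return numeric vector of leverages.
#' @export
simpleLeverage <- function(x) {
  n <- length(x)
  ss <- sum((x - mean(x))^2)
  if (ss == 0) stop("predictor is constant; leverage undefined")
  1 / n + (x - mean(x))^2 / ss
}

#' Compare visual stomach inspection with the molecular signal
#'
#' Correlates copies per gram with visually counted larvae, otoliths and
#' their pooled sum, and attaches leverage diagnostics for the regression
#' of copies on the pooled count. Points with leverage above twice the
#' average (2 * 2/n) are flagged high-leverage; they are reported, never
#' dropped.
#'
#' @param visual data.frame with stomach_id, larvae_seen, otoliths_seen.
#' @param copies data.frame with stomach_id, copies_per_g (e.g. from
#'   [copiesPerGram()]).
#' @return list with \code{correlations} (list of
#'   [CorrelationResult-class] for larvae/otoliths/pooled) and
#'   \code{leverage} (data.frame stomach_id, pooled, leverage,
#'   high_leverage).
#' @export
visualVsMolecular <- function(visual, copies) {
  stopifnot(all(c("stomach_id", "larvae_seen", "otoliths_seen") %in%
                  names(visual)))
  stopifnot(all(c("stomach_id", "copies_per_g") %in% names(copies)))
  m <- merge(visual, copies[, c("stomach_id", "copies_per_g")],
             by = "stomach_id")
  if (nrow(m) == 0) stop("no common stomach ids between the two tables")
  m$pooled <- m$larvae_seen + m$otoliths_seen
  cors <- list(
    larvae = pearsonPredictorCor(m$copies_per_g, m$larvae_seen,
                                 "larvae_seen"),
    otoliths = pearsonPredictorCor(m$copies_per_g, m$otoliths_seen,
                                   "otoliths_seen"),
    pooled = pearsonPredictorCor(m$copies_per_g, m$pooled, "pooled")
  )
  h <- simpleLeverage(m$pooled)
  lev <- data.frame(stomach_id = m$stomach_id, pooled = m$pooled,
                    leverage = h,
                    high_leverage = h > 2 * (2 / nrow(m)),
                    stringsAsFactors = FALSE)
  list(correlations = cors, leverage = lev)
}

#' Schoener's D overlap between two normalized distributions
#'
#' \code{D = 1 - 0.5 * sum(|p_i - q_i|)} after normalizing both inputs to
#' sum to 1. D is 0 for disjoint and 1 for identical distributions. This
#' index is an extension for summarizing predator-prey spatial overlap on
#' a common grid.
#'
#' @param p,q non-negative vectors or matrices on the same cells.
#' @return overlap in [0, 1].
#' @examples
#' schoenersD(c(1, 0, 0), c(0, 0, 1))  # 0
#' @export
schoenersD <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (sum(p) == 0 || sum(q) == 0)
    stop("distributions must have positive mass")
  p <- p / sum(p); q <- q / sum(q)
  1 - 0.5 * sum(abs(p - q))
}

#' Per-station overlap of larvae, predators and predation signal
#'
#' Joins larval densities, swept-area predator biomass and mean copies
#' per gram by station, the tabular counterpart of overlaying the three
#' survey layers on a map.
#'
#' @param plankton data.frame with station_id, larval_count,
#'   filtered_volume (or a precomputed larval_density column).
#' @param trawl data.frame with station_id, catch_weight, tow_distance,
#'   effective_width (or a precomputed swept_density column).
#' @param copies data.frame with station_id, copies_per_g per stomach.
#' @return data.frame per station: larval_density (per 10 m^3),
#'   predator_density (kg/NM^2), mean_copies_per_g, n_stomachs.
#' @export
overlapSummary <- function(plankton, trawl, copies) {
  if (!"larval_density" %in% names(plankton))
    plankton$larval_density <- larvalDensity(plankton$larval_count,
                                             plankton$filtered_volume)
  if (!"swept_density" %in% names(trawl))
    trawl$swept_density <- sweptAreaDensity(trawl$catch_weight,
                                            trawl$tow_distance,
                                            trawl$effective_width)
  pl <- aggregate(larval_density ~ station_id, plankton, mean)
  tr <- aggregate(swept_density ~ station_id, trawl, mean)
  cp <- aggregate(copies_per_g ~ station_id, copies, mean)
  ncp <- aggregate(copies_per_g ~ station_id, copies, length)
  names(cp)[2] <- "mean_copies_per_g"
  names(tr)[2] <- "predator_density"
  names(ncp)[2] <- "n_stomachs"
  out <- merge(merge(pl, tr, by = "station_id"),
               merge(cp, ncp, by = "station_id"), by = "station_id")
  if (nrow(out) == 0)
    stop("no stations common to the larval, trawl and copies tables")
  out
}
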