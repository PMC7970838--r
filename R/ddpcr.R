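## Droplet digital PCR quantification chain: droplet-count QC, Poisson
## partition statistics, and normalization to mt16S gene copies per gram
## of stomach content.

DDPCR_DEFAULTS <- list(
  v_template = 5.5,    # ul template added per reaction
  v_reaction = 22,     # ul final reaction volume
  v_droplet_nl = 0.85, # droplet volume, nL (QX200 convention)
  v_elution = 150,     # ul DNA eluate per subsample (midpoint of 100-200)
  pbs_ratio = 3,       # volumes buffer per volume stomach content
  qc_min_droplets = 13000,
  qc_max_droplets = 21000,
  min_negative_droplets = 30,  # fewer negatives -> saturated
  empty_tissue_g = 0.01        # nominal tissue weight of an empty stomach
)

#' Droplet-count quality control
#'
#' A reaction passes when its accepted droplet count lies in the
#' [13,000, 21,000] band (theoretical ideal 20,000 droplets per reaction);
#' wells outside the band are flagged \code{qc_droplet_count} and should
#' be repeated. Boundaries are inclusive.
#'
#' @param nTotal accepted droplets per well (vectorized).
#' @param minDroplets,maxDroplets QC band (defaults 13000 / 21000).
#' @return character vector, "pass" or "qc_droplet_count".
#' @examples
#' qcReaction(c(12999, 13000, 21000, 21001))
#' @export
qcReaction <- function(nTotal,
                       minDroplets = DDPCR_DEFAULTS$qc_min_droplets,
                       maxDroplets = DDPCR_DEFAULTS$qc_max_droplets) {
  ifelse(nTotal < minDroplets | nTotal > maxDroplets,
         "qc_droplet_count", "pass")
}

#' Poisson concentration from droplet counts
#'
#' Template molecules partition into droplets approximately Poisson, so
#' the concentration in the reaction is \code{-ln(1 - p) / v} copies/ul,
#' with \code{p} the positive-droplet fraction and \code{v} the droplet
#' volume in ul. Wells with no positive droplets return 0 and are flagged
#' \code{below_detection}; wells with fewer than \code{minNegatives}
#' negative droplets are evaluated at that threshold and flagged
#' \code{saturated} (the value is a lower bound; such wells are repeated
#' at higher template dilution).
#'
#' @param nPositive,nTotal positive / accepted droplet counts
#'   (vectorized).
#' @param vDropletNl droplet volume in nL (default 0.85).
#' @param minNegatives saturation threshold on negative droplets.
#' @return data.frame with columns \code{conc} (copies per ul of
#'   reaction) and \code{flag} ("" | below_detection | saturated).
#' @examples
#' poissonConcentration(10000, 20000)   # ~815.5 copies/ul
#' @export
poissonConcentration <- function(nPositive, nTotal,
                                 vDropletNl = DDPCR_DEFAULTS$v_droplet_nl,
                                 minNegatives = DDPCR_DEFAULTS$min_negative_droplets) {
  if (any(nTotal <= 0))
    stop("reaction with zero accepted droplets cannot be quantified")
  if (any(nPositive < 0 | nPositive > nTotal))
    stop("n_positive must lie in [0, n_total]")
  vUl <- vDropletNl / 1000
  sat <- (nTotal - nPositive) < minNegatives
  p <- ifelse(sat, (nTotal - minNegatives) / nTotal, nPositive / nTotal)
  conc <- -log(1 - p) / vUl
  conc[nPositive == 0] <- 0
  flag <- rep("", length(conc))
  flag[nPositive == 0] <- "below_detection"
  flag[sat] <- "saturated"
  data.frame(conc = conc, flag = flag, stringsAsFactors = FALSE)
}

## Tissue weight of a subsample after removing homogenization buffer:
## wet weight includes `ratio` volumes of buffer per volume of content
## (buffer density ~ 1 g/mL).
tissueWeight <- function(wetWeight, pbsRatio = DDPCR_DEFAULTS$pbs_ratio) {
  wetWeight / (1 + pbsRatio)
}

#' Normalize droplet counts to gene copies per gram stomach content
#'
#' Runs the full normalization chain per replicate subsample and averages
#' replicates per stomach (arithmetic mean on the copies-per-gram scale):
#' \deqn{copies/g = \frac{-\ln(1-p)}{v_{droplet}} \cdot
#'   \frac{v_{reaction}}{v_{template}} \cdot dilution \cdot v_{elution}
#'   / tissue_g}
#' with \code{tissue_g = wet_weight / (1 + pbs_ratio)}, or 0.01 g for
#' stomachs recorded as empty (so empty stomachs with residual DNA still
#' yield a defined value). Replicates failing droplet-count QC are
#' excluded; an error lists the wells if every replicate of a stomach
#' fails. Below-detection replicates enter the mean as 0 by default.
#'
#' @param droplets data.frame with columns well_id, stomach_id,
#'   replicate, n_total, n_positive, dilution; optional v_template,
#'   v_reaction, v_droplet_nl.
#' @param subsamples data.frame with stomach_id, replicate, wet_weight;
#'   optional pbs_ratio, v_elution.
#' @param stomachs data.frame with stomach_id, station_id, year,
#'   fish_weight, content_weight, empty.
#' @param belowDetection "include" (as 0, default) or "exclude" from the
#'   replicate mean.
#' @return data.frame (one row per stomach): stomach_id, station_id,
#'   year, copies_per_ul_reaction, copies_per_g, n_replicates, flags
#'   (comma-separated union over replicates).
#' @examples
#' d <- data.frame(well_id = "A1", stomach_id = "s1", replicate = 1,
#'                 n_total = 20000, n_positive = 20000 * (1 - exp(-0.085)),
#'                 dilution = 10)
#' s <- data.frame(stomach_id = "s1", replicate = 1, wet_weight = 0.2)
#' st <- data.frame(stomach_id = "s1", station_id = "A", year = 2017,
#'                  fish_weight = 400, content_weight = 4, empty = FALSE)
#' copiesPerGram(d, s, st)$copies_per_g   # 1.2e7
#' @export
copiesPerGram <- function(droplets, subsamples, stomachs,
                          belowDetection = c("include", "exclude")) {
  belowDetection <- match.arg(belowDetection)
  need <- c("well_id", "stomach_id", "replicate", "n_total", "n_positive",
            "dilution")
  if (!all(need %in% names(droplets)))
    stop("droplet table must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(c("stomach_id", "replicate", "wet_weight") %in%
                  names(subsamples)))
  stopifnot(all(c("stomach_id", "empty") %in% names(stomachs)))

  d <- merge(droplets, subsamples, by = c("stomach_id", "replicate"))
  if (nrow(d) < nrow(droplets))
    stop("droplet wells without a matching subsample record")
  if (is.null(d$v_template)) d$v_template <- DDPCR_DEFAULTS$v_template
  if (is.null(d$v_reaction)) d$v_reaction <- DDPCR_DEFAULTS$v_reaction
  if (is.null(d$v_droplet_nl)) d$v_droplet_nl <- DDPCR_DEFAULTS$v_droplet_nl
  if (is.null(d$v_elution)) d$v_elution <- DDPCR_DEFAULTS$v_elution
  if (is.null(d$pbs_ratio)) d$pbs_ratio <- DDPCR_DEFAULTS$pbs_ratio

  d$qc <- qcReaction(d$n_total)
  pc <- poissonConcentration(d$n_positive, d$n_total,
                             vDropletNl = d$v_droplet_nl[1])
  d$conc <- pc$conc
  d$pois_flag <- pc$flag

  out <- lapply(split(d, d$stomach_id), function(sd) {
    srow <- stomachs[match(sd$stomach_id[1], stomachs$stomach_id), ]
    if (is.na(srow$stomach_id))
      stop("no stomach record for ", sd$stomach_id[1])
    ok <- sd$qc == "pass"
    if (!any(ok))
      stop("all replicates failed droplet-count QC for stomach ",
           sd$stomach_id[1], " (wells ",
           paste(sd$well_id, collapse = ", "), ")")
    flags <- unique(c(sd$pois_flag[ok], sd$qc[!ok]))
    sd <- sd[ok, , drop = FALSE]
    if (belowDetection == "exclude" && any(sd$n_positive > 0))
      sd <- sd[sd$n_positive > 0, , drop = FALSE]
    tg <- if (isTRUE(srow$empty)) DDPCR_DEFAULTS$empty_tissue_g else
      tissueWeight(sd$wet_weight, sd$pbs_ratio)
    if (any(tg <= 0))
      stop("nonpositive tissue weight for stomach ", sd$stomach_id[1])
    perUlExtract <- sd$conc * (sd$v_reaction / sd$v_template) * sd$dilution
    perG <- perUlExtract * sd$v_elution / tg
    data.frame(
      stomach_id = sd$stomach_id[1],
      station_id = if ("station_id" %in% names(srow)) srow$station_id else NA,
      year = if ("year" %in% names(srow)) srow$year else NA,
      copies_per_ul_reaction = mean(sd$conc),
      copies_per_g = mean(perG),
      n_replicates = nrow(sd),
      flags = paste(setdiff(flags, ""), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Check plate controls of a ddPCR run
#'
#' Every run must carry at least one no-template control (NTC), one
#' positive control and one negative control. Any NTC/negative/blank well
#' with positive droplets above \code{tolerance} marks the run
#' \code{contamination_suspect}; a positive control without positive
#' droplets invalidates the run.
#'
#' @param wells data.frame with columns well_id, role (one of sample,
#'   ntc, positive, negative, blank), n_total, n_positive.
#' @param tolerance positive droplets tolerated in control wells
#'   (default 2).
#' @return list with elements \code{valid}, \code{contamination_suspect}
#'   and \code{details} (the offending control wells).
#' @export
checkControls <- function(wells, tolerance = 2) {
  stopifnot(all(c("well_id", "role", "n_positive") %in% names(wells)))
  roles <- tolower(wells$role)
  if (!any(roles == "ntc"))
    stop("run is missing a no-template control (NTC)")
  if (!any(roles == "positive"))
    stop("run is missing a positive control")
  contam <- roles %in% c("ntc", "negative", "blank") &
    wells$n_positive > tolerance
  posDead <- roles == "positive" & wells$n_positive == 0
  list(
    valid = !any(posDead),
    contamination_suspect = any(contam),
    details = wells[contam | posDead, c("well_id", "role", "n_positive"),
                    drop = FALSE]
  )
}

#' Final primer concentration in a reaction
#'
#' @param amountPmol primer amount per reaction in pmol.
#' @param volumeUl final reaction volume in ul.
#' @return final concentration in nM (pmol/ul = uM; times 1000).
#' @examples
#' primerFinalConcentration(2.2, 22)  # 100 nM
#' @export
primerFinalConcentration <- function(amountPmol, volumeUl) {
  stopifnot(volumeUl > 0)
  amountPmol / volumeUl * 1000
}
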