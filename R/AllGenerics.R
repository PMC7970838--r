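## Accessors and show methods for the S4 containers.

#' @describeIn FlowField-class longitude axis (degrees east)
#' @param object a FlowField
#' @export
setGeneric("lonAxis", function(object) standardGeneric("lonAxis"))
#' @describeIn FlowField-class latitude axis (degrees north)
#' @export
setGeneric("latAxis", function(object) standardGeneric("latAxis"))
#' @describeIn FlowField-class depth axis (m, positive down)
#' @export
setGeneric("depthAxis", function(object) standardGeneric("depthAxis"))
#' @describeIn FlowField-class calendar days of the daily means
#' @export
setGeneric("fieldDates", function(object) standardGeneric("fieldDates"))
#' @describeIn FlowField-class logical land mask, \code{[lon, lat]}
#' @export
setGeneric("landMask", function(object) standardGeneric("landMask"))

setMethod("lonAxis", "FlowField", function(object) object@lon)
setMethod("latAxis", "FlowField", function(object) object@lat)
setMethod("depthAxis", "FlowField", function(object) object@depth)
setMethod("fieldDates", "FlowField", function(object) object@dates)
setMethod("landMask", "FlowField", function(object) object@mask)

setMethod("show", "FlowField", function(object) {
  cat(sprintf(
    "FlowField: %d x %d x %d grid over %d day(s)\n",
    length(object@lon), length(object@lat), length(object@depth),
    length(object@dates)))
  cat(sprintf("  lon %.2f..%.2f E, lat %.2f..%.2f N, depth %.0f..%.0f m\n",
              min(object@lon), max(object@lon), min(object@lat),
              max(object@lat), min(object@depth), max(object@depth)))
  cat(sprintf("  dates %s..%s; max speed %.3f m/s; %d land cell(s)\n",
              format(min(object@dates)), format(max(object@dates)),
              max(sqrt(object@u^2 + object@v^2)), sum(object@mask)))
})

#' @describeIn SimulationResult-class snapshot particle table for a date
#' @param object a SimulationResult
#' @param date a Date (or string) with a stored snapshot
#' @export
setGeneric("snapshotAt", function(object, date) standardGeneric("snapshotAt"))

setMethod("snapshotAt", "SimulationResult", function(object, date) {
  key <- format(as.Date(date))
  if (!key %in% names(object@snapshots))
    stop("no snapshot stored for ", key)
  object@snapshots[[key]]
})

#' @describeIn SimulationResult-class dates with stored snapshots
#' @export
setGeneric("snapshotDates", function(object) standardGeneric("snapshotDates"))
setMethod("snapshotDates", "SimulationResult",
          function(object) as.Date(names(object@snapshots)))

setMethod("show", "SimulationResult", function(object) {
  fs <- object@finalState
  cat(sprintf("SimulationResult: %d particles, %d snapshot(s), dt = %ds\n",
              object@released, length(object@snapshots), object@dt))
  if (nrow(fs))
    cat(sprintf("  final: %d active, %d beached, %d exited\n",
                sum(fs$status == "active"), sum(fs$status == "beached"),
                sum(fs$status == "exited")))
})

setMethod("show", "ReleaseConfig", function(object) {
  cat(sprintf("ReleaseConfig: %d particles, hatch %s..%s (mean %.1f d, sd %.2f d)\n",
              object@totalParticles, format(object@hatchStart),
              format(object@hatchEnd), object@hatchMean, object@hatchSD))
  cat(sprintf("  grounds: %s\n",
              paste(sprintf("%s (%.0f%%)", object@grounds$name,
                            100 * object@grounds$fraction), collapse = ", ")))
})

setMethod("show", "DensityGrid", function(object) {
  cat(sprintf("DensityGrid: %d x %d cells, transform = %s, total n = %d\n",
              nrow(object@counts), ncol(object@counts), object@transform,
              sum(object@counts)))
})

#' @describeIn DensityGrid-class transformed cell values
#' @param object a DensityGrid
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
setMethod("gridValues", "DensityGrid", function(object) object@values)

#' @describeIn DensityGrid-class raw cell counts
#' @export
setGeneric("gridCounts", function(object) standardGeneric("gridCounts"))
setMethod("gridCounts", "DensityGrid", function(object) object@counts)

setMethod("show", "PrimerAssay", function(object) {
  cat(sprintf("PrimerAssay: fwd 5'-%s-3', rev 5'-%s-3' (<= %d mismatch/site)\n",
              object@forward, object@reverse, object@maxMismatches))
})

setMethod("show", "StationTestResult", function(object) {
  cat(sprintf("One-way station ANOVA%s: F(%d, %d) = %.4g, p = %.4g\n",
              if (is.na(object@year)) "" else sprintf(" [%d]", object@year),
              object@dfBetween, object@dfWithin, object@F, object@p))
  sig <- sum(object@tukey$p_adj < 0.05)
  cat(sprintf("  Tukey HSD: %d of %d pairs significant at 0.05\n",
              sig, nrow(object@tukey)))
  if (length(object@excluded))
    cat("  excluded stations (< 2 obs): ",
        paste(object@excluded, collapse = ", "), "\n")
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Pearson correlation vs %s: r = %.4f, t = %.4f, df = %d, p = %.4g\n",
              object@label, object@r, object@t, object@df, object@p))
})
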