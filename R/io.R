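## Delimited-text IO for the pipeline's tables and the flow field.
## The flow field travels as two CSVs: a long-format velocity table
## (lon, lat, depth, date, u, v) and a mask table (lon, lat, land).

#' Write a FlowField to delimited text
#'
#' @param field a [FlowField-class].
#' @param path base path; writes \code{<path>_velocity.csv} and
#'   \code{<path>_mask.csv}.
#' @return invisibly, the two file paths.
#' @export
writeFlowField <- function(field, path) {
  grid <- expand.grid(lon = field@lon, lat = field@lat,
                      depth = field@depth, date = format(field@dates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$u <- as.vector(field@u)
  grid$v <- as.vector(field@v)
  vfile <- paste0(path, "_velocity.csv")
  mfile <- paste0(path, "_mask.csv")
  write.csv(grid, vfile, row.names = FALSE)
  maskDf <- expand.grid(lon = field@lon, lat = field@lat,
                        KEEP.OUT.ATTRS = FALSE)
  maskDf$land <- as.vector(field@mask)
  write.csv(maskDf, mfile, row.names = FALSE)
  invisible(c(vfile, mfile))
}

#' Read a FlowField written by [writeFlowField()]
#'
#' @param path base path used when writing.
#' @param maxSpeed speed cap for the reconstructed field.
#' @return a [FlowField-class].
#' @export
readFlowField <- function(path, maxSpeed = 1.0) {
  vel <- read.csv(paste0(path, "_velocity.csv"))
  maskDf <- read.csv(paste0(path, "_mask.csv"))
  lon <- sort(unique(vel$lon)); lat <- sort(unique(vel$lat))
  depth <- sort(unique(vel$depth)); dates <- sort(unique(as.Date(vel$date)))
  dims <- c(length(lon), length(lat), length(depth), length(dates))
  ord <- order(match(as.Date(vel$date), dates), match(vel$depth, depth),
               match(vel$lat, lat), match(vel$lon, lon))
  u <- array(vel$u[ord], dims)
  v <- array(vel$v[ord], dims)
  mord <- order(match(maskDf$lat, lat), match(maskDf$lon, lon))
  mask <- matrix(maskDf$land[mord], dims[1], dims[2])
  FlowField(lon, lat, depth, dates, u, v, mask = mask, maxSpeed = maxSpeed)
}

#' Write a density grid as delimited text
#'
#' One row per cell with cell edges, raw count and transformed value.
#'
#' @param grid a [DensityGrid-class].
#' @param path output CSV path.
#' @export
writeDensityGrid <- function(grid, path) {
  nx <- length(grid@lonEdges) - 1; ny <- length(grid@latEdges) - 1
  df <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  out <- data.frame(
    lon_lo = grid@lonEdges[df$i], lon_hi = grid@lonEdges[df$i + 1],
    lat_lo = grid@latEdges[df$j], lat_hi = grid@latEdges[df$j + 1],
    count = as.vector(grid@counts), value = as.vector(grid@values),
    transform = grid@transform)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write survey tables to a directory
#'
#' @param tables named list of data.frames (as from
#'   [genStomachSurvey()]; the truth element, if present, is written as
#'   truth_*.csv).
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeSurveyTables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(tables)) {
    if (nm == "truth") {
      for (tn in names(tables$truth)) {
        p <- file.path(dir, paste0("truth_", tn, ".csv"))
        write.csv(tables$truth[[tn]], p, row.names = FALSE)
        paths <- c(paths, p)
      }
    } else {
      p <- file.path(dir, paste0(nm, ".csv"))
      write.csv(tables[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
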