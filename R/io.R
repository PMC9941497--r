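# File interchange: CSV for hypnograms/traces/edges/band summaries,
# multi-page TIFF + JSON sidecar for linescan stacks.

#' Read and write hypnograms as CSV
#'
#' Columns `state`, `t0_s`, `t1_s`.
#'
#' @param x a [Hypnogram-class].
#' @param path file path.
#' @return `writeHypnogram` returns `path` invisibly; `readHypnogram`
#'   returns a [Hypnogram-class].
#' @export
writeHypnogram <- function(x, path) {
  iv <- intervals(x)
  write.csv(data.frame(state = iv$state, t0_s = iv$t0, t1_s = iv$t1),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHypnogram
#' @export
readHypnogram <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  hypnogram(data.frame(state = d$state, t0 = d$t0_s, t1 = d$t1_s))
}

#' Read and write vessel traces as CSV
#'
#' One file per vessel with columns `time_s`, `lumen_um`, `endfoot_um`,
#' `pvs_um`, `state`, mirroring the per-frame export schema of the
#' recordings.
#'
#' @param x a [VesselTrace-class].
#' @param path file path.
#' @param vessel_id,kind metadata used when reading.
#' @return `writeVesselTrace` returns `path` invisibly; `readVesselTrace`
#'   returns a [VesselTrace-class].
#' @export
writeVesselTrace <- function(x, path) {
  write.csv(data.frame(time_s = x@t, lumen_um = x@lumen,
                       endfoot_um = x@endfoot, pvs_um = x@pvs,
                       state = x@state),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeVesselTrace
#' @export
readVesselTrace <- function(path, vessel_id = "v1",
                            kind = "penetrating_arteriole") {
  d <- read.csv(path, stringsAsFactors = FALSE)
  fs <- 1 / median(diff(d$time_s))
  vesselTrace(vessel_id, kind, fs, d$time_s, d$lumen_um, d$endfoot_um,
              d$state)
}

#' Write an edge trace as CSV
#'
#' Columns `time_s`, `left_um`, `right_um`, `diameter_um`, `missing`.
#'
#' @param x an [EdgeTrace-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeEdgeTrace <- function(x, path) {
  write.csv(data.frame(time_s = x@t, left_um = x@left, right_um = x@right,
                       diameter_um = edgeDiameter(x), missing = x@missing),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a band summary as CSV
#'
#' @param x band-summary data.frame from [summarizeEpisodes()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeBandSummary <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write linescan stacks as multi-page TIFF + JSON sidecar
#'
#' The red and green channels are stored as interleaved pages (red frame 1,
#' green frame 1, red frame 2, ...), x along rows; the sidecar
#' (`<path>.json`) stores `dx`, `fs` and any embedded ground truth.
#' Intensities are clipped to [0, 1] for TIFF storage.
#'
#' @param x a [LinescanStack-class].
#' @param path TIFF file path.
#' @return `writeLinescan` returns `path` invisibly; `readLinescan`
#'   returns a [LinescanStack-class].
#' @export
writeLinescan <- function(x, path) {
  nf <- ncol(x@red)
  pages <- vector("list", 2 * nf)
  clip <- function(v) pmin(pmax(v, 0), 1)
  for (k in seq_len(nf)) {
    pages[[2 * k - 1]] <- matrix(clip(x@red[, k]), ncol = 1)
    pages[[2 * k]] <- matrix(clip(x@green[, k]), ncol = 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  side <- list(dx = x@dx, fs = x@fs)
  if (nrow(x@truth)) side$truth <- as.list(x@truth)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLinescan
#' @export
readLinescan <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nf <- length(pages) / 2
  red <- vapply(pages[seq(1, 2 * nf, by = 2)], as.numeric,
                numeric(length(pages[[1]])))
  green <- vapply(pages[seq(2, 2 * nf, by = 2)], as.numeric,
                  numeric(length(pages[[1]])))
  truth <- if (!is.null(side$truth)) as.data.frame(side$truth)
           else data.frame()
  new("LinescanStack", red = red, green = green, dx = side$dx,
      fs = side$fs, truth = truth)
}
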