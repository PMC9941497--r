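#' Detect individual oscillation events in a band-filtered signal
#'
#' Finds local minima and maxima, enforces strict trough/peak alternation
#' (of two same-kind neighbours the more extreme one is kept), and derives
#' one event per consecutive (trough, peak) pair. The peak-to-trough (P-T)
#' amplitude is the signal difference between the two; the P-P period is
#' the time to the next peak (`NA` for the last event).
#'
#' @param x band-filtered signal.
#' @param fs sampling rate (Hz).
#' @param t optional time vector (defaults to `(0:(n-1))/fs`).
#' @return data.frame with columns `t_trough`, `t_peak`, `pt_amplitude`,
#'   `pp_period`; zero rows when the signal has no alternating extrema.
#' @export
#' @examples
#' fs <- 100; t <- seq(0, 10, by = 1 / fs)
#' ev <- detectOscillations(0.5 * sin(2 * pi * 0.5 * t), fs)
#' median(ev$pt_amplitude)  # ~1 (twice the sine amplitude)
detectOscillations <- function(x, fs, t = NULL) {
  n <- length(x)
  if (is.null(t)) t <- (seq_len(n) - 1) / fs
  empty <- data.frame(t_trough = numeric(0), t_peak = numeric(0),
                      pt_amplitude = numeric(0), pp_period = numeric(0))
  if (n < 3) return(empty)
  d <- diff(x)
  s <- sign(d)
  if (any(s == 0)) {  # carry the previous trend over flat segments
    for (k in seq_along(s)) if (s[k] == 0 && k > 1) s[k] <- s[k - 1]
  }
  ds <- diff(s)
  imax <- which(ds < 0) + 1
  imin <- which(ds > 0) + 1
  if (!length(imax) || !length(imin)) return(empty)
  ext <- rbind(data.frame(i = imax, kind = 1),
               data.frame(i = imin, kind = -1))
  ext <- ext[order(ext$i), ]
  # strict alternation: among consecutive same-kind extrema keep the extreme
  keep <- rep(TRUE, nrow(ext))
  last <- 1
  for (k in seq_len(nrow(ext))[-1]) {
    if (ext$kind[k] == ext$kind[last]) {
      better <- if (ext$kind[k] == 1) x[ext$i[k]] >= x[ext$i[last]]
                else x[ext$i[k]] <= x[ext$i[last]]
      if (better) { keep[last] <- FALSE; last <- k }
      else keep[k] <- FALSE
    } else last <- k
  }
  ext <- ext[keep, ]
  if (nrow(ext) < 2) return(empty)
  ev <- list()
  peakTimes <- t[ext$i[ext$kind == 1]]
  pp <- c(diff(peakTimes), NA_real_)
  np <- 0
  for (k in seq_len(nrow(ext) - 1)) {
    if (ext$kind[k] == -1 && ext$kind[k + 1] == 1) {
      np <- np + 1
      ev[[length(ev) + 1]] <- data.frame(
        t_trough = t[ext$i[k]], t_peak = t[ext$i[k + 1]],
        pt_amplitude = x[ext$i[k + 1]] - x[ext$i[k]],
        pp_period = pp[match(t[ext$i[k + 1]], peakTimes)])
    }
  }
  if (!length(ev)) return(empty)
  do.call(rbind, ev)
}

#' Edge-correlation quality control
#'
#' The displacements of both sides of a single structure share the global
#' rigid tissue motion and should therefore correlate strongly; a weak
#' correlation indicates that one edge was not tracked reliably. The filter
#' passes when the Pearson correlation of the two edge-position series is
#' at least 0.8 for the lumen or 0.7 for the endfoot tube (inclusive).
#'
#' @param left,right edge-position series (um).
#' @param structure `"lumen"` or `"endfoot"`.
#' @param nMin minimum number of paired non-missing samples.
#' @return list with elements `pass`, `r`, `threshold`, and `reason` when
#'   failing.
#' @export
#' @examples
#' z <- cumsum(rnorm(200))
#' qcSideCorrelation(z, z + 3, "lumen")$pass
qcSideCorrelation <- function(left, right,
                              structure = c("lumen", "endfoot"),
                              nMin = 100) {
  structure <- match.arg(structure)
  thr <- if (structure == "lumen") 0.8 else 0.7
  ok <- is.finite(left) & is.finite(right)
  if (sum(ok) < nMin)
    stop("need at least ", nMin, " paired samples", call. = FALSE)
  l <- left[ok]; r <- right[ok]
  if (sd(l) == 0 || sd(r) == 0)
    return(list(pass = FALSE, r = NA_real_, threshold = thr,
                reason = "undefined correlation (constant series)"))
  rr <- cor(l, r)
  list(pass = rr >= thr, r = rr, threshold = thr)
}
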