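#' The five frequency bands
#'
#' The fixed decomposition bands: continuous (0-0.1 Hz, a low-pass), very
#' low frequency (VLF, 0.1-0.3 Hz), low frequency (LF, 0.3-1 Hz),
#' respiratory (1-4 Hz) and cardiac (4-15 Hz).
#'
#' @return data.frame with columns `band`, `f_lo`, `f_hi` (Hz).
#' @export
#' @examples
#' bandDefs()
bandDefs <- function() {
  data.frame(band = c("continuous", "VLF", "LF", "respiratory", "cardiac"),
             f_lo = c(0, 0.1, 0.3, 1, 4),
             f_hi = c(0.1, 0.3, 1, 4, 15))
}

#' Savitzky-Golay smoothing
#'
#' Order-3 Savitzky-Golay filter with a window spanning 0.1 s (nearest odd
#' sample count), removing high-frequency noise while reproducing cubic
#' trends exactly.
#'
#' @param x signal.
#' @param fs sampling rate (Hz); must be at least 40 so the window holds at
#'   least 5 samples.
#' @param window window length (s).
#' @param order polynomial order.
#' @return Smoothed signal, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' x <- 2 + t - t^3
#' max(abs(smoothSavGol(x, 100) - x)) < 1e-10
smoothSavGol <- function(x, fs, window = 0.1, order = 3) {
  n <- round(window * fs)
  if (n %% 2 == 0) n <- n + 1
  if (n < order + 2)
    stop("window holds fewer than order+2 samples; need fs >= 40 Hz",
         call. = FALSE)
  as.numeric(signal::sgolayfilt(x, p = order, n = n))
}

#' Decompose a signal into the five frequency bands
#'
#' Zero-phase (forward-backward) order-3 Butterworth filtering per band:
#' the continuous band is a 0.1 Hz low-pass carrying the DC level; the
#' others are band-passes. Bands whose upper edge is not below the Nyquist
#' frequency are rejected.
#'
#' @param x signal.
#' @param fs sampling rate (Hz); must exceed 30 Hz.
#' @param bands band definition table, default [bandDefs()].
#' @param order Butterworth order.
#' @return Named list of band signals, each the length of `x`.
#' @export
#' @examples
#' fs <- 50; t <- seq(0, 60, by = 1 / fs)
#' b <- bandDecompose(sin(2 * pi * 0.2 * t), fs)
#' names(b)
bandDecompose <- function(x, fs, bands = bandDefs(), order = 3) {
  stopIfNot(fs > 30, "fs must exceed 30 Hz")
  out <- list()
  for (k in seq_len(nrow(bands))) {
    b <- bands[k, ]
    if (fs <= 2 * b$f_hi)
      stop("band ", b$band, " rejected: fs must exceed twice its upper edge",
           call. = FALSE)
    if (b$f_lo == 0) {
      bf <- signal::butter(order, b$f_hi / (fs / 2), type = "low")
    } else {
      bf <- signal::butter(order, c(b$f_lo, b$f_hi) / (fs / 2), type = "pass")
    }
    out[[b$band]] <- as.numeric(signal::filtfilt(bf, x))
  }
  out
}
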