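#' Default ECoG/EMG synthesis parameters
#'
#' Per-state amplitudes for the band-limited ECoG components (delta 0.5-4,
#' theta 5-9, sigma 9-16, broadband 0.5-30 Hz) and the amplitude-modulated
#' EMG. NREM is delta-dominant; IS has elevated sigma/theta with reduced
#' delta; REM is theta-dominant (theta/delta power ratio far above 0.5) with
#' the lowest EMG; wake states are broadband with high EMG.
#'
#' @return data.frame with one row per state and columns `delta`, `theta`,
#'   `sigma`, `broad`, `emg`.
#' @export
physioParams <- function() {
  p <- rbind(
    QW    = c(0.7, 0.7, 0.5, 0.5, 1.0),
    WHISK = c(0.7, 0.7, 0.5, 0.5, 1.0),
    LOCO  = c(0.6, 0.8, 0.5, 0.5, 1.3),
    WBS   = c(0.7, 0.7, 0.5, 0.5, 1.0),
    NREM  = c(2.0, 0.4, 0.3, 0.2, 0.20),
    IS    = c(1.2, 0.5, 0.9, 0.2, 0.20),
    REM   = c(0.5, 1.5, 0.3, 0.2, 0.05),
    WAS   = c(0.7, 0.7, 0.5, 0.5, 1.0),
    MA    = c(0.7, 0.7, 0.5, 0.5, 1.0)
  )
  out <- as.data.frame(p)
  names(out) <- c("delta", "theta", "sigma", "broad", "emg")
  out$state <- rownames(p)
  rownames(out) <- NULL
  out[, c("state", "delta", "theta", "sigma", "broad", "emg")]
}

#' Generate synthetic ECoG and EMG signals for a hypnogram
#'
#' The ECoG is a sum of band-limited Gaussian noise components (delta,
#' theta, sigma and a 0.5-30 Hz broadband floor) whose amplitudes are gated
#' by the sleep-wake state; the EMG is broadband noise whose amplitude is
#' high in wake and microarousals, low in NREM/IS and lowest in REM.
#'
#' @param h a [Hypnogram-class].
#' @param fs sampling rate (Hz), at least 100.
#' @param params per-state amplitude table, see [physioParams()].
#' @param seed integer seed.
#' @return A [PhysioSignals-class].
#' @export
#' @examples
#' h <- makeHypnogram(nCycles = 1, seed = 2)
#' ps <- makeEcogEmg(h, seed = 2)
makeEcogEmg <- function(h, fs = 100, params = physioParams(), seed = NULL) {
  stopIfNot(fs >= 100, "fs must be at least 100 Hz")
  iv <- intervals(h)
  t <- seq(iv$t0[1], iv$t1[nrow(iv)] - 1 / fs, by = 1 / fs)
  state <- stateAtTime(h, t)
  rownames(params) <- params$state
  withSeed(seed, {
    n <- length(t)
    comp <- function(lo, hi) {
      bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
      w <- rnorm(n)
      x <- signal::filtfilt(bf, w)
      x / sd(x)
    }
    delta <- comp(0.5, 4); theta <- comp(5, 9); sigma <- comp(9, 16)
    broad <- comp(0.5, 30)
    amp <- function(col) unname(unlist(params[state, col]))
    ecog <- amp("delta") * delta + amp("theta") * theta +
      amp("sigma") * sigma + amp("broad") * broad
    emg <- amp("emg") * rnorm(n)
    new("PhysioSignals", ecog = ecog, emg = emg, fs = fs)
  })
}
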