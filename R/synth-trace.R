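#' Default per-state vessel parameters
#'
#' Builds the parameter bundle consumed by [makeVesselTrace()]: per-state
#' median lumen and endfoot diameters and per-(state, band) relative
#' peak-to-trough oscillation amplitudes with their carrier frequencies.
#' The qualitative pattern emulates the recorded dynamics: VLF (0.1-0.3 Hz)
#' and LF (0.3-1 Hz) oscillations largest in NREM and IS, a REM dilation with
#' PVS shrinkage, constriction with PVS enlargement upon arousal (WAS, MA),
#' plus small respiratory (1-4 Hz) and cardiac (4-15 Hz) components.
#' The numeric values are plausible placeholders for a penetrating arteriole,
#' not measured values, and every one of them is overridable.
#'
#' @param lumenBase baseline (quiet wakefulness) median lumen diameter (um).
#' @param endfootBase baseline median endfoot tube diameter (um).
#' @param remDilation multiplicative REM lumen dilation factor (> 1 dilates).
#' @param arousalConstriction multiplicative lumen constriction factor for
#'   WAS/MA (< 1 constricts).
#' @param noiseSd measurement noise s.d. (um) added independently to each
#'   diameter sample.
#' @param driftSd stationary s.d. (um) of the rigid tissue drift shared by
#'   both edges of a structure; modelled as a mean-reverting random walk
#'   (Ornstein-Uhlenbeck) so the vessel stays in the field of view.
#' @param driftTau drift reversion time constant (s).
#' @param tau state-transition ramp time constant (s).
#' @param fs sampling rate (Hz).
#' @return A named list with components `states` (per-state list of
#'   `lumen`, `endfoot`, and a `bands` data.frame with columns `band`,
#'   `a_rel`, `freq`), `noiseSd`, `driftSd`, `tau`, `fs`.
#' @export
#' @examples
#' p <- vesselParams()
#' p$states$NREM$bands
vesselParams <- function(lumenBase = 16, endfootBase = 24, remDilation = 1.2,
                         arousalConstriction = 0.93, noiseSd = 0.05,
                         driftSd = 3, driftTau = 10, tau = 2, fs = 100) {
  bands <- function(vlf = 0, lf = 0, resp = 0.01, card = 0.01) {
    data.frame(band = c("VLF", "LF", "respiratory", "cardiac"),
               a_rel = c(vlf, lf, resp, card),
               freq = c(0.2, 0.5, 2.5, 8))
  }
  st <- function(lum, end, ...) list(lumen = lum, endfoot = end,
                                     bands = bands(...))
  states <- list(
    QW    = st(lumenBase, endfootBase, vlf = 0.02, lf = 0.01),
    WHISK = st(lumenBase * 1.03, endfootBase * 1.01, vlf = 0.02, lf = 0.02),
    LOCO  = st(lumenBase * 1.10, endfootBase * 1.03, vlf = 0.08, lf = 0.04),
    WBS   = st(lumenBase, endfootBase, vlf = 0.02, lf = 0.01),
    NREM  = st(lumenBase * 1.02, endfootBase * 1.005, vlf = 0.10, lf = 0.05),
    IS    = st(lumenBase * 1.05, endfootBase * 1.015, vlf = 0.08, lf = 0.04),
    REM   = st(lumenBase * remDilation, endfootBase * 1.04,
               vlf = 0.02, lf = 0.01),
    WAS   = st(lumenBase * arousalConstriction, endfootBase * 0.995,
               vlf = 0.02, lf = 0.02),
    MA    = st(lumenBase * arousalConstriction, endfootBase * 0.995,
               vlf = 0.02, lf = 0.02)
  )
  list(states = states, noiseSd = noiseSd, driftSd = driftSd,
       driftTau = driftTau, tau = tau, fs = fs)
}

#' Generate a synthetic vessel diameter trace
#'
#' Synthesises lumen and endfoot-tube diameter time series over a hypnogram
#' as sums of state-gated band-limited sinusoids (one uniformly random phase
#' per episode and band, shared between lumen and endfoot so the area
#' oscillation is coherent), with exponential state-transition ramps,
#' independent Gaussian measurement noise on each diameter, and a shared
#' rigid tissue drift on the structure centreline. The PVS width is
#' recomputed as the endfoot minus lumen diameter.
#'
#' @param h a [Hypnogram-class].
#' @param params parameter bundle from [vesselParams()].
#' @param kind vessel kind.
#' @param vessel_id identifier.
#' @param seed integer seed; identical seeds give identical traces.
#' @return A [VesselTrace-class].
#' @export
#' @examples
#' h <- makeHypnogram(nCycles = 1, seed = 1)
#' tr <- makeVesselTrace(h, vesselParams(), seed = 1)
#' tr
makeVesselTrace <- function(h, params = vesselParams(),
                            kind = "penetrating_arteriole",
                            vessel_id = "v1", seed = NULL) {
  fs <- params$fs
  bandTop <- max(unlist(lapply(params$states, function(s) s$bands$freq)))
  stopIfNot(fs >= 2 * bandTop,
            "fs must be at least twice the highest band frequency used")
  iv <- intervals(h)
  t <- seq(iv$t0[1], iv$t1[nrow(iv)] - 1 / fs, by = 1 / fs)
  state <- stateAtTime(h, t)
  for (s in unique(state))
    if (!s %in% names(params$states))
      stop("no parameters for state ", s, call. = FALSE)

  withSeed(seed, {
    lumByState <- vapply(params$states, function(s) s$lumen, 0)
    endByState <- vapply(params$states, function(s) s$endfoot, 0)
    lumEnv <- expRamp(unname(lumByState[state]), fs, params$tau)
    endEnv <- expRamp(unname(endByState[state]), fs, params$tau)

    bandNames <- params$states[[1]]$bands$band
    lumOsc <- numeric(length(t))
    endOsc <- numeric(length(t))
    epi <- findInterval(t, iv$t0)
    for (b in bandNames) {
      aByState <- vapply(params$states, function(s) {
        s$bands$a_rel[s$bands$band == b]
      }, 0)
      fByState <- vapply(params$states, function(s) {
        s$bands$freq[s$bands$band == b]
      }, 0)
      aTar <- unname(aByState[state])
      fTar <- unname(fByState[state])
      aEnv <- expRamp(aTar, fs, params$tau)
      phase <- runif(nrow(iv), 0, 2 * pi)
      # per-episode carrier: phase restarts at each episode
      theta <- 2 * pi * fTar * (t - iv$t0[epi]) + phase[epi]
      s <- sin(theta)
      # sine amplitude a*m/2 makes the peak-to-trough amplitude a*m,
      # i.e. `a_rel` is the relative P-T amplitude of the diameter
      lumOsc <- lumOsc + 0.5 * aEnv * lumEnv * s
      endOsc <- endOsc + 0.5 * (aEnv / 2) * endEnv * s
    }

    lumen <- lumEnv + lumOsc
    endfoot <- endEnv + endOsc
    if (params$noiseSd > 0) {
      lumen <- lumen + rnorm(length(t), 0, params$noiseSd)
      endfoot <- endfoot + rnorm(length(t), 0, params$noiseSd)
    }
    if (any(endfoot <= lumen))
      stop("parameters imply endfoot diameter <= lumen diameter; ",
           "increase the PVS width or reduce amplitudes/noise",
           call. = FALSE)
    center <- if (params$driftSd > 0) {
      # mean-reverting rigid drift with stationary s.d. driftSd
      rho <- exp(-1 / (fs * params$driftTau))
      eps <- rnorm(length(t), 0, params$driftSd * sqrt(1 - rho^2))
      as.numeric(stats::filter(eps, rho, method = "recursive"))
    } else numeric(length(t))

    vesselTrace(vessel_id, kind, fs, t, lumen, endfoot, state, center)
  })
}
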