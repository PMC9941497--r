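#' Rule-based sleep-wake scoring from ECoG and EMG
#'
#' Epoch-wise band powers (delta 0.5-4, theta 5-9, sigma 9-16 Hz) drive the
#' standard rodent rules: high EMG gives wake; low EMG with a theta/delta
#' power ratio above 0.5 gives REM; low EMG with rising sigma and theta and
#' falling delta relative to a running NREM baseline gives IS; remaining
#' low-EMG epochs are NREM. Within NREM/IS, a drop in ECoG total power
#' coupled with EMG activation lasting at least 1 s but less than 10 s is a
#' microarousal (MA); longer activations are wake. Wake immediately before
#' NREM is relabelled WBS (last 15 s), wake immediately after REM is
#' relabelled WAS (first 10 s), other wake is QW.
#'
#' The EMG high/low split is found by a deterministic two-means clustering
#' of log epoch power unless an absolute threshold is supplied.
#'
#' @param physio a [PhysioSignals-class] (ECoG band-limited 0.5-30 Hz; EMG
#'   broadband or envelope).
#' @param params list of tuning parameters: `epoch` (s, default 0.5; gives
#'   the 1 s microarousal minimum a clean two-epoch implementation),
#'   `thetaDeltaREM` (0.5), `isSigmaRise` (1.8), `isDeltaFall` (0.7),
#'   `maPowerDrop` (0.9), `baselineWindow` (s, 60), `powerSmooth` (epochs of
#'   running-median power smoothing, 5), `minREM`/`minIS` (s; shorter
#'   candidate episodes are returned to the surrounding slow-wave state),
#'   `emgThreshold`
#'   (absolute epoch EMG power; `NULL` = automatic).
#' @return A [Hypnogram-class] of scored states.
#' @export
#' @examples
#' h <- makeHypnogram(nCycles = 1, seed = 3)
#' ps <- makeEcogEmg(h, seed = 3)
#' scoreSleepStates(ps)
scoreSleepStates <- function(physio, params = list()) {
  p <- list(epoch = 0.5, thetaDeltaREM = 0.5, isSigmaRise = 1.8,
            isDeltaFall = 0.7, maPowerDrop = 0.9, baselineWindow = 60,
            powerSmooth = 5, minREM = 5, minIS = 1, emgThreshold = NULL)
  p[names(params)] <- params
  if (anyNA(physio@ecog) || anyNA(physio@emg))
    stop("NaN/NA in physio signals: filter the recordings first",
         call. = FALSE)
  fs <- physio@fs
  ne <- floor(length(physio@ecog) / (p$epoch * fs))
  stopIfNot(ne >= 4, "recording shorter than four epochs")
  spe <- round(p$epoch * fs)
  grp <- rep(seq_len(ne), each = spe)[seq_len(ne * spe)]

  bp <- function(x, lo, hi) {
    bf <- signal::butter(3, c(lo, hi) / (fs / 2), type = "pass")
    as.numeric(signal::filtfilt(bf, x))
  }
  epow <- function(x) as.numeric(tapply(x[seq_len(ne * spe)]^2, grp, mean))
  # running-median smoothing tames the chi-squared noise of short-epoch
  # power estimates; the EMG is left unsmoothed so brief microarousal
  # activations keep their duration
  smoothP <- function(x) {
    w <- p$powerSmooth
    if (w %% 2 == 0) w <- w + 1
    if (w > 1 && length(x) > w) as.numeric(stats::runmed(x, w)) else x
  }
  delta <- smoothP(epow(bp(physio@ecog, 0.5, 4)))
  theta <- smoothP(epow(bp(physio@ecog, 5, 9)))
  sigma <- smoothP(epow(bp(physio@ecog, 9, 16)))
  total <- epow(physio@ecog)
  emg <- epow(physio@emg)

  emgThr <- if (is.null(p$emgThreshold)) twoMeansSplit(log(emg + 1e-12))
            else log(p$emgThreshold)
  emgHigh <- log(emg + 1e-12) > emgThr

  lab <- classifySleepEpochs(delta, theta, sigma, total, emgHigh, p)

  # contextual wake labels
  lab <- relabelWake(lab, p$epoch)
  labelsToHypnogram(lab, p$epoch)
}

# Epoch-feature rule engine: given per-epoch band powers and the EMG
# high/low mask, return WAKE/NREM/IS/REM/MA labels. Kept separate from the
# signal processing so the rules are unit-testable on exact features.
classifySleepEpochs <- function(delta, theta, sigma, total, emgHigh, p) {
  ne <- length(delta)
  lab <- rep("WAKE", ne)
  sws <- !emgHigh & (theta / delta <= p$thetaDeltaREM)
  lab[!emgHigh & (theta / delta > p$thetaDeltaREM)] <- "REM"
  lab[sws] <- "NREM"

  # IS: sigma/theta rise with delta fall relative to a running NREM baseline
  win <- round(p$baselineWindow / p$epoch)
  gDelta <- median(delta[sws]); gSigma <- median(sigma[sws])
  for (e in which(sws)) {
    lo <- max(1, e - win)
    # baseline over trailing epochs still scored NREM, so a long IS episode
    # does not drag its own elevated sigma into the reference
    ref <- which(lab[lo:e] == "NREM") + lo - 1
    bD <- if (length(ref) >= 5) median(delta[ref]) else gDelta
    bS <- if (length(ref) >= 5) median(sigma[ref]) else gSigma
    if (sigma[e] > p$isSigmaRise * bS && delta[e] < p$isDeltaFall * bD)
      lab[e] <- "IS"
  }

  # physiological minimum durations: REM and IS episodes last far longer
  # than an epoch, so sub-threshold flickers are relabelled to the
  # neighbouring slow-wave state
  lab <- dropShortRuns(lab, "REM", p$minREM / p$epoch, c("NREM", "IS"))
  lab <- dropShortRuns(lab, "IS", p$minIS / p$epoch, "NREM")

  # microarousals: wake-like runs inside sleep lasting [1, 10) s with an
  # ECoG total-power drop. A run of n epochs is compatible with true
  # durations in ((n-2)e, n e) (boundary epochs catch partial activations);
  # the run is a microarousal when that interval intersects [1, 10) s.
  sleepTotal <- median(total[lab %in% c("NREM", "IS")])
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] != "WAKE") next
    n <- r$lengths[k]
    inside <- k > 1 && k < length(r$values) &&
      r$values[k - 1] %in% c("NREM", "IS") &&
      r$values[k + 1] %in% c("NREM", "IS")
    if (!inside) next
    idx <- starts[k]:ends[k]
    drop <- median(total[idx]) < p$maPowerDrop * sleepTotal
    if (n * p$epoch > 1 && (n - 2) * p$epoch < 10 && drop) {
      lab[idx] <- "MA"
      if (n * p$epoch >= 10) {
        # boundary epochs only partially overlap the activation; return
        # them to the neighbours so the stored duration stays below 10 s
        lab[idx[1]] <- r$values[k - 1]
        lab[idx[n]] <- r$values[k + 1]
      }
    } else if (n * p$epoch <= 1) {
      lab[idx] <- r$values[k - 1]  # sub-second activation: not an arousal
    }
  }
  lab
}

# relabel runs of `state` shorter than minEpochs to a neighbouring state
# drawn from `to` (previous neighbour preferred)
dropShortRuns <- function(lab, state, minEpochs, to) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] != state || r$lengths[k] >= minEpochs) next
    repl <- NULL
    if (k > 1 && r$values[k - 1] %in% to) repl <- r$values[k - 1]
    else if (k < length(r$values) && r$values[k + 1] %in% to)
      repl <- r$values[k + 1]
    if (!is.null(repl)) lab[starts[k]:ends[k]] <- repl
  }
  lab
}

# deterministic 1-D two-means: returns the midpoint between cluster centres
twoMeansSplit <- function(x) {
  c1 <- min(x); c2 <- max(x)
  if (c2 - c1 < 1e-9) return(c2 + 1)  # everything is one cluster: all "low"
  for (it in 1:50) {
    a <- abs(x - c1) <= abs(x - c2)
    n1 <- mean(x[a]); n2 <- mean(x[!a])
    if (is.nan(n1) || is.nan(n2)) break
    if (abs(n1 - c1) + abs(n2 - c2) < 1e-12) break
    c1 <- n1; c2 <- n2
  }
  (c1 + c2) / 2
}

relabelWake <- function(lab, epoch) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- lab
  for (k in seq_along(r$values)) {
    if (r$values[k] != "WAKE") next
    idx <- starts[k]:ends[k]
    out[idx] <- "QW"
    if (k < length(r$values) && r$values[k + 1] == "NREM") {
      nWbs <- min(length(idx), round(15 / epoch))
      out[tail(idx, nWbs)] <- "WBS"
    }
    if (k > 1 && r$values[k - 1] == "REM") {
      nWas <- min(length(idx), round(10 / epoch))
      out[head(idx, nWas)] <- "WAS"
    }
  }
  out
}

labelsToHypnogram <- function(lab, epoch) {
  r <- rle(lab)
  ends <- cumsum(r$lengths) * epoch
  starts <- c(0, head(ends, -1))
  hypnogram(data.frame(state = r$values, t0 = starts, t1 = ends))
}

#' Per-sample agreement between two hypnograms
#'
#' Samples both hypnograms on a common grid and reports the fraction of
#' samples whose labels agree after mapping all wake labels (QW, WHISK,
#' LOCO, WBS, WAS) to a single wake class; NREM, IS, REM and MA are kept
#' distinct.
#'
#' @param truth,scored [Hypnogram-class] objects.
#' @param dt sampling step (s).
#' @return Fraction in [0, 1].
#' @export
scoringAgreement <- function(truth, scored, dt = 0.1) {
  tEnd <- min(duration(truth), duration(scored))
  t <- seq(dt / 2, tEnd - dt / 2, by = dt)
  wake <- c("QW", "WHISK", "LOCO", "WBS", "WAS")
  mapW <- function(s) ifelse(s %in% wake, "WAKE", s)
  mean(mapW(stateAtTime(truth, t)) == mapW(stateAtTime(scored, t)),
       na.rm = TRUE)
}
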