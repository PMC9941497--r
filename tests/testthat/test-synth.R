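test_that("a single cycle with no microarousals is the canonical sequence", {
  h <- makeHypnogram(nCycles = 1, maRate = 0, seed = 1)
  expect_identical(intervals(h)$state, c("WBS", "NREM", "IS", "REM", "WAS"))
  expect_equal(intervals(h)$t0[1], 0)
  expect_equal(duration(h), 15 + 120 + 30 + 60 + 10)
  # zero MA rate: no MA anywhere, also across many cycles
  h3 <- makeHypnogram(nCycles = 3, maRate = 0, seed = 2)
  expect_false("MA" %in% intervals(h3)$state)
})

test_that("hypnograms are deterministic in the seed and reject bad input", {
  a <- makeHypnogram(nCycles = 2, maRate = 0.05, seed = 7)
  b <- makeHypnogram(nCycles = 2, maRate = 0.05, seed = 7)
  expect_identical(intervals(a), intervals(b))
  c <- makeHypnogram(nCycles = 2, maRate = 0.05, seed = 8)
  expect_false(identical(intervals(a), intervals(c)))
  expect_error(makeHypnogram(durations = list(nrem = -5)), "nrem")
  expect_error(makeHypnogram(durations = list(bogus = 5)), "bogus")
})

test_that("microarousals obey duration and containment rules", {
  h <- makeHypnogram(nCycles = 4, maRate = 0.05, seed = 42)
  iv <- intervals(h)
  ma <- iv[iv$state == "MA", ]
  expect_gt(nrow(ma), 0)
  d <- ma$t1 - ma$t0
  expect_true(all(d >= 1 & d < 10))
  # contiguity of the whole hypnogram
  expect_equal(iv$t0[-1], iv$t1[-nrow(iv)])
  # every MA is flanked by NREM or IS
  for (k in which(iv$state == "MA")) {
    nb <- c(if (k > 1) iv$state[k - 1], if (k < nrow(iv)) iv$state[k + 1])
    expect_true(any(nb %in% c("NREM", "IS")))
  }
})

test_that("the class validity catches malformed hypnograms", {
  expect_error(hypnogram(data.frame(state = "NAP", t0 = 0, t1 = 10)),
               "unknown state")
  expect_error(hypnogram(data.frame(state = c("QW", "NREM"),
                                    t0 = c(0, 20), t1 = c(10, 30))),
               "contiguous")
  expect_error(hypnogram(data.frame(state = c("NREM", "MA", "NREM"),
                                    t0 = c(0, 30, 30.5), t1 = c(30, 30.5, 60))),
               "MA duration")
})

test_that("vessel traces honour the construction contracts", {
  h <- makeHypnogram(nCycles = 1, seed = 3)
  # all amplitudes zero, no noise, no ramps: piecewise-constant state medians
  p0 <- vesselParams(noiseSd = 0, driftSd = 0, tau = 0)
  for (s in names(p0$states)) p0$states[[s]]$bands$a_rel[] <- 0
  tr0 <- makeVesselTrace(h, p0, seed = 4)
  nremSel <- tr0@state == "NREM"
  expect_equal(unique(tr0@lumen[nremSel]), p0$states$NREM$lumen)
  expect_equal(unique(tr0@endfoot[tr0@state == "REM"]), p0$states$REM$endfoot)
  # pvs identity at machine precision
  tr <- makeVesselTrace(h, vesselParams(), seed = 5)
  expect_equal(tr@pvs, tr@endfoot - tr@lumen, tolerance = 1e-12)
  # determinism
  tr2 <- makeVesselTrace(h, vesselParams(), seed = 5)
  expect_identical(tr@lumen, tr2@lumen)
  expect_identical(tr@center, tr2@center)
})

test_that("REM dilates the lumen and shrinks the PVS relative to NREM", {
  h <- makeHypnogram(nCycles = 2, seed = 6)
  tr <- makeVesselTrace(h, vesselParams(remDilation = 1.2), seed = 6)
  expect_gt(median(tr@lumen[tr@state == "REM"]),
            median(tr@lumen[tr@state == "NREM"]))
  expect_lt(median(tr@pvs[tr@state == "REM"]),
            median(tr@pvs[tr@state == "NREM"]))
  # arousal: constricted lumen, enlarged PVS
  expect_lt(median(tr@lumen[tr@state == "WAS"]),
            median(tr@lumen[tr@state == "WBS"]) * 1.001)
  expect_gt(median(tr@pvs[tr@state == "WAS"]),
            median(tr@pvs[tr@state == "NREM"]))
})

test_that("impossible diameter parameters are rejected", {
  h <- makeHypnogram(nCycles = 1, seed = 9)
  p <- vesselParams(lumenBase = 16, endfootBase = 16.2, noiseSd = 0.5)
  expect_error(makeVesselTrace(h, p, seed = 1), "endfoot")
})

test_that("single-band variance lands in the intended band after decomposition", {
  h <- makeHypnogram(nCycles = 1, seed = 10)
  p <- vesselParams(noiseSd = 0, driftSd = 0, fs = 50)
  for (s in names(p$states)) {
    p$states[[s]]$bands$a_rel <- c(0.1, 0, 0, 0)  # VLF only, 0.2 Hz
    p$states[[s]]$lumen <- 16; p$states[[s]]$endfoot <- 24
  }
  tr <- makeVesselTrace(h, p, seed = 11)
  b <- bandDecompose(tr@lumen - mean(tr@lumen), tr@fs)
  v <- vapply(b, var, 0)
  expect_gt(v[["VLF"]] / sum(v), 0.90)
})

test_that("synthetic ECoG has the state-defining band structure", {
  h <- makeHypnogram(nCycles = 1, seed = 12)
  ps <- makeEcogEmg(h, seed = 13)
  fs <- ps@fs
  bp <- function(x, lo, hi) {
    bf <- signal::butter(3, c(lo, hi) / (fs / 2), type = "pass")
    as.numeric(signal::filtfilt(bf, x))
  }
  t <- (seq_along(ps@ecog) - 1) / fs
  st <- stateAtTime(h, t)
  pow <- function(sel, lo, hi) mean(bp(ps@ecog, lo, hi)[sel]^2)
  rem <- st == "REM"; nrem <- st == "NREM"
  expect_gt(pow(rem, 5, 9) / pow(rem, 0.5, 4), 0.5)     # REM theta-dominant
  expect_gt(pow(nrem, 0.5, 4), pow(nrem, 5, 9))         # NREM delta > theta
  # EMG: wake high, NREM low, REM lowest
  emgP <- function(sel) mean(ps@emg[sel]^2)
  expect_gt(emgP(st == "WBS"), 5 * emgP(nrem))
  expect_lt(emgP(rem), emgP(nrem))
  # determinism
  ps2 <- makeEcogEmg(h, seed = 13)
  expect_identical(ps@ecog, ps2@ecog)
})
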