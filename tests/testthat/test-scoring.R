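# direct rule checks on hand-built physiology, then a round trip

synthPhysio <- function(states, amps, fs = 100, epochLen = NULL) {
  # states: vector of labels; amps: physioParams()-style table
  h <- hypnogram(data.frame(state = states,
                            t0 = seq(0, by = 30, length.out = length(states)),
                            t1 = seq(30, by = 30, length.out = length(states))))
  makeEcogEmg(h, fs = fs, params = amps, seed = 201)
}

test_that("the REM theta/delta rule and NREM delta rule fire as specified", {
  amps <- physioParams()
  ps <- synthPhysio(c("WBS", "NREM", "REM", "WAS"), amps)
  sc <- scoreSleepStates(ps)
  st <- stateAtTime(sc, c(45, 75))
  expect_identical(st[1], "NREM")
  expect_identical(stateAtTime(sc, 75), "REM")
  # exact-feature rule checks on the epoch classifier:
  # theta/delta = 0.4 with high delta and low EMG is NREM, never REM
  p <- list(epoch = 0.5, thetaDeltaREM = 0.5, isSigmaRise = 1.8,
            isDeltaFall = 0.7, maPowerDrop = 0.9, baselineWindow = 60,
            powerSmooth = 5, minREM = 5, minIS = 1)
  ne <- 120
  lab <- perivasc:::classifySleepEpochs(delta = rep(4, ne),
                                        theta = rep(4 * 0.4, ne),
                                        sigma = rep(0.1, ne),
                                        total = rep(5, ne),
                                        emgHigh = rep(FALSE, ne), p)
  expect_true(all(lab == "NREM"))
  # ratio 0.8 with low EMG is REM
  lab2 <- perivasc:::classifySleepEpochs(delta = rep(1, ne),
                                         theta = rep(0.8, ne),
                                         sigma = rep(0.1, ne),
                                         total = rep(2, ne),
                                         emgHigh = rep(FALSE, ne), p)
  expect_true(all(lab2 == "REM"))
  # ratio exactly at the threshold stays non-REM (the rule is "> 0.5")
  lab3 <- perivasc:::classifySleepEpochs(delta = rep(2, ne),
                                         theta = rep(1, ne),
                                         sigma = rep(0.1, ne),
                                         total = rep(3, ne),
                                         emgHigh = rep(FALSE, ne), p)
  expect_false(any(lab3 == "REM"))
  # high EMG is wake regardless of the ECoG pattern
  lab4 <- perivasc:::classifySleepEpochs(delta = rep(4, ne),
                                         theta = rep(0.4, ne),
                                         sigma = rep(0.1, ne),
                                         total = rep(5, ne),
                                         emgHigh = rep(TRUE, ne), p)
  expect_true(all(lab4 == "WAKE"))
})

test_that("sub-second EMG bursts are not scored as microarousals", {
  h <- hypnogram(data.frame(state = c("WBS", "NREM", "WAS"),
                            t0 = c(0, 30, 150), t1 = c(30, 150, 160)))
  ps <- makeEcogEmg(h, seed = 202)
  fs <- ps@fs
  burst <- function(ps, t0, len) {
    i <- round(t0 * fs):round((t0 + len) * fs)
    ps@emg[i] <- rnorm(length(i), 0, 1.3)
    # microarousal signature includes an ECoG power drop
    ps@ecog[i] <- ps@ecog[i] * 0.5
    ps
  }
  ps05 <- burst(ps, 80, 0.45)
  sc05 <- scoreSleepStates(ps05)
  expect_false("MA" %in% intervals(sc05)$state)
  # a 4 s activation in the same place is a microarousal
  ps4 <- burst(ps, 80, 4)
  sc4 <- scoreSleepStates(ps4)
  iv <- intervals(sc4)
  ma <- iv[iv$state == "MA", ]
  expect_equal(nrow(ma), 1)
  expect_lt(abs(ma$t0 - 80), 1.5)
  d <- ma$t1 - ma$t0
  expect_true(d >= 1 && d < 10)
})

test_that("scored wake is relabelled WBS before NREM and WAS after REM", {
  h <- makeHypnogram(nCycles = 1, qwLead = 40, seed = 203)
  ps <- makeEcogEmg(h, seed = 204)
  sc <- scoreSleepStates(ps)
  iv <- intervals(sc)
  before <- iv$state[which(iv$state == "NREM")[1] - 1]
  expect_identical(before, "WBS")
  after <- iv$state[tail(which(iv$state == "REM"), 1) + 1]
  expect_identical(after, "WAS")
})

test_that("scoring round-trips synthetic recordings at high accuracy", {
  h <- makeHypnogram(nCycles = 2, maRate = 0.02, qwLead = 60, seed = 11)
  ps <- makeEcogEmg(h, seed = 101)
  expect_gt(scoringAgreement(h, scoreSleepStates(ps)), 0.95)
})
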