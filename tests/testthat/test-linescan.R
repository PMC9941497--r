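# shared small fixture: ~6 s of quiet wakefulness, modest noise
lsFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      h <- hypnogram(data.frame(state = "QW", t0 = 0, t1 = 6))
      tr <- makeVesselTrace(h, vesselParams(), seed = 51)
      cache <<- makeLinescan(tr, fov = 40, fs = 250, psfSd = 0.3,
                             noiseSd = 0.1, seed = 52)
    }
    cache
  }
})

test_that("downsampling factors match exhaustive enumeration", {
  # the recorded frame rates map to a temporal factor of 3 toward 100 Hz
  expect_identical(downsampleFactor(250, 100), enumFactor(250, 100))
  expect_identical(downsampleFactor(250, 100), 3L)
  expect_identical(downsampleFactor(333, 100), enumFactor(333, 100))
  expect_identical(downsampleFactor(333, 100), 3L)
  expect_identical(downsampleFactor(100, 100), 1L)
  expect_identical(downsampleFactor(40, 20), enumFactor(40, 20))
  # property: agreement with enumeration over a rate sweep
  for (r in seq(60, 500, by = 17))
    expect_identical(downsampleFactor(r, 100), enumFactor(r, 100))
})

test_that("block averaging preserves block means and metadata", {
  st <- lsFixture()
  ds <- downsampleStack(st)
  expect_equal(ds@fs, 250 / 3)
  expect_equal(ds@dx, st@dx * 2)  # 40 samples/um -> 20 samples/um
  # DC conservation: the first block mean is reproduced exactly
  expect_equal(ds@red[1, 1], mean(st@red[1:2, 1:3]), tolerance = 1e-12)
  expect_equal(mean(ds@red), mean(st@red[1:(2 * nrow(ds@red)),
                                         1:(3 * ncol(ds@red))]),
               tolerance = 1e-12)
  # factor-1 case leaves the stack unchanged
  same <- downsampleStack(ds)
  expect_identical(dim(same@red), dim(ds@red))
})

test_that("edge tracing recovers a noiseless top-hat to within one sample", {
  h <- hypnogram(data.frame(state = "QW", t0 = 0, t1 = 0.2))
  p <- vesselParams(noiseSd = 0, driftSd = 0)
  for (s in names(p$states)) p$states[[s]]$bands$a_rel[] <- 0
  p$states$QW$lumen <- 20; p$states$QW$endfoot <- 28
  st <- makeLinescan(makeVesselTrace(h, p, seed = 1), fov = 40, fs = 250,
                     psfSd = 0.05, noiseSd = 0, seed = 1)
  et <- traceEdges(st, thresholdSpec("red", 0, 0.5))
  expect_true(all(!et@missing))
  expect_true(all(abs(edgeDiameter(et) - 20) <= st@dx))
  # green channel: outer edges of the flanking bands give the endfoot tube
  eg <- traceEdges(st, thresholdSpec("green", 0, 0.5))
  expect_true(all(abs(edgeDiameter(eg) - 28) <= st@dx))
  # noiseless stacks are reproducible regardless of seed
  st2 <- makeLinescan(makeVesselTrace(h, p, seed = 1), fov = 40, fs = 250,
                      psfSd = 0.05, noiseSd = 0, seed = 99)
  expect_identical(st@red, st2@red)
})

test_that("thresholds interpolate linearly in time with constant extrapolation", {
  # triangular profile peaking at 30: detected width = 40 (1 - thr/30)
  x <- seq(0.025, 39.975, by = 0.05)
  prof <- pmax(0, 30 * (1 - abs(x - 20) / 20))
  stack <- new("LinescanStack", red = matrix(rep(prof, 3), ncol = 3),
               green = matrix(0, length(x), 3), dx = 0.05, fs = 0.1,
               truth = data.frame())
  # frames at t = 0, 10, 20 s; control points at (0, 10) and (20, 20)
  spec <- thresholdSpec("red", c(0, 20), c(10, 20))
  et <- traceEdges(stack, spec)
  expect_equal(edgeDiameter(et)[1], 40 * (1 - 10 / 30), tolerance = 1e-3)
  expect_equal(edgeDiameter(et)[2], 40 * (1 - 15 / 30), tolerance = 1e-3)
  expect_equal(edgeDiameter(et)[3], 40 * (1 - 20 / 30), tolerance = 1e-3)
  # all-dark frame: missing, never interpolated
  dark <- stack
  dark@red[, 2] <- 0
  et2 <- traceEdges(dark, spec)
  expect_true(et2@missing[2])
  expect_true(is.na(edgeDiameter(et2)[2]))
  expect_error(traceEdges(stack, new("ThresholdSpec", channel = "red",
                                     t = numeric(0),
                                     threshold = numeric(0))),
               "control point")
})

test_that("raising the threshold never widens the detected core", {
  st <- lsFixture()
  widths <- vapply(seq(0.2, 0.8, by = 0.1), function(thr) {
    median(edgeDiameter(traceEdges(st, thresholdSpec("red", 0, thr))),
           na.rm = TRUE)
  }, 0)
  expect_true(all(diff(widths) <= 1e-9))
})

test_that("PVS width is the endfoot minus lumen diameter with QC flags", {
  l <- new("EdgeTrace", t = c(0, 1, 2), left = c(10, 10, 10),
           right = c(30, 30, 30), missing = rep(FALSE, 3))
  e <- new("EdgeTrace", t = c(0, 1, 2), left = c(6, 10, 11),
           right = c(34, 30, 29), missing = rep(FALSE, 3))
  pw <- pvsWidth(l, e)
  expect_equal(pw$total, c(8, 0, -2))
  expect_equal(pw$left, c(4, 0, -1))
  expect_identical(pw$qc_flag, c(FALSE, FALSE, TRUE))  # negative flagged
  bad <- new("EdgeTrace", t = c(0, 1), left = c(1, 1), right = c(2, 2),
             missing = c(FALSE, FALSE))
  expect_error(pvsWidth(l, bad), "time base")
})

test_that("vessels wider than the field of view are rejected", {
  h <- hypnogram(data.frame(state = "QW", t0 = 0, t1 = 1))
  p <- vesselParams(lumenBase = 30, endfootBase = 42, driftSd = 0)
  tr <- makeVesselTrace(h, p, seed = 2)
  expect_error(makeLinescan(tr, fov = 40, seed = 1), "field of view")
  expect_error(makeLinescan(tr, fov = 60, psfSd = 0, seed = 1), "PSF")
})

test_that("linescan stacks round-trip through TIFF + JSON", {
  st <- lsFixture()
  ds <- downsampleStack(st)
  sm <- new("LinescanStack", red = ds@red[, 1:40], green = ds@green[, 1:40],
            dx = ds@dx, fs = ds@fs, truth = ds@truth[1:40, ])
  path <- file.path(tempdir(), "scan.tiff")
  writeLinescan(sm, path)
  back <- readLinescan(path)
  expect_equal(dim(back@red), dim(sm@red))
  expect_equal(back@dx, sm@dx)
  expect_equal(back@fs, sm@fs)
  # 16-bit storage: intensities preserved to ~1/65535 (after clipping)
  expect_lt(max(abs(back@red - pmin(pmax(sm@red, 0), 1))), 2e-4)
  expect_equal(back@truth$lumen, sm@truth$lumen, tolerance = 1e-9)
})
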