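# Property tests on desk-scale grids (shorter domains and horizons keep the
# suite fast; the full 600 um study geometry is exercised in the acceptance
# tests).

dex70 <- knownSolutes()$dex70

test_that("with no flow the variance grows as 2 D t (heat-equation limit)", {
  m <- refModel(a_rel = 0, L = 300)
  sol <- solveTransport(m, dex70, T = 5,
                        ic = list(type = "gaussian", sigma = 4, center = 150),
                        bc = "closed", flowOn = FALSE)
  nT <- length(sol@t)
  slope <- (sol@variance[nT] - sol@variance[1]) / (sol@t[nT] - sol@t[1])
  expect_equal(slope / (2 * dex70@D), 1, tolerance = 0.01)
})

test_that("tracer mass is conserved to 1e-6 with no-flux boundaries and flow on", {
  m <- refModel(L = 300)
  sol <- solveTransport(m, dex70, T = 10,
                        ic = list(type = "gaussian", sigma = 4, center = 150),
                        bc = "closed")
  expect_lt(max(abs(sol@mass / sol@mass[1] - 1)), 1e-6)
})

test_that("the influx solution obeys the discrete maximum principle", {
  m <- refModel(L = 300)
  sol <- influxFront(m, dex70, depth = 150, Tmax = 40)
  expect_lt(sol@cmax, 1 + 1e-3)
  expect_gt(sol@cmin, -1e-3)
  # front is non-decreasing after time-smoothing over one period
  sm <- sol@front$depth_smooth
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) > -1e-6))
})

test_that("pure-diffusion influx matches the erfc closed form and scales as 1/D", {
  m <- refModel(a_rel = 0, L = 300)
  s1 <- influxFront(m, dex70, flowOn = FALSE, depth = 50, Tmax = 60)
  expect_equal(s1@t_front, erfcFrontTime(50, 17), tolerance = 0.05)
  fast <- soluteSpec("fast", 70, 34)
  s2 <- influxFront(m, fast, flowOn = FALSE, depth = 50, Tmax = 60)
  expect_equal(s1@t_front / s2@t_front, 2, tolerance = 0.02)
  # a front that never arrives is censored, not an error
  slow <- soluteSpec("slow", 2000, 2)
  s3 <- influxFront(m, slow, flowOn = FALSE, depth = 250, Tmax = 5)
  expect_true(is.na(s3@t_front))
  expect_true(s3@meta$censored)
})

test_that("oscillatory flow accelerates the influx front", {
  m <- refModel(L = 300)
  on <- influxFront(m, dex70, depth = 100, Tmax = 120)
  off <- influxFront(m, dex70, flowOn = FALSE, depth = 100, Tmax = 120)
  expect_lt(on@t_front, off@t_front)
})

test_that("zero-flow dispersion recovers the molecular diffusivity within 1%", {
  m <- refModel(a_rel = 0, L = 300)
  s <- dispersionEnhancement(m, dex70, T = 10, flowOn = FALSE)
  expect_equal(s@D_eff, dex70@D, tolerance = 0.01)
  expect_lt(abs(s@enhancement), 1)
  # fit and moment estimators agree within the 2% contract
  expect_equal(s@D_eff, s@meta$D_eff_moment, tolerance = 0.02)
})

test_that("steady-flow dispersion matches the Taylor-Aris quadrature oracle", {
  A <- pi * (16^2 - 10^2)
  m <- pvsModel(A_med = A, a_rel = 0, period = 1, R_ast = 16, L = 1200)
  sol <- solveTransport(m, dex70, T = 12,
                        ic = list(type = "gaussian", sigma = 5, center = 300),
                        bc = "open", steadyU = 30, ny = 1200, saveDt = 0.5)
  sel <- sol@t >= 4   # past the initial Taylor transient (h^2/D ~ 2 s)
  slope <- coef(lm(sol@variance[sel] ~ sol@t[sel]))[[2]]
  expect_equal(slope / 2, taylorArisAnnulus(10, 16, 30, dex70@D),
               tolerance = 0.1)
})

test_that("enhancement is non-negative and scales with amplitude squared", {
  r <- vapply(c(0.02, 0.04), function(a) {
    dispersionEnhancement(refModel(a_rel = a), dex70, T = 40)@enhancement
  }, 0)
  expect_true(all(r >= 0))
  expect_equal(r[2] / r[1], 4, tolerance = 0.4)  # within 10% of quadratic
})

test_that("enhancement decreases when the molecular diffusivity increases", {
  m <- refModel(L = 400)
  r <- vapply(c(10, 17, 34), function(D) {
    dispersionEnhancement(m, soluteSpec("s", 70, D), T = 10)@enhancement
  }, 0)
  expect_true(all(diff(r) < 0))
})

test_that("cardiac scenarios calibrate to the target peak velocity", {
  cs0 <- cardiacScenario(A_med = 250, R_ast = 12, targetUPeak = 0,
                         runDispersion = FALSE)
  expect_equal(cs0$a_rel, 0)
  r <- vapply(c(10, 50, 100), function(tg) {
    cs <- cardiacScenario(A_med = 250, R_ast = 12, targetUPeak = tg,
                          L = 400, T = 15)
    expect_equal(cs$u_peak, tg, tolerance = 0.01)
    cs$enhancement
  }, 0)
  expect_true(all(diff(r) > 0))   # enhancement rises with the driving speed
  expect_error(cardiacScenario(A_med = 250, R_ast = 12, targetUPeak = 10,
                               period = 2), "cardiac band")
})

test_that("unsafe explicit configurations and bad geometry are rejected", {
  m <- refModel(L = 300)
  expect_error(solveTransport(m, dex70, T = 1, dt = 0.2), "CFL")
  expect_error(solveTransport(m, dex70, T = 1, ny = 100), "1 um")
  expect_error(solveTransport(m, dex70, T = 1, nr = 4), "8 radial")
  expect_error(influxFront(m, dex70, depth = 400), "less than")
  expect_error(dispersionEnhancement(refModel(L = 80), dex70, T = 40),
               "boundary contamination")
})

test_that("halving step and cells changes the dispersion estimate by < 2%", {
  m <- refModel(L = 300)
  base <- dispersionEnhancement(m, dex70, T = 10, saveDt = 0.1)
  # halving the cell sizes also drives the auto-selected step well below
  # half the coarse-run step (axial diffusion CFL scales with dy^2)
  fine <- dispersionEnhancement(m, dex70, T = 10, saveDt = 0.1,
                                ny = 600, nr = 20)
  expect_equal(fine@D_eff / base@D_eff, 1, tolerance = 0.02)
})
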