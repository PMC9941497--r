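test_that("the area law evaluates the cosine form exactly", {
  m <- pvsModel(A_med = 100, a_rel = 0.1, period = 4, alpha = 0.25,
                R_ast = 12)
  expect_equal(areaLaw(m, 0), 100 * 1.05 - 25)
  tt <- seq(0, 4, length.out = 4001)
  A <- areaLaw(m, tt)
  expect_equal(max(A) - min(A), 10, tolerance = 1e-6)   # P-T = <A> a
  expect_equal(mean(A[-1]), 75, tolerance = 1e-4)
  # a_rel = 0: constant <A> - A_SMC
  m0 <- pvsModel(A_med = 100, a_rel = 0, period = 4, alpha = 0.25, R_ast = 12)
  expect_identical(unique(areaLaw(m0, tt)), 75)
  # collapse rejected
  expect_error(pvsModel(A_med = 100, a_rel = 1.2, period = 4, alpha = 0.5,
                        R_ast = 12), "collapses")
  expect_error(areaLaw(NULL, 0, A_med = 100, a_rel = 1.9, period = 1,
                       alpha = 0.2), "collapses")
})

test_that("the inner radius inverts the annulus area", {
  expect_equal(innerRadius(pi * 44, 12), 10)   # 144 - 44 = 100
  expect_equal(innerRadius(0, 7), 7)
  expect_error(innerRadius(pi * 145, 12), "R_ast")
  # R_v = 0 boundary is excluded by the model invariant
  expect_error(pvsModel(A_med = pi * 144, a_rel = 0, period = 1, R_ast = 12),
               "inner radius")
})

test_that("the reduced Stokes solution conserves mass and is quiescent without forcing", {
  m <- refModel()
  sol <- solvePvsFlow(m)
  expect_lt(massConservationResidual(sol), 1e-6)
  expect_equal(sol@u_mean[length(sol@y), ], rep(0, length(sol@t)))  # deep end
  expect_equal(sol@p[1, ], rep(0, length(sol@t)))                   # entrance
  m0 <- refModel(a_rel = 0)
  sol0 <- solvePvsFlow(m0)
  expect_equal(max(abs(sol0@u_mean)), 0)
  expect_equal(max(abs(sol0@p)), 0)
  expect_equal(peakVelocity(sol0), 0)
})

test_that("velocity and pressure scale linearly in the small-amplitude regime", {
  u1 <- peakVelocity(solvePvsFlow(refModel(a_rel = 0.025)))
  u2 <- peakVelocity(solvePvsFlow(refModel(a_rel = 0.05)))
  expect_equal(u2 / u1, 2, tolerance = 0.05)
  # halving the period doubles dA/dt, hence the velocity
  u3 <- peakVelocity(solvePvsFlow(refModel(a_rel = 0.025, period = 2.5)))
  expect_equal(u3 / u1, 2, tolerance = 0.05)
  # pressure gradient scales with viscosity at fixed kinematics
  m2x <- pvsModel(A_med = 250, a_rel = 0.05, period = 5, R_ast = 12,
                  fluids = fluidConstants(mu = 2 * 6.93e-4))
  dp1 <- pressureDrop(solvePvsFlow(refModel(a_rel = 0.05)))$dp_Pa
  dp2 <- pressureDrop(solvePvsFlow(m2x))$dp_Pa
  expect_equal(dp2 / dp1, 2, tolerance = 1e-6)
})

test_that("annular conductance approaches the plane-Poiseuille law in the thin gap", {
  mu <- 6.93e-4
  Ra <- 100e-6; h <- 1e-6; Rv <- Ra - h
  kAnn <- perivasc:::annularConductance(Rv, Ra, mu)
  kPlane <- 2 * pi * ((Ra + Rv) / 2) * h^3 / (12 * mu)
  expect_equal(kAnn / kPlane, 1, tolerance = 0.02)
  # conductance itself against independent numerical integration of the
  # velocity profile (flux per unit pressure gradient)
  Rv2 <- 8e-6; Ra2 <- 12e-6
  r <- seq(Rv2, Ra2, length.out = 20001)
  lnb <- log(Ra2 / Rv2)
  psi <- (Ra2^2 - r^2 - (Ra2^2 - Rv2^2) * log(Ra2 / r) / lnb) / (4 * mu)
  qNum <- 2 * pi * sum((psi * r)[-1] + (psi * r)[-length(r)]) / 2 *
    (r[2] - r[1])
  expect_equal(perivasc:::annularConductance(Rv2, Ra2, mu) / qNum, 1,
               tolerance = 1e-3)
})

test_that("peak velocity rises strictly with the obstructed fraction", {
  u <- vapply(c(0, 0.25, 0.5), function(al)
    peakVelocity(solvePvsFlow(refModel(alpha = al))), 0)
  expect_true(all(diff(u) > 0))
})

test_that("pressure outputs include the per-mm gradient", {
  sol <- solvePvsFlow(refModel())
  pd <- pressureDrop(sol)
  expect_equal(pd$grad_Pa_mm, pd$dp_Pa / 0.6)
  # 7 Pa over the 0.6 mm PVS corresponds to 11.7 Pa/mm
  expect_equal(7 / 0.6, 11.7, tolerance = 0.01)
})

test_that("Womersley and Reynolds estimates match the upper-bound inputs", {
  dn <- dimensionlessNumbers(10, 15, 200, fluidConstants(mu = 7e-4))
  expect_equal(signif(dn$Wo, 1), 0.1)
  expect_equal(signif(dn$Re, 1), 3e-3)
  expect_equal(dimensionlessNumbers(10, 0, 100)$Wo, 0)
  expect_error(dimensionlessNumbers(-1, 1, 1), "positive")
})
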