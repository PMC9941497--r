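# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Taylor-Aris effective diffusivity for steady annular Poiseuille flow with
# cross-section mean velocity U, via quadrature of the radial cell problem:
#   (1/r)(r B')' = u'(r),  B'(R_v) = B'(R_ast) = 0
#   D_eff = D + 2 int r B'^2 dr / ((R_ast^2 - R_v^2) D)
taylorArisAnnulus <- function(Rv, Ra, U, D, n = 4000) {
  r <- seq(Rv, Ra, length.out = n)
  lnb <- log(Ra / Rv)
  dR2 <- Ra^2 - Rv^2
  psi <- Ra^2 - r^2 - dR2 * log(Ra / r) / lnb
  psim <- (Ra^2 + Rv^2) / 2 - dR2 / (2 * lnb)
  uprime <- U * (psi / psim - 1)
  f <- uprime * r
  S <- c(0, cumsum((f[-1] + f[-n]) / 2 * diff(r)))   # int u' rho drho
  Bp <- S / r
  g <- r * Bp^2
  I <- sum((g[-1] + g[-n]) / 2 * diff(r))
  D + 2 * I / (dR2 * D)
}

# time for a semi-infinite diffusive front (entrance held at 1) to carry the
# level-`lev` contour to depth x:  c = erfc(x / (2 sqrt(D t)))
erfcFrontTime <- function(x, D, lev = 0.1) {
  # erfc(z) = lev  <=>  z = qnorm(1 - lev/2) / sqrt(2)
  z <- stats::qnorm(1 - lev / 2) / sqrt(2)
  (x / (2 * z))^2 / D
}

# brute-force oscillation statistics for a smooth signal whose local extrema
# already alternate (direct neighbour comparison, no merging logic)
bruteForceEvents <- function(x, t) {
  n <- length(x)
  kind <- integer(0)
  idx <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) { idx <- c(idx, i); kind <- c(kind, 1) }
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) { idx <- c(idx, i); kind <- c(kind, -1) }
  }
  ev <- NULL
  for (k in seq_along(idx)[-1]) {
    if (kind[k] == 1 && kind[k - 1] == -1) {
      ev <- rbind(ev, data.frame(t_trough = t[idx[k - 1]], t_peak = t[idx[k]],
                                 pt_amplitude = x[idx[k]] - x[idx[k - 1]]))
    }
  }
  ev
}

# exhaustive-enumeration oracle for the block-averaging factor
enumFactor <- function(rate, target, kmax = 50) {
  best <- 1L
  for (k in seq_len(kmax))
    if (abs(rate / k - target) < abs(rate / best - target)) best <- k
  best
}

# reference model reused across flow/transport tests (penetrating arteriole:
# outer radius 12 um, inner 8 um at the median, VLF-scale oscillation)
refModel <- function(a_rel = 0.1, period = 5, alpha = 0, L = 600) {
  pvsModel(A_med = 250, a_rel = a_rel, period = period, alpha = alpha,
           R_ast = 12, L = L)
}
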