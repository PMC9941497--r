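#' Cross-section area law
#'
#' Evaluates
#' \deqn{A(t) = \langle A \rangle (1 + a/2 \cos(2\pi t / p)) - A_{SMC}}
#' with \eqn{A_{SMC} = \alpha \langle A \rangle_{baseline}}.
#'
#' @param model a [PVSModel-class], or `NULL` to pass explicit parameters.
#' @param t times (s).
#' @param A_med,a_rel,period,alpha,A_baseline explicit parameters when
#'   `model` is `NULL`.
#' @return Free cross-section area (um^2) at `t`.
#' @export
#' @examples
#' m <- pvsModel(A_med = 100, a_rel = 0.1, period = 4, alpha = 0.25,
#'               R_ast = 12)
#' areaLaw(m, 0)  # 100 * 1.05 - 25 = 80
areaLaw <- function(model = NULL, t, A_med, a_rel, period, alpha = 0,
                    A_baseline = A_med) {
  if (!is.null(model)) {
    A_med <- model@A_med; a_rel <- model@a_rel; period <- model@period
    alpha <- model@alpha; A_baseline <- model@A_baseline
  }
  stopIfNot(a_rel >= 0, "a_rel must be non-negative")
  stopIfNot(period > 0, "period must be positive")
  Asmc <- alpha * A_baseline
  A <- A_med * (1 + a_rel / 2 * cos(2 * pi * t / period)) - Asmc
  if (A_med * (1 - a_rel / 2) - Asmc <= 0)
    stop("PVS collapses: min over t of A_pvs(t) <= 0", call. = FALSE)
  A
}

areaLawRate <- function(model, t) {
  -model@A_med * model@a_rel / 2 * (2 * pi / model@period) *
    sin(2 * pi * t / model@period)
}

#' Inner radius from the area law
#'
#' The outer (endfoot) cylinder is fixed, so
#' \eqn{R_v(t) = \sqrt{R_{ast}^2 - A_{pvs}(t)/\pi}}.
#'
#' @param A free PVS cross-section area (um^2).
#' @param R_ast fixed outer radius (um).
#' @return Inner radius (um).
#' @export
#' @examples
#' innerRadius(pi * 44, 12)  # 10
innerRadius <- function(A, R_ast) {
  if (any(A >= pi * R_ast^2))
    stop("A_pvs must stay below pi*R_ast^2", call. = FALSE)
  if (any(A < 0)) stop("A_pvs must be non-negative", call. = FALSE)
  sqrt(R_ast^2 - A / pi)
}

# annular Poiseuille helpers ------------------------------------------------

# conductance k such that Q = k * (-dp/dy); SI units (m, Pa, s)
annularConductance <- function(Rv, Ra, mu) {
  lnb <- log(Ra / Rv)
  pi / (8 * mu) * (Ra^4 - Rv^4 - (Ra^2 - Rv^2)^2 / lnb)
}

# ratio of peak to cross-section-mean velocity of the annular profile
annularPeakRatio <- function(Rv, Ra) {
  lnb <- log(Ra / Rv)
  dR2 <- Ra^2 - Rv^2
  psi <- function(r) Ra^2 - r^2 - dR2 * log(Ra / r) / lnb
  rStar <- sqrt(dR2 / (2 * lnb))
  psiMean <- (Ra^2 + Rv^2) / 2 - dR2 / (2 * lnb)
  psi(rStar) / psiMean
}

#' Solve quasi-steady Stokes flow in the deforming annular PVS
#'
#' Quasi-steady incompressible Stokes flow driven by the uniform radial
#' deformation of the inner wall, with no-slip on both walls, zero reference
#' pressure at the surface entrance (y = 0) and no flow at the deep end
#' (y = L). Because the deformation is axially uniform and the Womersley and
#' Reynolds numbers are small, the solution reduces to mass conservation
#' plus annular Poiseuille resistance: the volume flux is
#' \eqn{Q(y,t) = dA/dt (L - y)}, the mean velocity \eqn{u = Q/A}, the axial
#' profile is the classical annulus profile between \eqn{R_v(t)} and
#' \eqn{R_{ast}}, and the pressure gradient follows from the conductance.
#'
#' @param model a [PVSModel-class].
#' @param nt time samples per period (default 400; two periods are
#'   simulated).
#' @param ny axial grid points (default 121).
#' @param nPeriods number of oscillation periods.
#' @return A [FlowSolution-class]. Velocities in um/s, pressure in Pa.
#' @export
#' @examples
#' m <- pvsModel(A_med = 250, a_rel = 0.1, period = 5, R_ast = 12)
#' sol <- solvePvsFlow(m)
#' peakVelocity(sol)
solvePvsFlow <- function(model, nt = 400, ny = 121, nPeriods = 2) {
  validObject(model)
  t <- seq(0, nPeriods * model@period, length.out = nt * nPeriods + 1)
  y <- seq(0, model@L, length.out = ny)
  A <- areaLaw(model, t)
  g <- areaLawRate(model, t)
  Rv <- innerRadius(A, model@R_ast)
  # mean velocity u(y, t) = g (L - y) / A   [um/s]
  u <- outer(model@L - y, g / A)
  # pressure: dp/dy = -Q/k, Q(y) = g (L - y)  ->  p(y) = -(g/k)(L y - y^2/2)
  mu <- model@fluids@mu
  k <- annularConductance(Rv * 1e-6, model@R_ast * 1e-6, mu)  # m^4/(Pa s)
  gSI <- g * 1e-12                                            # m^2/s
  ySI <- y * 1e-6
  p <- -outer(model@L * 1e-6 * ySI - ySI^2 / 2, gSI / k)      # Pa
  ratio <- vapply(Rv, function(r) annularPeakRatio(r, model@R_ast), 0)
  uPeak <- max(abs(u[1, ] * ratio))
  new("FlowSolution", y = y, t = t, u_mean = u, p = p, A = A, dAdt = g,
      R_v = Rv, u_peak = uPeak, model = model)
}

#' Peak fluid velocity of a flow solution
#'
#' Maximum over radius, depth and time of the axial velocity magnitude;
#' attained at the surface entrance (y = 0) at the radius where the annular
#' profile peaks.
#'
#' @param sol a [FlowSolution-class].
#' @return Peak velocity (um/s).
#' @export
peakVelocity <- function(sol) sol@u_peak

#' Pressure drop along the PVS
#'
#' @param sol a [FlowSolution-class].
#' @return list with `dp_Pa` (max over t of |p(L, t) - p(0, t)|) and
#'   `grad_Pa_mm` (the same divided by the PVS length in mm; 7 Pa over
#'   0.6 mm gives 11.7 Pa/mm).
#' @export
pressureDrop <- function(sol) {
  dp <- max(abs(sol@p[length(sol@y), ] - sol@p[1, ]))
  list(dp_Pa = dp, grad_Pa_mm = dp / (sol@model@L / 1000))
}

#' Mass-conservation residual of a flow solution
#'
#' Evaluates \eqn{\partial A/\partial t + \partial (A u)/\partial y} on the
#' solution grid (analytic time derivative, central differences in y) and
#' returns the maximum magnitude relative to the peak area rate.
#'
#' @param sol a [FlowSolution-class].
#' @return Relative residual (dimensionless).
#' @export
massConservationResidual <- function(sol) {
  ny <- length(sol@y)
  dy <- sol@y[2] - sol@y[1]
  Au <- sweep(sol@u_mean, 2, sol@A, `*`)
  dAu <- (Au[3:ny, , drop = FALSE] - Au[1:(ny - 2), , drop = FALSE]) /
    (2 * dy)
  res <- sweep(dAu, 2, sol@dAdt, `+`)
  scale <- max(abs(sol@dAdt), 1e-300)
  max(abs(res)) / scale
}

#' Womersley and Reynolds numbers
#'
#' \eqn{Wo = h \sqrt{2 \rho \pi f / \mu}} and \eqn{Re = \rho u h / \mu},
#' evaluated in SI from the given gap width, frequency and velocity.
#'
#' @param h PVS gap width (um).
#' @param f oscillation frequency (Hz); may be 0.
#' @param u fluid velocity (um/s); may be 0.
#' @param fluids [FluidConstants-class].
#' @return list with `Wo` and `Re`.
#' @export
#' @examples
#' dimensionlessNumbers(10, 15, 200, fluidConstants(mu = 7e-4))
dimensionlessNumbers <- function(h, f, u, fluids = fluidConstants()) {
  stopIfNot(h > 0, "h must be positive")
  stopIfNot(f >= 0 && u >= 0, "f and u must be non-negative")
  hSI <- h * 1e-6
  uSI <- u * 1e-6
  list(Wo = hSI * sqrt(2 * fluids@rho * pi * f / fluids@mu),
       Re = fluids@rho * uSI * hSI / fluids@mu)
}
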