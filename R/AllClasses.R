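#' Hypnogram: ordered, labelled sleep/wake intervals
#'
#' An ordered, contiguous, non-overlapping sequence of sleep-wake state
#' intervals. Microarousals (MA) must lie inside NREM/IS spans and last at
#' least 1 s but less than 10 s.
#'
#' @slot intervals data.frame with columns `state`, `t0`, `t1` (seconds).
#' @seealso [hypnogram()], [makeHypnogram()], [stateAtTime()]
#' @export
setClass("Hypnogram", slots = c(intervals = "data.frame"))

setValidity("Hypnogram", function(object) {
  iv <- object@intervals
  if (!all(c("state", "t0", "t1") %in% names(iv)))
    return("intervals must have columns state, t0, t1")
  if (nrow(iv) == 0) return("hypnogram has no intervals")
  if (!all(iv$state %in% sleepStates()))
    return(paste("unknown state label(s):",
                 paste(setdiff(iv$state, sleepStates()), collapse = ", ")))
  if (any(iv$t1 <= iv$t0)) return("every interval needs t1 > t0")
  if (nrow(iv) > 1) {
    gaps <- iv$t0[-1] - iv$t1[-nrow(iv)]
    if (any(abs(gaps) > 1e-8))
      return("intervals must be contiguous and non-overlapping")
  }
  ma <- which(iv$state == "MA")
  for (k in ma) {
    d <- iv$t1[k] - iv$t0[k]
    if (d < 1 - 1e-9 || d >= 10)
      return("MA duration must satisfy 1 s <= d < 10 s")
    nb <- c(if (k > 1) iv$state[k - 1], if (k < nrow(iv)) iv$state[k + 1])
    if (!any(nb %in% c("NREM", "IS")))
      return("MA intervals may only occur inside NREM or IS spans")
  }
  TRUE
})

#' Construct a Hypnogram
#'
#' @param intervals data.frame with columns `state`, `t0`, `t1` (seconds),
#'   contiguous and ordered in time.
#' @return A [Hypnogram-class] object.
#' @export
#' @examples
#' hypnogram(data.frame(state = c("WBS", "NREM"), t0 = c(0, 15), t1 = c(15, 75)))
hypnogram <- function(intervals) {
  intervals <- as.data.frame(intervals)
  intervals$state <- as.character(intervals$state)
  new("Hypnogram", intervals = intervals)
}

#' VesselTrace: diameter time series for one vessel
#'
#' Uniformly sampled lumen diameter, endfoot-tube diameter and PVS width for
#' a single vessel, with a per-sample sleep-wake state label. The PVS width
#' is identically the endfoot diameter minus the lumen diameter.
#'
#' @slot vessel_id character scalar.
#' @slot kind one of `"pial_artery"`, `"penetrating_arteriole"`, `"venule"`.
#' @slot fs sampling rate (Hz).
#' @slot t time (s).
#' @slot lumen lumen diameter (um).
#' @slot endfoot endfoot tube diameter (um).
#' @slot pvs total PVS width (um), `endfoot - lumen`.
#' @slot state per-sample state label.
#' @slot center rigid tissue drift of the structure centreline (um); may be
#'   empty.
#' @seealso [vesselTrace()], [makeVesselTrace()]
#' @export
setClass("VesselTrace",
         slots = c(vessel_id = "character", kind = "character",
                   fs = "numeric", t = "numeric", lumen = "numeric",
                   endfoot = "numeric", pvs = "numeric", state = "character",
                   center = "numeric"))

setValidity("VesselTrace", function(object) {
  n <- length(object@t)
  if (length(object@lumen) != n || length(object@endfoot) != n ||
      length(object@pvs) != n || length(object@state) != n)
    return("t, lumen, endfoot, pvs and state must have equal length")
  if (length(object@center) && length(object@center) != n)
    return("center must be empty or match the sample count")
  if (!object@kind %in% c("pial_artery", "penetrating_arteriole", "venule"))
    return("kind must be pial_artery, penetrating_arteriole or venule")
  if (any(object@lumen <= 0)) return("lumen diameters must be positive")
  if (any(object@endfoot <= object@lumen))
    return("endfoot diameter must exceed lumen diameter at every sample")
  err <- max(abs(object@pvs - (object@endfoot - object@lumen)))
  if (err > 1e-9 * max(1, max(abs(object@endfoot))))
    return("pvs must equal endfoot - lumen at every sample")
  if (n > 1) {
    dt <- diff(object@t)
    if (max(abs(dt - 1 / object@fs)) > 1e-6 / object@fs)
      return("sampling must be uniform at rate fs")
  }
  TRUE
})

#' Construct a VesselTrace
#'
#' @param vessel_id identifier.
#' @param kind vessel kind.
#' @param fs sampling rate (Hz).
#' @param t time (s).
#' @param lumen,endfoot diameters (um).
#' @param state per-sample state label (recycled if scalar).
#' @param center optional rigid drift (um).
#' @return A [VesselTrace-class] object; `pvs` is computed as
#'   `endfoot - lumen`.
#' @export
vesselTrace <- function(vessel_id, kind, fs, t, lumen, endfoot,
                        state = "QW", center = numeric()) {
  if (length(state) == 1) state <- rep(state, length(t))
  new("VesselTrace", vessel_id = as.character(vessel_id), kind = kind,
      fs = fs, t = as.numeric(t), lumen = as.numeric(lumen),
      endfoot = as.numeric(endfoot),
      pvs = as.numeric(endfoot) - as.numeric(lumen),
      state = as.character(state), center = as.numeric(center))
}

#' LinescanStack: synthetic two-photon x-t linescan
#'
#' Red (lumen dye) and green (astrocyte endfoot) intensity arrays with space
#' along rows and time along columns, plus the optical sampling parameters
#' and (for synthetic stacks) the embedded ground-truth diameters.
#'
#' @slot red,green numeric matrices (x along rows, t along columns).
#' @slot dx spatial sampling (um per sample).
#' @slot fs frame rate (Hz).
#' @slot truth data.frame with columns `t`, `lumen`, `endfoot`, `center`
#'   (zero rows when unknown).
#' @seealso [makeLinescan()], [downsampleStack()], [traceEdges()]
#' @export
setClass("LinescanStack",
         slots = c(red = "matrix", green = "matrix", dx = "numeric",
                   fs = "numeric", truth = "data.frame"))

setValidity("LinescanStack", function(object) {
  if (!all(dim(object@red) == dim(object@green)))
    return("red and green channels must have identical dimensions")
  if (object@dx <= 0) return("dx must be positive")
  if (object@fs <= 0) return("fs must be positive")
  TRUE
})

#' PhysioSignals: ECoG and EMG traces
#'
#' @slot ecog electrocorticography signal (a.u.), band-limited 0.5-30 Hz.
#' @slot emg nuchal EMG signal (a.u.; broadband, amplitude-modulated).
#' @slot fs sampling rate (Hz), at least 100.
#' @seealso [makeEcogEmg()], [scoreSleepStates()]
#' @export
setClass("PhysioSignals",
         slots = c(ecog = "numeric", emg = "numeric", fs = "numeric"))

setValidity("PhysioSignals", function(object) {
  if (length(object@ecog) != length(object@emg))
    return("ecog and emg must have equal length")
  if (object@fs < 100) return("fs must be at least 100 Hz")
  TRUE
})

#' ThresholdSpec: time-interpolated intensity thresholds
#'
#' Control points (time, threshold) that are linearly interpolated across the
#' scan, with constant extrapolation beyond the first and last point. This is
#' the programmatic replacement for interactively adjusted thresholds.
#'
#' @slot channel `"red"` or `"green"`.
#' @slot t control-point times (s), ordered.
#' @slot threshold intensity thresholds (a.u.).
#' @seealso [thresholdSpec()], [traceEdges()]
#' @export
setClass("ThresholdSpec",
         slots = c(channel = "character", t = "numeric",
                   threshold = "numeric"))

setValidity("ThresholdSpec", function(object) {
  if (length(object@t) < 1) return("at least one control point is required")
  if (length(object@t) != length(object@threshold))
    return("t and threshold must have equal length")
  if (is.unsorted(object@t)) return("control points must be ordered in t")
  if (!object@channel %in% c("red", "green"))
    return("channel must be 'red' or 'green'")
  TRUE
})

#' Construct a ThresholdSpec
#' @param channel `"red"` or `"green"`.
#' @param t control-point times (s).
#' @param threshold intensity thresholds (a.u.).
#' @return A [ThresholdSpec-class] object.
#' @export
thresholdSpec <- function(channel, t, threshold) {
  new("ThresholdSpec", channel = channel, t = as.numeric(t),
      threshold = as.numeric(threshold))
}

#' EdgeTrace: traced structure edges over time
#'
#' Left/right edge positions (um) of one structure (lumen or endfoot tube)
#' per frame; frames where no threshold crossing exists are flagged missing
#' and never interpolated.
#'
#' @slot t frame times (s).
#' @slot left,right edge positions (um).
#' @slot missing logical mask.
#' @seealso [traceEdges()], [edgeDiameter()], [pvsWidth()]
#' @export
setClass("EdgeTrace",
         slots = c(t = "numeric", left = "numeric", right = "numeric",
                   missing = "logical"))

setValidity("EdgeTrace", function(object) {
  n <- length(object@t)
  if (length(object@left) != n || length(object@right) != n ||
      length(object@missing) != n)
    return("t, left, right, missing must have equal length")
  ok <- !object@missing
  if (any(object@right[ok] < object@left[ok]))
    return("right edge must not lie left of the left edge")
  TRUE
})

#' FluidConstants: CSF fluid properties
#'
#' @slot mu dynamic viscosity (Pa s). Default 6.93e-4 (water at 35 C).
#' @slot rho density (kg/m^3); used only for dimensionless numbers.
#' @export
setClass("FluidConstants", slots = c(mu = "numeric", rho = "numeric"))

setValidity("FluidConstants", function(object) {
  if (object@mu <= 0 || object@rho <= 0) return("mu and rho must be positive")
  TRUE
})

#' Construct fluid constants
#'
#' Defaults are water viscosity at 35 C (0.693 mPa s) and unit density
#' (1 g/cm^3). The rounded value 7e-4 Pa s used for the dimensionless-number
#' estimates can be passed explicitly.
#'
#' @param mu dynamic viscosity (Pa s).
#' @param rho density (kg/m^3).
#' @return A [FluidConstants-class] object.
#' @export
#' @examples
#' fluidConstants()
fluidConstants <- function(mu = 6.93e-4, rho = 1000) {
  new("FluidConstants", mu = mu, rho = rho)
}

#' PVSModel: geometry and area-law parameters for one simulation
#'
#' Defines an axisymmetric annular PVS of length `L` with fixed outer radius
#' `R_ast` whose free cross-section area follows
#' \deqn{A(t) = \langle A \rangle (1 + a/2 \cos(2\pi t / p)) - A_{SMC},}
#' where \eqn{A_{SMC} = \alpha \langle A \rangle_{baseline}} is the area
#' occupied by smooth muscle cells and other obstructing constituents.
#'
#' @slot L PVS length (um).
#' @slot R_ast fixed outer (endfoot tube) radius (um).
#' @slot A_med median free PVS cross-section area \eqn{\langle A \rangle}
#'   (um^2).
#' @slot a_rel relative peak-to-trough area amplitude (dimensionless).
#' @slot period oscillation period (s), the median lumen P-P period.
#' @slot alpha obstructed fraction of the baseline PVS area, in [0, 1).
#' @slot A_baseline baseline (quiet wakefulness) median PVS area (um^2).
#' @slot fluids [FluidConstants-class].
#' @seealso [pvsModel()], [areaLaw()], [solvePvsFlow()]
#' @export
setClass("PVSModel",
         slots = c(L = "numeric", R_ast = "numeric", A_med = "numeric",
                   a_rel = "numeric", period = "numeric", alpha = "numeric",
                   A_baseline = "numeric", fluids = "FluidConstants"))

setValidity("PVSModel", function(object) {
  if (object@L <= 0) return("L must be positive")
  if (object@R_ast <= 0) return("R_ast must be positive")
  if (object@a_rel < 0) return("a_rel must be non-negative")
  if (object@period <= 0) return("period must be positive")
  if (object@alpha < 0 || object@alpha >= 1) return("alpha must lie in [0, 1)")
  Asmc <- object@alpha * object@A_baseline
  Amin <- object@A_med * (1 - object@a_rel / 2) - Asmc
  Amax <- object@A_med * (1 + object@a_rel / 2) - Asmc
  if (Amin <= 0) return("PVS collapses: min over t of A_pvs(t) <= 0")
  if (Amax >= pi * object@R_ast^2)
    return("A_pvs(t) exceeds pi*R_ast^2: inner radius would vanish")
  TRUE
})

#' Construct a PVSModel
#'
#' @param A_med median free PVS cross-section area (um^2).
#' @param a_rel relative peak-to-trough area amplitude.
#' @param period oscillation period (s).
#' @param alpha obstructed fraction of the baseline area (0, 0.25, 0.5 in the
#'   reference scenarios; any value in [0, 1) is accepted).
#' @param R_ast fixed outer radius (um). Defaults to the radius that makes
#'   the baseline inner radius 8 um (a typical penetrating arteriole).
#' @param L PVS length (um); default 600.
#' @param A_baseline baseline median PVS area used for the obstruction term;
#'   defaults to `A_med`.
#' @param fluids [FluidConstants-class]; default [fluidConstants()].
#' @return A [PVSModel-class] object.
#' @export
#' @examples
#' m <- pvsModel(A_med = 250, a_rel = 0.1, period = 5, alpha = 0.25,
#'               R_ast = 12)
#' m
pvsModel <- function(A_med, a_rel, period, alpha = 0, R_ast = NULL, L = 600,
                     A_baseline = A_med, fluids = fluidConstants()) {
  if (is.null(R_ast)) R_ast <- sqrt(8^2 + A_med / pi)
  new("PVSModel", L = L, R_ast = R_ast, A_med = A_med, a_rel = a_rel,
      period = period, alpha = alpha, A_baseline = A_baseline,
      fluids = fluids)
}

#' FlowSolution: quasi-steady Stokes flow in the deforming annulus
#'
#' @slot y axial grid (um), 0 at the surface entrance.
#' @slot t time grid (s).
#' @slot u_mean cross-section mean axial velocity (um/s), `length(y)` by
#'   `length(t)`; positive into the brain.
#' @slot p pressure (Pa), same shape; `p[1, ] == 0`.
#' @slot A free cross-section area (um^2) at each time.
#' @slot dAdt its analytic time derivative (um^2/s).
#' @slot R_v inner (vessel) radius (um) at each time.
#' @slot u_peak maximum over r, y, t of the axial velocity magnitude (um/s).
#' @slot model the [PVSModel-class] solved.
#' @seealso [solvePvsFlow()], [peakVelocity()], [pressureDrop()]
#' @export
setClass("FlowSolution",
         slots = c(y = "numeric", t = "numeric", u_mean = "matrix",
                   p = "matrix", A = "numeric", dAdt = "numeric",
                   R_v = "numeric", u_peak = "numeric", model = "PVSModel"))

#' SoluteSpec: tracer molecular properties
#'
#' @slot name solute name.
#' @slot mw molecular weight (kDa).
#' @slot D molecular diffusion coefficient in CSF (um^2/s).
#' @seealso [soluteSpec()], [knownSolutes()]
#' @export
setClass("SoluteSpec",
         slots = c(name = "character", mw = "numeric", D = "numeric"))

setValidity("SoluteSpec", function(object) {
  if (object@D <= 0) return("D must be positive")
  TRUE
})

#' Construct a SoluteSpec
#' @param name solute name.
#' @param mw molecular weight (kDa).
#' @param D molecular diffusion coefficient (um^2/s).
#' @return A [SoluteSpec-class] object.
#' @export
soluteSpec <- function(name, mw, D) new("SoluteSpec", name = name,
                                        mw = mw, D = D)

#' Registry of dextran tracers
#'
#' Returns the dextran tracers used in the transport analyses. For 70 kDa
#' dextran the molecular diffusion coefficient is 17 um^2/s (apparent
#' diffusion 0.84e-7 cm^2/s in neuropil with tortuosity 2). For 2000 kDa the
#' literature value printed alongside it is 68 um^2/s; because that exceeds
#' the 70 kDa coefficient (physically inverted for a larger molecule), the
#' alternative reading 6.8 um^2/s is also provided; neither is asserted as
#' the intended value.
#'
#' @return Named list of [SoluteSpec-class] objects: `dex70`, `dex2000`,
#'   `dex2000_alt`.
#' @export
#' @examples
#' knownSolutes()$dex70
knownSolutes <- function() {
  list(dex70 = soluteSpec("dextran-70kDa", 70, 17),
       dex2000 = soluteSpec("dextran-2000kDa", 2000, 68),
       dex2000_alt = soluteSpec("dextran-2000kDa-alt", 2000, 6.8))
}

#' TransportSolution: concentration field and derived transport measures
#'
#' @slot y axial cell centres (um).
#' @slot t saved times (s).
#' @slot cbar cross-section-averaged concentration, `length(y)` by
#'   `length(t)`.
#' @slot mass total tracer mass (a.u.) at saved times.
#' @slot variance axial variance of the concentration distribution (um^2).
#' @slot front data.frame `t`, `depth`: concentration-front trajectory (um).
#' @slot t_front first time the front reaches the requested depth (s);
#'   `NA` when censored or not requested.
#' @slot D_eff fitted effective diffusivity (um^2/s); empty if not computed.
#' @slot enhancement dispersion enhancement (%); empty if not computed.
#' @slot cmax,cmin extreme concentrations seen during the run.
#' @slot solute the [SoluteSpec-class] transported.
#' @slot model the [PVSModel-class] geometry.
#' @slot meta list of solver settings (dt, dy, nr, bc, ...).
#' @seealso [solveTransport()], [dispersionEnhancement()], [influxFront()]
#' @export
setClass("TransportSolution",
         slots = c(y = "numeric", t = "numeric", cbar = "matrix",
                   mass = "numeric", variance = "numeric",
                   front = "data.frame", t_front = "numeric",
                   D_eff = "numeric", enhancement = "numeric",
                   cmax = "numeric", cmin = "numeric",
                   solute = "SoluteSpec", model = "PVSModel",
                   meta = "list"))
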