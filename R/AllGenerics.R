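#' Accessors
#'
#' Small accessor generics for the package's data classes.
#'
#' @param x an object.
#' @name accessors
NULL

#' @describeIn accessors interval table of a [Hypnogram-class].
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname accessors
#' @export
setMethod("intervals", "Hypnogram", function(x) x@intervals)

#' @describeIn accessors total duration (s).
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setMethod("duration", "Hypnogram", function(x) {
  iv <- x@intervals
  iv$t1[nrow(iv)] - iv$t0[1]
})

#' @describeIn accessors sampling rate (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "VesselTrace", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("samplingRate", "LinescanStack", function(x) x@fs)

#' @rdname accessors
#' @export
setMethod("samplingRate", "PhysioSignals", function(x) x@fs)

#' State label at given times
#'
#' @param x a [Hypnogram-class].
#' @param t times (s).
#' @return Character vector of state labels (`NA` outside the hypnogram).
#' @export
#' @examples
#' h <- makeHypnogram(nCycles = 1, seed = 1)
#' stateAtTime(h, c(1, 20))
stateAtTime <- function(x, t) {
  iv <- intervals(x)
  idx <- findInterval(t, iv$t0)
  out <- rep(NA_character_, length(t))
  ok <- idx >= 1 & t <= iv$t1[pmax(idx, 1)] + 1e-9
  out[ok] <- iv$state[idx[ok]]
  out
}

#' Diameter from an edge trace
#'
#' @param x an [EdgeTrace-class].
#' @return Numeric diameter (um), `NA` where frames are missing.
#' @export
edgeDiameter <- function(x) {
  d <- x@right - x@left
  d[x@missing] <- NA_real_
  d
}

setMethod("show", "Hypnogram", function(object) {
  iv <- object@intervals
  cat("Hypnogram:", nrow(iv), "intervals,",
      sprintf("%.1f s", duration(object)), "\n")
  tb <- tapply(iv$t1 - iv$t0, iv$state, sum)
  cat("  time per state (s):",
      paste(sprintf("%s=%.1f", names(tb), tb), collapse = ", "), "\n")
})

setMethod("show", "VesselTrace", function(object) {
  cat("VesselTrace", object@vessel_id, sprintf("(%s)", object@kind), "\n")
  cat(sprintf("  %d samples at %g Hz (%.1f s)\n", length(object@t),
              object@fs, length(object@t) / object@fs))
  cat(sprintf("  lumen %.2f um, endfoot %.2f um, PVS width %.2f um (medians)\n",
              median(object@lumen), median(object@endfoot),
              median(object@pvs)))
})

setMethod("show", "LinescanStack", function(object) {
  cat(sprintf("LinescanStack: %d x-samples x %d frames, dx = %g um, fs = %g Hz\n",
              nrow(object@red), ncol(object@red), object@dx, object@fs))
  if (nrow(object@truth)) cat("  ground truth embedded\n")
})

setMethod("show", "PVSModel", function(object) {
  cat("PVSModel: annular PVS, L =", object@L, "um, R_ast =",
      sprintf("%.2f um\n", object@R_ast))
  cat(sprintf("  <A> = %.1f um^2, a_rel = %.3f, period = %.3g s, alpha = %g\n",
              object@A_med, object@a_rel, object@period, object@alpha))
})

setMethod("show", "FlowSolution", function(object) {
  cat("FlowSolution:", length(object@y), "axial x", length(object@t),
      "time points\n")
  cat(sprintf("  u_peak = %.2f um/s, max |dp| = %.3g Pa\n", object@u_peak,
              max(abs(object@p[length(object@y), ]))))
})

setMethod("show", "TransportSolution", function(object) {
  cat("TransportSolution:", length(object@y), "axial cells,",
      length(object@t), "saved times\n")
  if (length(object@D_eff))
    cat(sprintf("  D_eff = %.3f um^2/s (enhancement %.2f%%)\n",
                object@D_eff, object@enhancement))
  if (length(object@t_front) && !is.na(object@t_front))
    cat(sprintf("  front reached target depth at t = %.1f s\n",
                object@t_front))
})
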