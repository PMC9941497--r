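#' Synthesise a two-photon x-t linescan stack from a vessel trace
#'
#' Renders an x-t intensity stack for a cross-sectional linescan placed over
#' a vessel. The red channel is a boxcar of width equal to the lumen diameter
#' (dye-filled lumen); the green channel is two bands flanking the lumen
#' whose outer edges are the endfoot diameter apart (astrocyte endfeet).
#' Both are convolved along x with a Gaussian point-spread function and
#' corrupted with additive Gaussian noise. The structure centreline follows
#' the trace's rigid tissue drift. Ground-truth diameters are embedded.
#'
#' @param trace a [VesselTrace-class].
#' @param fov field of view (um); the vessel is centred in it.
#' @param dx spatial sampling (um/sample). The default 0.025 um (40
#'   samples/um) downsamples cleanly to the 20 samples/um working
#'   resolution.
#' @param fs frame rate (Hz); 250 or 333 in the recordings emulated. The
#'   trace is linearly interpolated onto the frame clock.
#' @param psfSd Gaussian PSF standard deviation (um); must be positive.
#' @param noiseSd additive intensity noise s.d. (plateau intensity is 1).
#' @param seed integer seed (irrelevant when `noiseSd = 0`).
#' @return A [LinescanStack-class] with embedded truth.
#' @export
#' @examples
#' h <- makeHypnogram(nCycles = 1, seed = 1)
#' tr <- makeVesselTrace(h, vesselParams(), seed = 1)
#' st <- makeLinescan(tr, fov = 40, fs = 250, seed = 1)
#' st
makeLinescan <- function(trace, fov = 40, dx = 0.025, fs = 250,
                         psfSd = 0.3, noiseSd = 0.05, seed = NULL) {
  stopIfNot(psfSd > 0, "PSF standard deviation must be positive")
  stopIfNot(dx > 0, "dx must be positive")
  tEnd <- trace@t[length(trace@t)]
  tf <- seq(trace@t[1], tEnd, by = 1 / fs)
  lum <- approx(trace@t, trace@lumen, tf, rule = 2)$y
  end <- approx(trace@t, trace@endfoot, tf, rule = 2)$y
  cen <- if (length(trace@center))
    approx(trace@t, trace@center, tf, rule = 2)$y else numeric(length(tf))
  if (max(end + 2 * abs(cen)) >= fov)
    stop("vessel wider than the field of view: enlarge fov", call. = FALSE)

  x <- seq(dx / 2, fov - dx / 2, by = dx)
  nf <- length(tf)
  cx <- fov / 2 + cen
  # analytic Gaussian-blurred box edges: a top-hat [a, b] convolved with a
  # Gaussian PSF is (Phi((x-a)/s) - Phi((x-b)/s))
  blurBox <- function(a, b) {
    # x varies along rows, frames along columns
    A <- matrix(a, nrow = length(x), ncol = nf, byrow = TRUE)
    B <- matrix(b, nrow = length(x), ncol = nf, byrow = TRUE)
    X <- matrix(x, nrow = length(x), ncol = nf)
    stats::pnorm((X - A) / psfSd) - stats::pnorm((X - B) / psfSd)
  }
  red <- blurBox(cx - lum / 2, cx + lum / 2)
  green <- blurBox(cx - end / 2, cx + end / 2) -
    blurBox(cx - lum / 2, cx + lum / 2)
  withSeed(seed, {
    if (noiseSd > 0) {
      red <- red + matrix(rnorm(length(red), 0, noiseSd), nrow = nrow(red))
      green <- green + matrix(rnorm(length(green), 0, noiseSd),
                              nrow = nrow(green))
    }
    new("LinescanStack", red = red, green = green, dx = dx, fs = fs,
        truth = data.frame(t = tf, lumen = lum, endfoot = end, center = cen))
  })
}
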