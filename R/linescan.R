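#' Spatiotemporally downsample a linescan stack
#'
#' Block-averages an integer number of samples in time and space to most
#' closely reach a working rate of 100 Hz and 20 samples per micrometre.
#' Each factor is the positive integer minimising the distance of the
#' resulting rate from the target; ties break toward the smaller factor.
#' Block means preserve the DC level of each block exactly. Embedded truth
#' is block-averaged on the same temporal grid.
#'
#' @param stack a [LinescanStack-class].
#' @param targetFs target frame rate (Hz), default 100.
#' @param targetSpm target spatial density (samples/um), default 20.
#' @return A downsampled [LinescanStack-class].
#' @export
#' @examples
#' downsampleFactor(250, 100)   # 3
#' downsampleFactor(333, 100)   # 3
downsampleStack <- function(stack, targetFs = 100, targetSpm = 20) {
  kt <- downsampleFactor(stack@fs, targetFs)
  kx <- downsampleFactor(1 / stack@dx, targetSpm)
  red <- blockMean2(stack@red, kx, kt)
  green <- blockMean2(stack@green, kx, kt)
  truth <- stack@truth
  if (nrow(truth)) {
    nt <- ncol(red)
    idx <- rep(seq_len(nt), each = kt)[seq_len(nt * kt)]
    agg <- function(v) as.numeric(tapply(v[seq_len(nt * kt)], idx, mean))
    truth <- data.frame(t = agg(truth$t), lumen = agg(truth$lumen),
                        endfoot = agg(truth$endfoot),
                        center = agg(truth$center))
  }
  new("LinescanStack", red = red, green = green, dx = stack@dx * kx,
      fs = stack@fs / kt, truth = truth)
}

#' @describeIn downsampleStack the integer factor minimising
#'   `|rate/k - target|` (ties toward the smaller factor).
#' @param rate sampling rate before downsampling.
#' @param target target rate after downsampling.
#' @export
downsampleFactor <- function(rate, target) {
  ks <- seq_len(max(1L, ceiling(rate / target) * 4L))
  err <- abs(rate / ks - target)
  ks[which.min(err)]  # which.min returns the first (smallest) minimiser
}

blockMean2 <- function(m, kx, kt) {
  nx <- nrow(m) %/% kx
  nt <- ncol(m) %/% kt
  m <- m[seq_len(nx * kx), seq_len(nt * kt), drop = FALSE]
  if (kx > 1) {
    grp <- rep(seq_len(nx), each = kx)
    m <- rowsum(m, grp) / kx
  }
  if (kt > 1) {
    grp <- rep(seq_len(nt), each = kt)
    m <- t(rowsum(t(m), grp) / kt)
  }
  m
}

#' Automatic per-frame threshold
#'
#' Half-maximum between robust background and foreground intensity
#' percentiles of each frame, returned as a [ThresholdSpec-class] with one
#' control point per frame. This is the automated default standing in for
#' interactively chosen thresholds.
#'
#' @param stack a [LinescanStack-class].
#' @param channel `"red"` or `"green"`.
#' @param bgQuantile,fgQuantile background/foreground percentiles.
#' @return A [ThresholdSpec-class].
#' @export
autoThreshold <- function(stack, channel = c("red", "green"),
                          bgQuantile = 0.1, fgQuantile = 0.95) {
  channel <- match.arg(channel)
  m <- slot(stack, channel)
  tf <- seq(0, by = 1 / stack@fs, length.out = ncol(m))
  thr <- apply(m, 2, function(p) {
    q <- quantile(p, c(bgQuantile, fgQuantile), names = FALSE)
    (q[1] + q[2]) / 2
  })
  thresholdSpec(channel, tf, thr)
}

#' Trace structure edges through a linescan stack
#'
#' Per frame, the threshold is the linear interpolation of the control
#' points (constant extrapolation beyond the first/last point); the edges
#' are the outermost crossings of the thresholded intensity profile, with
#' sub-sample localisation by linear interpolation between the two samples
#' bracketing the crossing. For the red channel this traces the bright lumen
#' core; for the green channel the outer edges of the two flanking endfoot
#' bands. Frames with no crossing are flagged missing and never
#' interpolated.
#'
#' @param stack a [LinescanStack-class].
#' @param spec a [ThresholdSpec-class], e.g. from [autoThreshold()].
#' @return An [EdgeTrace-class]; edge positions are in um from the left end
#'   of the field of view.
#' @export
traceEdges <- function(stack, spec) {
  validObject(spec)
  m <- slot(stack, spec@channel)
  nf <- ncol(m)
  tf <- seq(0, by = 1 / stack@fs, length.out = nf)
  thr <- if (length(spec@t) == 1) rep(spec@threshold, nf)
         else approx(spec@t, spec@threshold, tf, rule = 2)$y
  x <- (seq_len(nrow(m)) - 0.5) * stack@dx
  left <- right <- rep(NA_real_, nf)
  miss <- rep(TRUE, nf)
  for (k in seq_len(nf)) {
    p <- m[, k]
    above <- p >= thr[k]
    if (!any(above)) next
    i1 <- which(above)[1]
    i2 <- tail(which(above), 1)
    # sub-sample localisation of the outermost crossings
    if (i1 == 1) left[k] <- x[1]
    else left[k] <- x[i1 - 1] + (thr[k] - p[i1 - 1]) / (p[i1] - p[i1 - 1]) *
        stack@dx
    if (i2 == length(p)) right[k] <- x[length(p)]
    else right[k] <- x[i2] + (p[i2] - thr[k]) / (p[i2] - p[i2 + 1]) *
        stack@dx
    miss[k] <- FALSE
  }
  new("EdgeTrace", t = tf, left = left, right = right, missing = miss)
}

#' PVS width from lumen and endfoot edge traces
#'
#' Total PVS width is the endfoot tube diameter minus the lumen diameter;
#' per-side widths are the corresponding edge differences. Negative values
#' are retained but flagged for quality control.
#'
#' @param lumen,endfoot [EdgeTrace-class] objects on the same time base.
#' @return data.frame with columns `t`, `total`, `left`, `right`,
#'   `missing`, `qc_flag` (TRUE where any width is negative).
#' @export
#' @examples
#' l <- new("EdgeTrace", t = 0, left = 10, right = 30, missing = FALSE)
#' e <- new("EdgeTrace", t = 0, left = 6, right = 34, missing = FALSE)
#' pvsWidth(l, e)$total  # 8
pvsWidth <- function(lumen, endfoot) {
  if (length(lumen@t) != length(endfoot@t) ||
      max(abs(lumen@t - endfoot@t)) > 1e-9)
    stop("lumen and endfoot traces must share the same time base",
         call. = FALSE)
  total <- edgeDiameter(endfoot) - edgeDiameter(lumen)
  leftW <- lumen@left - endfoot@left
  rightW <- endfoot@right - lumen@right
  miss <- lumen@missing | endfoot@missing
  leftW[miss] <- NA_real_
  rightW[miss] <- NA_real_
  qc <- !miss & (total < 0 | leftW < 0 | rightW < 0)
  data.frame(t = lumen@t, total = total, left = leftW, right = rightW,
             missing = miss, qc_flag = qc)
}
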