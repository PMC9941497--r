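# internal helpers

# Run `code` under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(code)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# exponential first-order smoothing toward a piecewise target, time constant
# tau (s); tau <= 0 returns the target unchanged
expRamp <- function(target, fs, tau) {
  if (tau <= 0) return(target)
  a <- 1 - exp(-1 / (fs * tau))
  as.numeric(stats::filter(a * target, 1 - a, method = "recursive",
                           init = target[1]))
}

#' Sleep-wake state labels
#'
#' The closed set of sleep-wake state labels used throughout the package:
#' quiet wakefulness (QW), whisking (WHISK), locomotion (LOCO), wake before
#' sleep (WBS), NREM sleep, intermediate state (IS), REM sleep, wake after
#' sleep (WAS) and microarousal (MA).
#'
#' @return Character vector of the nine state labels.
#' @export
#' @examples
#' sleepStates()
sleepStates <- function() {
  c("QW", "WHISK", "LOCO", "WBS", "NREM", "IS", "REM", "WAS", "MA")
}
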