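#' Generate a synthetic hypnogram
#'
#' Builds one or more sleep cycles in the canonical order
#' WBS -> NREM -> IS -> REM -> WAS, optionally preceded/followed by quiet
#' wakefulness, with microarousals (MA) inserted into NREM and IS spans as a
#' Poisson process. MA durations are uniform in [1, 10) s; WAS lasts 10 s and
#' WBS about 15 s, both configurable.
#'
#' @param durations named list of state durations (s):
#'   `wbs`, `nrem`, `is`, `rem`, `was`. Defaults 15, 120, 30, 60, 10.
#' @param nCycles number of sleep cycles.
#' @param maRate microarousal rate (events per second of NREM/IS); 0 disables
#'   MAs.
#' @param qwLead seconds of quiet wakefulness before the first cycle
#'   (default 0).
#' @param seed integer seed; identical seeds give identical hypnograms.
#' @return A [Hypnogram-class].
#' @export
#' @examples
#' makeHypnogram(nCycles = 1, maRate = 0, seed = 7)
makeHypnogram <- function(durations = list(), nCycles = 1, maRate = 0,
                          qwLead = 0, seed = NULL) {
  dur <- list(wbs = 15, nrem = 120, is = 30, rem = 60, was = 10)
  for (nm in names(durations)) {
    if (!nm %in% names(dur))
      stop("unknown duration field: ", nm, call. = FALSE)
    dur[[nm]] <- durations[[nm]]
  }
  for (nm in names(dur))
    if (dur[[nm]] <= 0)
      stop("duration '", nm, "' must be positive", call. = FALSE)
  stopIfNot(maRate >= 0, "maRate must be non-negative")
  stopIfNot(nCycles >= 1, "nCycles must be at least 1")

  withSeed(seed, {
    rows <- list()
    t <- 0
    add <- function(state, d) {
      rows[[length(rows) + 1]] <<- data.frame(state = state, t0 = t,
                                              t1 = t + d)
      t <<- t + d
    }
    if (qwLead > 0) add("QW", qwLead)
    order5 <- c("wbs", "nrem", "is", "rem", "was")
    labs <- c(wbs = "WBS", nrem = "NREM", is = "IS", rem = "REM", was = "WAS")
    for (cy in seq_len(nCycles)) {
      for (s in order5) {
        if (s %in% c("nrem", "is") && maRate > 0) {
          segs <- insertMicroarousals(t, dur[[s]], maRate)
          for (k in seq_len(nrow(segs)))
            add(if (segs$ma[k]) "MA" else labs[[s]], segs$d[k])
        } else {
          add(labs[[s]], dur[[s]])
        }
      }
    }
    hypnogram(do.call(rbind, rows))
  })
}

# Split a parent interval [t0, t0+d] by Poisson-placed microarousals.
# Candidate MAs keep a 1 s margin from the parent boundaries and from each
# other; overlapping candidates are dropped (first drawn wins).
insertMicroarousals <- function(t0, d, rate) {
  n <- rpois(1, rate * d)
  out <- data.frame(d = d, ma = FALSE)
  if (n == 0) return(out)
  start <- runif(n, 0, d)
  len <- runif(n, 1, 10)
  keep <- logical(n)
  placed <- matrix(numeric(0), ncol = 2)
  for (k in order(start)) {
    a <- start[k]; b <- start[k] + len[k]
    if (a < 1 || b > d - 1) next
    if (nrow(placed) && any(a < placed[, 2] + 1 & b > placed[, 1] - 1)) next
    placed <- rbind(placed, c(a, b))
    keep[k] <- TRUE
  }
  if (!any(keep)) return(out)
  placed <- placed[order(placed[, 1]), , drop = FALSE]
  segs <- list()
  cur <- 0
  for (k in seq_len(nrow(placed))) {
    segs[[length(segs) + 1]] <- c(placed[k, 1] - cur, 0)
    segs[[length(segs) + 1]] <- c(placed[k, 2] - placed[k, 1], 1)
    cur <- placed[k, 2]
  }
  segs[[length(segs) + 1]] <- c(d - cur, 0)
  m <- do.call(rbind, segs)
  data.frame(d = m[, 1], ma = m[, 2] == 1)
}
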