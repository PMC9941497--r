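#' Aggregate oscillation statistics into per-(state, band) band summaries
#'
#' The full signal chain for one vessel: the PVS cross-section area series
#' \eqn{A(t) = \pi/4 (d_{endfoot}^2 - d_{lumen}^2)} and the lumen diameter
#' are Savitzky-Golay smoothed and decomposed into the five frequency
#' bands; oscillation events are detected per band; events are grouped into
#' episodes (continuous single-state spans of the hypnogram); within each
#' episode the event P-T area amplitudes are averaged and divided by the
#' episode's median area (giving the relative amplitude) and the lumen P-P
#' periods are averaged; across episodes the median is taken per
#' (state, band). These are the \eqn{\langle A \rangle},
#' \eqn{\langle a_{P-T} \rangle} and \eqn{\langle p_{P-P} \rangle} of the
#' area law.
#'
#' Respiratory and cardiac amplitudes of endfoot-derived quantities are
#' computed like any other band but flagged unreliable (`reliable = FALSE`):
#' at the recording resolution they sit below the measurement limit.
#'
#' @param trace a QC-passed [VesselTrace-class].
#' @param h the matching [Hypnogram-class] (defaults to the trace's own
#'   state labels).
#' @param bands band table, default [bandDefs()] without the continuous
#'   band (a low-pass has no oscillation events).
#' @param minEpisode minimum episode duration (s) entering the statistics;
#'   default 10.
#' @return data.frame (one row per state x band present) with columns
#'   `vessel_id`, `state`, `band`, `a_rel`, `p_pp_s`, `A_med_um2`,
#'   `r_lumen_um`, `r_endfoot_um`, `n_episodes`, `reliable`. States or
#'   bands with no usable episode are absent, never zero-filled.
#' @export
#' @examples
#' h <- makeHypnogram(nCycles = 2, seed = 4)
#' tr <- makeVesselTrace(h, vesselParams(fs = 50), seed = 4)
#' bs <- summarizeEpisodes(tr, h)
#' head(bs)
summarizeEpisodes <- function(trace, h = NULL, bands = NULL,
                              minEpisode = 10) {
  if (is.null(bands)) {
    bands <- bandDefs()
    bands <- bands[bands$band != "continuous", ]
  }
  fs <- trace@fs
  if (is.null(h)) {
    r <- rle(trace@state)
    ends <- cumsum(r$lengths) / fs
    h <- hypnogram(data.frame(state = r$values,
                              t0 = c(0, head(ends, -1)) + trace@t[1],
                              t1 = ends + trace@t[1]))
  }
  area <- pi / 4 * (trace@endfoot^2 - trace@lumen^2)
  areaS <- smoothSavGol(area, fs)
  lumS <- smoothSavGol(trace@lumen, fs)
  areaB <- bandDecompose(areaS, fs, bands)
  lumB <- bandDecompose(lumS, fs, bands)

  iv <- intervals(h)
  rows <- list()
  for (bi in seq_len(nrow(bands))) {
    b <- bands$band[bi]
    evA <- detectOscillations(areaB[[b]], fs, trace@t)
    evL <- detectOscillations(lumB[[b]], fs, trace@t)
    # per-episode statistics
    ep <- data.frame(state = iv$state, aRel = NA_real_, pp = NA_real_,
                     Amed = NA_real_, rl = NA_real_, re = NA_real_)
    for (k in seq_len(nrow(iv))) {
      if (iv$t1[k] - iv$t0[k] < minEpisode) next
      inEp <- trace@t >= iv$t0[k] & trace@t < iv$t1[k]
      medA <- median(area[inEp])
      selA <- evA$t_trough >= iv$t0[k] & evA$t_peak < iv$t1[k]
      selL <- evL$t_peak >= iv$t0[k] & evL$t_peak < iv$t1[k] &
        is.finite(evL$pp_period)
      if (any(selA)) ep$aRel[k] <- mean(evA$pt_amplitude[selA]) / medA
      if (any(selL)) ep$pp[k] <- mean(evL$pp_period[selL])
      ep$Amed[k] <- medA
      ep$rl[k] <- median(trace@lumen[inEp]) / 2
      ep$re[k] <- median(trace@endfoot[inEp]) / 2
    }
    for (s in unique(ep$state)) {
      sel <- ep$state == s & is.finite(ep$aRel) & is.finite(ep$pp)
      if (!any(sel)) next
      rows[[length(rows) + 1]] <- data.frame(
        vessel_id = trace@vessel_id, state = s, band = b,
        a_rel = median(ep$aRel[sel]), p_pp_s = median(ep$pp[sel]),
        A_med_um2 = median(ep$Amed[sel]),
        r_lumen_um = median(ep$rl[sel]),
        r_endfoot_um = median(ep$re[sel]),
        n_episodes = sum(sel),
        reliable = !(b %in% c("respiratory", "cardiac")))
    }
  }
  if (!length(rows))
    return(data.frame(vessel_id = character(0), state = character(0),
                      band = character(0), a_rel = numeric(0),
                      p_pp_s = numeric(0), A_med_um2 = numeric(0),
                      r_lumen_um = numeric(0), r_endfoot_um = numeric(0),
                      n_episodes = integer(0), reliable = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a PVSModel from one band-summary row
#'
#' @param summary band-summary data.frame from [summarizeEpisodes()].
#' @param state,band the row to use.
#' @param alpha obstructed fraction of the baseline PVS area.
#' @param baselineState state defining the baseline area (default `"QW"`,
#'   falling back to `"WBS"`, then the chosen state).
#' @param L PVS length (um).
#' @param fluids [FluidConstants-class].
#' @return A [PVSModel-class] whose outer radius is the state's median
#'   endfoot radius (the endfoot tube is the fixed outer cylinder).
#' @export
modelFromSummary <- function(summary, state, band, alpha = 0,
                             baselineState = "QW", L = 600,
                             fluids = fluidConstants()) {
  row <- summary[summary$state == state & summary$band == band, ]
  if (nrow(row) != 1)
    stop("summary must contain exactly one row for state ", state,
         " and band ", band, call. = FALSE)
  base <- summary[summary$band == band &
                    summary$state %in% c(baselineState, "WBS", state), ]
  base <- base[order(match(base$state, c(baselineState, "WBS", state))), ]
  pvsModel(A_med = row$A_med_um2, a_rel = row$a_rel, period = row$p_pp_s,
           alpha = alpha, R_ast = row$r_endfoot_um, L = L,
           A_baseline = base$A_med_um2[1], fluids = fluids)
}
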