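#' Flow-stop detector configuration
#'
#' Parameters of the flow-stop rule and of the flowrate estimator. The rule
#' itself is fixed by the study definition: a flow-stop is an interval where
#' the drainage flowrate falls below `flow_threshold` (0.8 mL/s) for at
#' least `min_duration` (2 s). The remaining parameters are reproducibility
#' choices that replace the manual inspection step of the clinical workflow:
#' a short local-regression window tames scale noise before thresholding,
#' brief above-threshold blips shorter than `merge_gap` do not split an
#' episode, and the suction-pressure extremum of an episode is searched in a
#' window padded by `pressure_window_pad` on both sides.
#'
#' @param flow_threshold Flowrate threshold (mL/s), default 0.8.
#' @param min_duration Minimum episode duration (s), default 2.
#' @param smooth_halfwidth Half-width (s) of the local linear-regression
#'   window used to estimate flowrate, default 0.6 (about 3 samples at
#'   2.5 Hz).
#' @param merge_gap Above-threshold gaps shorter than this (s) are merged
#'   into the surrounding episode, default 0.4.
#' @param pressure_window_pad Padding (s) around an episode when locating
#'   its peak suction pressure, default 1.
#' @param pressure_support_cutoff Episodes whose peak suction is below this
#'   (cmH2O) are flagged `pressure_supported`, default -5.
#' @return A `detector_config` list.
#' @export
detector_config <- function(flow_threshold = 0.8, min_duration = 2.0,
                            smooth_halfwidth = 0.6, merge_gap = 0.4,
                            pressure_window_pad = 1.0,
                            pressure_support_cutoff = -5) {
  if (flow_threshold <= 0) cf_config_error("`flow_threshold` must be > 0")
  if (min_duration <= 0) cf_config_error("`min_duration` must be > 0")
  if (smooth_halfwidth < 0 || merge_gap < 0 || pressure_window_pad < 0)
    cf_config_error("window parameters must be non-negative")
  structure(list(flow_threshold = flow_threshold,
                 min_duration = min_duration,
                 smooth_halfwidth = smooth_halfwidth,
                 merge_gap = merge_gap,
                 pressure_window_pad = pressure_window_pad,
                 pressure_support_cutoff = pressure_support_cutoff),
            class = "detector_config")
}

#' Estimate drainage flowrate from the cumulative-volume trace
#'
#' The flowrate at each sample is the slope of an ordinary least-squares
#' line fitted to cumulative volume over the samples within
#' `smooth_halfwidth` seconds on either side, clipped below at zero
#' (cumulative drained volume cannot decrease). A local regression slope is
#' used instead of first differences because scale noise at ~0.4 s spacing
#' makes raw differences cross the 0.8 mL/s threshold spuriously.
#'
#' @param trace A [profile_trace()].
#' @param cfg A [detector_config()].
#' @return Numeric vector of flowrates (mL/s) on the trace's time grid.
#' @export
estimate_flowrate <- function(trace, cfg = detector_config()) {
  if (!inherits(trace, "profile_trace"))
    cf_data_error("`trace` must be a profile_trace")
  t <- trace$t; v <- trace$volume
  n <- length(t)
  h <- cfg$smooth_halfwidth
  if (t[n] - t[1] < 2 * h)
    cf_data_error("trace is shorter than the smoothing window")
  # window bounds per sample via binary search on the sorted time grid
  lo <- findInterval(t - h, t, left.open = TRUE) + 1L
  hi <- findInterval(t + h, t)
  # prefix sums give each window's OLS slope in O(1); center time at the
  # trace origin for conditioning
  tc <- t - t[1]
  c1 <- cumsum(rep(1, n)); ct <- cumsum(tc); ct2 <- cumsum(tc^2)
  cv <- cumsum(v); ctv <- cumsum(tc * v)
  at <- function(cs, i) ifelse(i >= 1, cs[pmax(i, 1L)], 0)
  nw  <- at(c1, hi) - at(c1, lo - 1L)
  st  <- at(ct, hi) - at(ct, lo - 1L)
  st2 <- at(ct2, hi) - at(ct2, lo - 1L)
  sv  <- at(cv, hi) - at(cv, lo - 1L)
  stv <- at(ctv, hi) - at(ctv, lo - 1L)
  denom <- nw * st2 - st^2
  slope <- ifelse(denom > 1e-12, (nw * stv - st * sv) / denom, 0)
  pmax(slope, 0)
}

new_episode <- function(t_start, t_end, v_at_onset, min_flowrate,
                        peak_suction, terminal, pressure_supported) {
  list(t_start = t_start, t_end = t_end, v_at_onset = v_at_onset,
       min_flowrate = min_flowrate, peak_suction = peak_suction,
       terminal = terminal, pressure_supported = pressure_supported)
}

#' Detect flow-stop episodes in a catheterisation trace
#'
#' Applies the study's flow-stop rule to the estimated flowrate: a flow-stop
#' episode is a maximal interval, at or after flow onset, where the flowrate
#' stays below `flow_threshold` for at least `min_duration`. Flow onset is
#' the first sample at or above the threshold, so the pre-drainage dead time
#' never counts as a leading flow-stop; if the flowrate never reaches the
#' threshold the whole trace is returned as a single terminal episode.
#' Sub-threshold runs separated by above-threshold gaps shorter than
#' `merge_gap` are merged before the duration rule is applied. Episode
#' boundaries are closed on the left and open on the right. The episode that
#' extends to the end of the recording is marked `terminal`: the last
#' flow-stop is the end of catheterisation and is discounted from the
#' flow-stop count.
#'
#' @inheritParams estimate_flowrate
#' @return List of episodes, disjoint and time-ordered, each with fields
#'   `t_start`, `t_end` (s), `v_at_onset` (cumulative mL at onset),
#'   `min_flowrate` (mL/s), `peak_suction` (most negative pressure within
#'   the pad-extended window, capped at 0 cmH2O), `terminal` and
#'   `pressure_supported` (peak suction below the support cutoff).
#' @export
detect_flow_stops <- function(trace, cfg = detector_config()) {
  q <- estimate_flowrate(trace, cfg)
  t <- trace$t; v <- trace$volume; p <- trace$pressure
  n <- length(t)

  peak_in <- function(a, b) {
    w <- p[t >= a - cfg$pressure_window_pad & t <= b + cfg$pressure_window_pad]
    min(0, w)
  }
  mk <- function(i, j) {
    t_end <- if (j < n) t[j + 1L] else t[n]
    ps <- peak_in(t[i], t_end)
    new_episode(t[i], t_end, v[i], min(q[i:j]), ps, terminal = (j == n),
                pressure_supported = ps < cfg$pressure_support_cutoff)
  }

  onset <- which(q >= cfg$flow_threshold)[1]
  if (is.na(onset)) {
    ep <- mk(1L, n)
    ep$terminal <- TRUE
    return(list(ep))
  }

  below <- q < cfg$flow_threshold
  below[seq_len(onset - 1L)] <- FALSE
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0L) return(list())

  # merge runs separated by short above-threshold gaps
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      prev <- merged[[length(merged)]]
      gap_start <- t[prev[2] + 1L]
      gap_end <- t[runs[k, 1]]
      if (gap_end - gap_start < cfg$merge_gap) {
        merged[[length(merged)]] <- c(prev[1], runs[k, 2])
      } else {
        merged[[length(merged) + 1L]] <- runs[k, ]
      }
    }
  }

  eps <- list()
  for (run in merged) {
    i <- run[1]; j <- run[2]
    t_end <- if (j < n) t[j + 1L] else t[n]
    if (t_end - t[i] >= cfg$min_duration)
      eps[[length(eps) + 1L]] <- mk(i, j)
  }
  eps
}

#' Count non-terminal flow-stop episodes
#'
#' The last flow-stop is treated as the end of catheterisation, so a
#' catheterisation with a single (terminal) episode counts as zero
#' flow-stops.
#'
#' @param episodes Episode list from [detect_flow_stops()].
#' @return Integer count of non-terminal episodes.
#' @export
count_flow_stops <- function(episodes) {
  if (length(episodes) == 0L) return(0L)
  sum(!vapply(episodes, `[[`, logical(1), "terminal"))
}

#' Derive per-catheterisation endpoints
#'
#' Combines the detected episodes with the trace and (optionally) the
#' visit's clinical record into the per-catheterisation outcome set:
#' * `v_total` — total volume catheterised (mL);
#' * `v_first_stop` — cumulative volume at onset of the *first* episode,
#'   terminal or not (when the terminal episode is the only one, it is the
#'   first flow-stop, which is why catheterisations with zero counted
#'   flow-stops still have a positive residual);
#' * `rv1 = v_total - v_first_stop` — residual urine at the first flow-stop;
#' * `n_flow_stops` — non-terminal episode count;
#' * `peak_suction_first` — most negative pressure around the first episode;
#' * `haematuria_positive` and `postvoid_residual` from the clinical record
#'   (`NA` when no record is supplied).
#'
#' @param trace A [profile_trace()].
#' @param episodes Episodes from [detect_flow_stops()]; must contain at
#'   least one episode.
#' @param record Optional [clinical_record()] for the same visit.
#' @return A one-row `data.frame` of class `cath_endpoints`.
#' @export
derive_endpoints <- function(trace, episodes, record = NULL) {
  if (length(episodes) == 0L)
    cf_data_error("no episodes: a valid catheterisation ends in a terminal flow-stop")
  first <- episodes[[1L]]
  v_total <- max(trace$volume)
  v_first <- first$v_at_onset
  out <- data.frame(
    subject_id = trace$subject_id,
    device = trace$device,
    visit = trace$visit,
    v_total = v_total,
    v_first_stop = v_first,
    rv1 = v_total - v_first,
    n_flow_stops = count_flow_stops(episodes),
    peak_suction_first = first$peak_suction,
    haematuria_positive = if (is.null(record)) NA else
      classify_dipstick(record$dipstick),
    postvoid_residual = if (is.null(record)) NA_real_ else
      record$postvoid$mean_volume,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cath_endpoints", "data.frame")
  out
}
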