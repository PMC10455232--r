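# Independent oracles and fixture builders used across the suite.

# Naive per-sample flow-stop scan: enumerate every maximal sub-threshold run
# at/after flow onset with explicit loops, merge short gaps pairwise, then
# apply the duration rule. Deliberately written without reusing the package's
# run/merge machinery.
oracle_episodes <- function(trace, cfg = detector_config()) {
  q <- estimate_flowrate(trace, cfg)
  t <- trace$t
  n <- length(t)
  onset <- NA_integer_
  for (i in seq_len(n)) {
    if (q[i] >= cfg$flow_threshold) { onset <- i; break }
  }
  if (is.na(onset)) {
    return(data.frame(start = 1L, end = n, t_start = t[1], t_end = t[n],
                      terminal = TRUE))
  }
  runs <- list(); cur <- NULL
  for (i in onset:n) {
    if (q[i] < cfg$flow_threshold) {
      if (is.null(cur)) cur <- c(i, i) else cur[2] <- i
    } else if (!is.null(cur)) {
      runs[[length(runs) + 1L]] <- cur; cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  i <- 1L
  while (i < length(runs)) {
    gap_start <- t[runs[[i]][2] + 1L]
    gap_end <- t[runs[[i + 1L]][1]]
    if (gap_end - gap_start < cfg$merge_gap) {
      runs[[i]] <- c(runs[[i]][1], runs[[i + 1L]][2])
      runs[[i + 1L]] <- NULL
    } else {
      i <- i + 1L
    }
  }
  out <- NULL
  for (r in runs) {
    t_end <- if (r[2] < n) t[r[2] + 1L] else t[n]
    if (t_end - t[r[1]] >= cfg$min_duration) {
      out <- rbind(out, data.frame(start = r[1], end = r[2],
                                   t_start = t[r[1]], t_end = t_end,
                                   terminal = r[2] == n))
    }
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               t_start = numeric(0), t_end = numeric(0),
                               terminal = logical(0))
  else out
}

episodes_df <- function(eps) {
  do.call(rbind, lapply(eps, function(e)
    data.frame(t_start = e$t_start, t_end = e$t_end, terminal = e$terminal)))
}

# Exact signed-rank p-value by enumerating all 2^n sign assignments.
enumerate_signrank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- drop(signs %*% r)
  switch(alternative,
         greater = mean(Vs >= V),
         less = mean(Vs <= V),
         two.sided = min(1, 2 * min(mean(Vs >= V), mean(Vs <= V))))
}

# Simple hand-built trace: piecewise-constant flowrate segments
# (rate mL/s, duration s) integrated onto a 0.4 s grid, flat pressure.
segment_trace <- function(segments, dt = 0.4, device = "CEC",
                          pressure = NULL) {
  total <- sum(vapply(segments, `[[`, numeric(1), 2))
  t <- seq(0, total, by = dt)
  rate <- function(x) {
    acc <- 0
    for (s in segments) {
      if (x < acc + s[2]) return(s[1])
      acc <- acc + s[2]
    }
    0
  }
  q <- vapply(t, rate, numeric(1))
  v <- cumsum(c(0, q[-length(q)] * dt))
  p <- if (is.null(pressure)) rep(0, length(t)) else pressure
  profile_trace("fix", device, 1, t, v, p)
}

# A random-walk style trace for property tests: random flow segments that
# always end with a cessation long enough to be terminal.
random_segment_trace <- function() {
  n_seg <- sample(2:6, 1)
  segs <- lapply(seq_len(n_seg), function(i)
    c(runif(1, 0, 4), runif(1, 1, 12)))
  segs[[n_seg + 1]] <- c(0, runif(1, 3, 8))
  segment_trace(segs)
}
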