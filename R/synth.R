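#' Configuration of the synthetic catheterisation-profile generator
#'
#' A phenomenological model of one catheterisation, built so that every
#' quantity the detector must recover is known exactly (injected event times
#' and volumes are returned as ground truth). Drainage proceeds at a gently
#' tapering plateau flow; mucosal-suction events interrupt it (flowrate
#' drops to ~0, intra-catheter pressure spikes negative); the terminal
#' cessation is followed by a slow sub-threshold dribble and a short
#' zero-flow tail. Defaults are a synthetic calibration chosen to give
#' device-level endpoint distributions of the magnitude observed clinically
#' (counted stops near 0.17 per catheterisation for the micro-hole zone
#' catheter vs 1.09 for the eyelet catheter; right-skewed first-stop
#' residuals with means near 5 and 39 mL; suction amplitudes truncated at
#' the observed extremes of 87.7 and 423.2 cmH2O); they are generator
#' choices, not estimates from subject-level data.
#'
#' @param bladder_volume Range (mL) from which the pre-void bladder volume
#'   is drawn uniformly; the lower end respects the 150 mL eligibility rule.
#' @param plateau_flow Nominal free-flow drainage rate (mL/s).
#' @param flow_decay Exponent of the taper of flow with remaining volume
#'   (0 = constant flow).
#' @param n_suction_events Named vector of Poisson means of the number of
#'   (non-terminal) suction events per device.
#' @param suction_duration Range (s) of event durations; the lower end must
#'   exceed the detector's 2 s minimum so injected events are detectable.
#' @param suction_amplitude Per-device log-normal parameters and truncation
#'   bound (cmH2O magnitudes) of the suction-pressure spike.
#' @param first_stop_volume Per-device log-normal parameters and bounds (mL)
#'   of the residual drainable volume at the first stop (the true RV1).
#' @param dribble_rate Sub-threshold dribble flowrate after the terminal
#'   cessation (mL/s).
#' @param mass_noise_sd Scale noise SD on cumulative mass (g).
#' @param pressure_noise_sd Sensor noise SD on pressure (cmH2O).
#' @param sampling_rate Sampling rate (Hz), default 2.5.
#' @return A `profile_sim_config` list.
#' @export
profile_sim_config <- function(
    bladder_volume = c(150, 500),
    plateau_flow = 2.5,
    flow_decay = 0.25,
    n_suction_events = c(MHZC = 0.17, CEC = 1.09),
    suction_duration = c(3, 6),
    suction_amplitude = list(
      MHZC = list(meanlog = log(15), sdlog = 0.5, max = 87.7),
      CEC  = list(meanlog = log(90), sdlog = 0.6, max = 423.2)),
    first_stop_volume = list(
      MHZC = list(meanlog = log(4),  sdlog = 0.7, min = 0.2, max = 60),
      CEC  = list(meanlog = log(18), sdlog = 1.0, min = 0.5, max = 250)),
    dribble_rate = 0.25,
    mass_noise_sd = 0.05,
    pressure_noise_sd = 0.5,
    sampling_rate = 2.5) {
  if (bladder_volume[1] < 150)
    cf_config_error("`bladder_volume` lower bound must respect the 150 mL eligibility rule")
  if (sampling_rate <= 0) cf_config_error("`sampling_rate` must be positive")
  if (suction_duration[1] < 2.5)
    cf_config_error("`suction_duration` events must comfortably exceed the 2 s rule")
  if (dribble_rate <= 0 || dribble_rate >= 0.8)
    cf_config_error("`dribble_rate` must lie in (0, 0.8) mL/s")
  structure(list(bladder_volume = bladder_volume,
                 plateau_flow = plateau_flow, flow_decay = flow_decay,
                 n_suction_events = n_suction_events,
                 suction_duration = suction_duration,
                 suction_amplitude = suction_amplitude,
                 first_stop_volume = first_stop_volume,
                 dribble_rate = dribble_rate,
                 mass_noise_sd = mass_noise_sd,
                 pressure_noise_sd = pressure_noise_sd,
                 sampling_rate = sampling_rate),
            class = "profile_sim_config")
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  x <- rlnorm(n, meanlog, sdlog)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  x
}

#' Simulate one catheterisation trace with known ground truth
#'
#' Generates a [profile_trace()] from the phenomenological model in
#' [profile_sim_config()]. The number of non-terminal suction events and the
#' drainable volume remaining at the first stop can be supplied explicitly
#' (the trial generator uses this to condition traces on its endpoint-level
#' draws); otherwise they are drawn from the per-device defaults. Events are
#' kept clear of the trace start/end and of each other so ground truth is
#' unambiguous for detector tests.
#'
#' @param cfg A [profile_sim_config()].
#' @param device `"MHZC"` or `"CEC"`.
#' @param n_events Number of non-terminal suction events; `NULL` draws
#'   Poisson with the device's mean.
#' @param first_stop_volume Drainable volume (mL) remaining at the first
#'   stop — the true residual at first flow-stop; `NULL` draws from the
#'   device's log-normal.
#' @param subject_id,visit Metadata for the trace.
#' @return List with `trace` (a [profile_trace()]) and `truth`: `n_events`,
#'   `event_onset_times` (s), `event_volumes` (drainable mL remaining at
#'   each onset), `rv1` (true residual at first flow-stop), `v_total`
#'   (drainable volume), `amplitudes` (cmH2O) and `terminal_onset_time`.
#' @export
simulate_profile <- function(cfg = profile_sim_config(), device = "MHZC",
                             n_events = NULL, first_stop_volume = NULL,
                             subject_id = "sim", visit = 1) {
  check_device(device)
  dt <- 1 / cfg$sampling_rate
  if (is.null(n_events))
    n_events <- rpois(1, cfg$n_suction_events[[device]])
  fs <- cfg$first_stop_volume[[device]]
  if (is.null(first_stop_volume))
    first_stop_volume <- rlnorm_trunc(1, fs$meanlog, fs$sdlog, fs$min, fs$max)

  # drainable volume; the bladder is drawn large enough that the first stop
  # happens well after flow onset
  D <- runif(1, cfg$bladder_volume[1], cfg$bladder_volume[2])
  D <- max(D, first_stop_volume + 40)

  # onsets are parameterised by the drainable volume remaining; consecutive
  # onsets are kept >= `gap` mL apart so the above-threshold flow between
  # episodes survives smoothing and the merge rule
  gap <- max(4, 1.6 * cfg$plateau_flow)
  if (n_events > 0) {
    dribble <- rlnorm_trunc(1, log(1.5), 0.5, 0.3, 5)
    steps <- gap * runif(max(0, n_events - 1), 1, 2)
    ev <- first_stop_volume - c(0, cumsum(steps))
    deficit <- (dribble + gap) - ev[n_events]
    if (deficit > 0) ev <- ev + deficit
    rv1_true <- ev[1]
  } else {
    ev <- numeric(0)
    dribble <- first_stop_volume
    rv1_true <- dribble
  }

  amp_cfg <- cfg$suction_amplitude[[device]]
  amps <- if (n_events > 0)
    rlnorm_trunc(n_events, amp_cfg$meanlog, amp_cfg$sdlog, 0, amp_cfg$max)
  else numeric(0)
  durs <- if (n_events > 0)
    runif(n_events, cfg$suction_duration[1], cfg$suction_duration[2])
  else numeric(0)

  dead_time <- runif(1, 1, 3)
  tail_time <- 4

  # step the drainage forward sample by sample
  n_max <- ceiling((dead_time + D / 1.2 + dribble / cfg$dribble_rate +
                      sum(durs) + 3 * n_events + tail_time + 30) / dt) + 8L
  ts <- numeric(n_max); vs <- numeric(n_max); ps <- numeric(n_max)
  t <- 0; drained <- 0; k <- 1L
  ts[1] <- 0; vs[1] <- 0; ps[1] <- -0.5
  phase <- "dead"
  ev_idx <- 1L
  ev_left <- 0; ev_amp <- 0; ev_onset_t <- numeric(0)
  terminal_onset <- NA_real_; done_t <- NA_real_
  repeat {
    t <- t + dt
    q <- 0; p_mean <- -0.5
    if (phase == "dead") {
      if (t >= dead_time) phase <- "flow"
    } else if (phase == "event") {
      ev_left <- ev_left - dt
      p_mean <- -ev_amp
      if (ev_left <= 0) phase <- "flow"
    }
    if (phase == "flow") {
      remaining <- D - drained
      if (remaining <= dribble) {
        phase <- "dribble"
        terminal_onset <- t
      } else if (ev_idx <= n_events && remaining <= ev[ev_idx]) {
        phase <- "event"
        ev_left <- durs[ev_idx] - dt
        ev_amp <- amps[ev_idx]
        ev_onset_t <- c(ev_onset_t, t)
        ev_idx <- ev_idx + 1L
        p_mean <- -ev_amp
      } else {
        q <- max(1.2, cfg$plateau_flow * (remaining / D)^cfg$flow_decay)
        p_mean <- -1.5
      }
    }
    if (phase == "dribble") {
      if (drained < D) {
        q <- cfg$dribble_rate
      } else if (is.na(done_t)) {
        done_t <- t
      }
      p_mean <- -1.0
    }
    drained <- min(D, drained + q * dt)
    k <- k + 1L
    ts[k] <- t; vs[k] <- drained
    ps[k] <- p_mean + rnorm(1, 0, cfg$pressure_noise_sd)
    if (!is.na(done_t) && t - done_t >= tail_time) break
    if (k >= n_max) break  # safety net
  }
  ts <- ts[1:k]; vs <- vs[1:k]; ps <- ps[1:k]

  mass <- vs + rnorm(length(vs), 0, cfg$mass_noise_sd)
  mass[1] <- 0
  trace <- profile_trace(subject_id, device, visit, ts, mass, ps,
                         sampling_rate_nominal = cfg$sampling_rate)
  list(trace = trace,
       truth = list(n_events = n_events, event_onset_times = ev_onset_t,
                    event_volumes = ev, rv1 = rv1_true, v_total = D,
                    amplitudes = amps, dribble = dribble,
                    terminal_onset_time = terminal_onset))
}

#' Configuration of the synthetic crossover-trial generator
#'
#' Endpoint-level generative model for a two-period, two-device crossover
#' trial with block randomisation (block size 4). Each endpoint follows a
#' subject-random-intercept model on its natural link scale: identity for
#' the continuous endpoints, log for the flow-stop count (Poisson), logit
#' for haematuria (Bernoulli). Device effects are expressed against the
#' conventional catheter: a difference for continuous endpoints, a log rate
#' ratio for counts, a log odds ratio for haematuria. Defaults reproduce
#' the magnitude of the clinically observed device contrasts (first-stop
#' residual means near 39 vs 5 mL, count rate ratio 0.16, haematuria odds
#' ratio 0.26); the first-stop residual is generated on the log scale by
#' default because the endpoint is non-negative and strongly right-skewed.
#'
#' @param n_subjects Number of randomised subjects (default 42).
#' @param block_size Randomisation block size (default 4).
#' @param dropout_rate Probability a subject misses visit 2 (default 1/42,
#'   one expected dropout).
#' @param rv1_dist `"lognormal"` (default) or `"gaussian"` generation for
#'   the first-stop residual.
#' @param rv1_mean_cec Mean first-stop residual under the eyelet catheter
#'   (mL).
#' @param rv1_effect Device effect on the first-stop residual: CEC minus
#'   MHZC mean difference (mL); under `"lognormal"` the means are matched by
#'   a multiplicative shift `log(1 - rv1_effect / rv1_mean_cec)`.
#' @param rv1_sigma_subject,rv1_sigma_resid Between-subject and residual
#'   SDs; on the log scale when `rv1_dist = "lognormal"` (unitless), in mL
#'   otherwise.
#' @param count_mean_cec Mean flow-stop count under the eyelet catheter.
#' @param count_log_ratio Log rate ratio, MHZC vs CEC (default `log(0.16)`).
#' @param count_sigma_subject SD of the subject intercept on the log scale.
#' @param haem_p_cec Haematuria probability under the eyelet catheter.
#' @param haem_log_or Log odds ratio, MHZC vs CEC (default `log(0.26)`).
#' @param haem_sigma_subject SD of the subject intercept on the logit scale.
#' @param pressure_mean_cec,pressure_effect,pressure_sigma_subject,pressure_sigma_resid
#'   Peak-suction endpoint (cmH2O): CEC mean, CEC minus MHZC difference, SDs.
#' @param pvr_mean_cec,pvr_effect,pvr_sigma_subject,pvr_sigma_resid
#'   Post-void residual endpoint (mL): CEC mean, CEC minus MHZC difference,
#'   SDs.
#' @param visit_effect Additive visit-2 effect applied on each endpoint's
#'   link scale (default 0).
#' @param neurogenic_prop Proportion of subjects with a neurogenic history.
#' @return A `trial_sim_config` list.
#' @export
trial_sim_config <- function(
    n_subjects = 42, block_size = 4, dropout_rate = 1 / 42,
    rv1_dist = c("lognormal", "gaussian"),
    rv1_mean_cec = 39.4, rv1_effect = 34.3,
    rv1_sigma_subject = NULL, rv1_sigma_resid = NULL,
    count_mean_cec = 1.09, count_log_ratio = log(0.16),
    count_sigma_subject = 0.6,
    haem_p_cec = 0.29, haem_log_or = log(0.26), haem_sigma_subject = 1.0,
    pressure_mean_cec = -113, pressure_effect = -97.6,
    pressure_sigma_subject = 60, pressure_sigma_resid = 80,
    pvr_mean_cec = 7.13, pvr_effect = 1.21,
    pvr_sigma_subject = 10, pvr_sigma_resid = 20,
    visit_effect = 0, neurogenic_prop = 13 / 42) {
  rv1_dist <- match.arg(rv1_dist)
  if (is.null(rv1_sigma_subject))
    rv1_sigma_subject <- if (rv1_dist == "lognormal") 0.5 else 10
  if (is.null(rv1_sigma_resid))
    rv1_sigma_resid <- if (rv1_dist == "lognormal") 1.0 else 31
  if (n_subjects < 2) cf_config_error("`n_subjects` must be at least 2")
  if (block_size < 2 || block_size %% 2 != 0)
    cf_config_error("`block_size` must be a positive even number")
  if (dropout_rate < 0 || dropout_rate >= 1)
    cf_config_error("`dropout_rate` must lie in [0, 1)")
  if (any(c(rv1_sigma_subject, rv1_sigma_resid, count_sigma_subject,
            haem_sigma_subject, pressure_sigma_subject, pressure_sigma_resid,
            pvr_sigma_subject, pvr_sigma_resid) < 0))
    cf_config_error("all SDs must be non-negative")
  structure(as.list(environment()), class = "trial_sim_config")
}

assign_sequences <- function(n_subjects, block_size) {
  half <- block_size / 2
  seqs <- character(0)
  while (length(seqs) < n_subjects) {
    left <- n_subjects - length(seqs)
    if (left >= block_size) {
      block <- sample(rep(c("MHZC-CEC", "CEC-MHZC"), half))
    } else {
      # final partial block stays as balanced as the remainder allows
      block <- sample(rep(c("MHZC-CEC", "CEC-MHZC"), ceiling(left / 2)))[seq_len(left)]
    }
    seqs <- c(seqs, block)
  }
  seqs
}

#' Simulate a block-randomised crossover trial
#'
#' Draws one complete trial in long format: one row per subject-visit with
#' the device given by the subject's randomised sequence and all endpoint
#' values drawn from the random-intercept models in [trial_sim_config()].
#' With `with_traces = TRUE` each row additionally carries a synthetic
#' catheterisation trace conditioned on that row's drawn flow-stop count and
#' first-stop residual, so the signal-processing and the statistical layers
#' can be validated against each other.
#'
#' @param cfg A [trial_sim_config()].
#' @param seed Optional integer seed; identical seeds give identical
#'   datasets.
#' @param with_traces Also generate a [simulate_profile()] trace per row
#'   (slower).
#' @param profile_cfg A [profile_sim_config()], used when
#'   `with_traces = TRUE`.
#' @return A `data.frame` with columns `subject`, `sequence`, `visit`,
#'   `device`, `medical_history`, `rv1`, `n_flow_stops`,
#'   `haematuria_positive`, `peak_suction_first`, `postvoid_residual`.
#'   When `with_traces = TRUE`, the matching lists of traces and ground
#'   truths are attached as attributes `traces` and `truths`.
#' @export
simulate_trial <- function(cfg = trial_sim_config(), seed = NULL,
                           with_traces = FALSE,
                           profile_cfg = profile_sim_config()) {
  if (!inherits(cfg, "trial_sim_config"))
    cf_config_error("`cfg` must be a trial_sim_config")
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_subjects
  seqs <- assign_sequences(n, cfg$block_size)
  history <- sample(c("neurogenic", "non-neurogenic"), n, replace = TRUE,
                    prob = c(cfg$neurogenic_prop, 1 - cfg$neurogenic_prop))
  b_rv1 <- rnorm(n, 0, cfg$rv1_sigma_subject)
  b_cnt <- rnorm(n, 0, cfg$count_sigma_subject)
  b_hae <- rnorm(n, 0, cfg$haem_sigma_subject)
  b_prs <- rnorm(n, 0, cfg$pressure_sigma_subject)
  b_pvr <- rnorm(n, 0, cfg$pvr_sigma_subject)
  dropout <- runif(n) < cfg$dropout_rate

  rows <- list()
  for (i in seq_len(n)) {
    devs <- strsplit(seqs[i], "-", fixed = TRUE)[[1]]
    for (visit in 1:2) {
      if (visit == 2 && dropout[i]) next
      dev <- devs[visit]
      is_m <- as.numeric(dev == "MHZC")
      ve <- cfg$visit_effect * (visit == 2)

      if (cfg$rv1_dist == "lognormal") {
        # intercept set so that the *marginal* CEC mean matches rv1_mean_cec
        s2 <- cfg$rv1_sigma_subject^2 + cfg$rv1_sigma_resid^2
        mu0 <- log(cfg$rv1_mean_cec) - s2 / 2
        ratio <- 1 - cfg$rv1_effect / cfg$rv1_mean_cec
        eta <- mu0 + log(ratio) * is_m + ve + b_rv1[i] +
          rnorm(1, 0, cfg$rv1_sigma_resid)
        rv1 <- exp(eta)
      } else {
        mu0 <- cfg$rv1_mean_cec
        rv1 <- mu0 - cfg$rv1_effect * is_m + ve + b_rv1[i] +
          rnorm(1, 0, cfg$rv1_sigma_resid)
      }

      lam0 <- log(cfg$count_mean_cec) - cfg$count_sigma_subject^2 / 2
      lam <- exp(lam0 + cfg$count_log_ratio * is_m + ve + b_cnt[i])
      cnt <- rpois(1, lam)

      eta_h <- qlogis(cfg$haem_p_cec) + cfg$haem_log_or * is_m + ve + b_hae[i]
      hae <- runif(1) < plogis(eta_h)

      prs <- cfg$pressure_mean_cec - cfg$pressure_effect * is_m + ve +
        b_prs[i] + rnorm(1, 0, cfg$pressure_sigma_resid)
      pvr <- cfg$pvr_mean_cec - cfg$pvr_effect * is_m + ve +
        b_pvr[i] + rnorm(1, 0, cfg$pvr_sigma_resid)

      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", i), sequence = seqs[i], visit = visit,
        device = dev, medical_history = history[i],
        rv1 = rv1, n_flow_stops = cnt, haematuria_positive = hae,
        peak_suction_first = min(prs, 0), postvoid_residual = max(pvr, 0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL

  if (with_traces) {
    traces <- vector("list", nrow(out))
    truths <- vector("list", nrow(out))
    for (k in seq_len(nrow(out))) {
      fs <- profile_cfg$first_stop_volume[[out$device[k]]]
      sim <- simulate_profile(
        profile_cfg, out$device[k], n_events = out$n_flow_stops[k],
        first_stop_volume = min(max(out$rv1[k], fs$min), fs$max),
        subject_id = out$subject[k], visit = out$visit[k])
      traces[[k]] <- sim$trace
      truths[[k]] <- sim$truth
    }
    attr(out, "traces") <- traces
    attr(out, "truths") <- truths
  }
  out
}
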