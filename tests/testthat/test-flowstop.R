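test_that("flowrate estimator recovers the slope of clean ramps", {
  t <- seq(0, 10, by = 0.4)
  tr <- profile_trace("s", "MHZC", 1, t, 2 * t, rep(0, length(t)))
  q <- estimate_flowrate(tr)
  interior <- 3:(length(t) - 2)
  expect_equal(q[interior], rep(2, length(interior)), tolerance = 1e-10)

  tr0 <- profile_trace("s", "MHZC", 1, t, rep(5, length(t)), rep(0, length(t)))
  expect_equal(estimate_flowrate(tr0), rep(0, length(t)))

  # noisy ramp: local-regression slope stays near the true rate
  set.seed(31)
  t <- seq(0, 60, by = 0.4)
  v <- 3 * t + rnorm(length(t), 0, 0.2)
  tr <- profile_trace("s", "MHZC", 1, t, cummax(v), rep(0, length(t)))
  q <- estimate_flowrate(tr)
  interior <- 5:(length(t) - 4)
  expect_lt(abs(mean(q[interior]) - 3), 0.05)

  short <- profile_trace("s", "MHZC", 1, c(0, 0.4), c(0, 1), c(0, 0))
  expect_error(estimate_flowrate(short), class = "cathflow_data_error")
})

test_that("steady flow followed by cessation yields one terminal episode", {
  tr <- segment_trace(list(c(1.0, 30), c(0, 6)))
  eps <- detect_flow_stops(tr)
  expect_length(eps, 1)
  expect_true(eps[[1]]$terminal)
  expect_equal(count_flow_stops(eps), 0)
})

test_that("sub-threshold dips shorter than the minimum duration are ignored", {
  # 1.9 s dip mid-stream: below the 2 s rule, so only the terminal episode
  tr <- segment_trace(list(c(2.5, 20), c(0, 1.9), c(2.5, 20), c(0, 6)))
  eps <- detect_flow_stops(tr)
  expect_equal(count_flow_stops(eps), 0)
  expect_length(eps, 1)
  expect_true(eps[[1]]$terminal)

  # a 5 s dip is an episode
  tr <- segment_trace(list(c(2.5, 20), c(0, 5), c(2.5, 20), c(0, 6)))
  eps <- detect_flow_stops(tr)
  expect_equal(count_flow_stops(eps), 1)
  expect_length(eps, 2)
})

test_that("injected stops are found at the injected onsets", {
  set.seed(77)
  sim <- simulate_profile(device = "CEC", n_events = 2,
                          first_stop_volume = 45)
  eps <- detect_flow_stops(sim$trace)
  expect_length(eps, 3)
  expect_equal(count_flow_stops(eps), 2)
  expect_true(eps[[3]]$terminal)
  onsets <- vapply(eps[1:2], `[[`, numeric(1), "t_start")
  dt <- 1 / sim$trace$sampling_rate_nominal
  expect_lt(max(abs(onsets - sim$truth$event_onset_times)), 2 * dt + 1e-9)
})

test_that("a trace whose flow never reaches threshold is one terminal episode", {
  t <- seq(0, 12, by = 0.4)
  tr <- profile_trace("s", "MHZC", 1, t, 0.3 * t, rep(0, length(t)))
  eps <- detect_flow_stops(tr)
  expect_length(eps, 1)
  expect_true(eps[[1]]$terminal)
  expect_equal(count_flow_stops(eps), 0)
  expect_equal(eps[[1]]$t_start, 0)
  expect_equal(eps[[1]]$t_end, t[length(t)])
})

test_that("episode boundaries respect the left-closed right-open convention", {
  tr <- segment_trace(list(c(2.5, 20), c(0, 5), c(2.5, 20), c(0, 6)))
  eps <- detect_flow_stops(tr)
  for (i in seq_len(length(eps) - 1)) {
    expect_lte(eps[[i]]$t_end, eps[[i + 1]]$t_start)
    expect_gte(eps[[i]]$t_end - eps[[i]]$t_start,
               detector_config()$min_duration)
  }
})

test_that("detector matches the naive per-sample oracle on random traces", {
  set.seed(88)
  for (i in 1:120) {
    tr <- random_segment_trace()
    got <- episodes_df(detect_flow_stops(tr))
    want <- oracle_episodes(tr)
    if (nrow(want) == 0) {
      expect_null(got)
    } else {
      expect_equal(got$t_start, want$t_start)
      expect_equal(got$t_end, want$t_end)
      expect_equal(got$terminal, want$terminal)
    }
  }
})

test_that("raising the flow threshold never shrinks the covered stop time", {
  set.seed(92)
  covered <- function(tr, thr) {
    eps <- detect_flow_stops(tr, detector_config(flow_threshold = thr))
    sum(vapply(eps, function(e) e$t_end - e$t_start, numeric(1)))
  }
  for (i in 1:20) {
    tr <- random_segment_trace()
    cov <- vapply(c(0.4, 0.8, 1.5, 2.5), function(th) covered(tr, th),
                  numeric(1))
    expect_true(all(diff(cov) >= -1e-9))
  }
})

test_that("endpoints satisfy the residual-volume identity", {
  tr <- segment_trace(list(c(2.5, 104), c(0, 4), c(2.5, 16), c(0, 6)))
  eps <- detect_flow_stops(tr)
  ep <- derive_endpoints(tr, eps)
  expect_equal(ep$rv1 + ep$v_first_stop, ep$v_total)
  expect_gte(ep$rv1, 0)
  # first stop at ~260 mL of a ~300 mL drainage: residual equals the rest
  expect_equal(ep$v_total - ep$v_first_stop, ep$rv1)
  expect_equal(ep$n_flow_stops, 1)

  set.seed(5)
  for (i in 1:10) {
    sim <- simulate_profile(device = sample(c("MHZC", "CEC"), 1))
    eps <- detect_flow_stops(sim$trace)
    ep <- derive_endpoints(sim$trace, eps)
    expect_equal(ep$rv1 + ep$v_first_stop, ep$v_total)
  }
})

test_that("a single-episode catheterisation has zero counted stops but positive rv1", {
  set.seed(41)
  sim <- simulate_profile(device = "MHZC", n_events = 0,
                          first_stop_volume = 12)
  eps <- detect_flow_stops(sim$trace)
  ep <- derive_endpoints(sim$trace, eps)
  expect_equal(ep$n_flow_stops, 0)
  # the terminal episode is the first flow-stop, so the dribble drained
  # after its onset is the residual at first stop
  dt <- 1 / sim$trace$sampling_rate_nominal
  tol <- 2.5 * dt + 4 * 0.15
  expect_lt(abs(ep$rv1 - 12), tol)
})

test_that("the first episode's suction peak is picked up within the padded window", {
  set.seed(19)
  sim <- simulate_profile(device = "CEC", n_events = 1,
                          first_stop_volume = 30)
  eps <- detect_flow_stops(sim$trace)
  ep <- derive_endpoints(sim$trace, eps)
  expect_lte(ep$peak_suction_first, 0)
  expect_lt(abs(-ep$peak_suction_first - sim$truth$amplitudes[1]), 3)
})

test_that("deriving endpoints without any episode is an error", {
  tr <- segment_trace(list(c(2.5, 20)))
  expect_error(derive_endpoints(tr, list()), class = "cathflow_data_error")
})
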