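# balanced AB/BA dataset built directly from a linear predictor
make_crossover <- function(n, effect_cec_minus_mhzc = 0, subj_sd = 0,
                           resid_sd = 0, mu = 5, visit_effect = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subj <- sprintf("S%02d", 1:n)
  b <- rnorm(n, 0, subj_sd)
  seqs <- rep(c("MHZC-CEC", "CEC-MHZC"), length.out = n)
  rows <- list()
  for (i in 1:n) {
    devs <- strsplit(seqs[i], "-")[[1]]
    for (v in 1:2) {
      y <- mu + effect_cec_minus_mhzc * (devs[v] == "CEC") +
        visit_effect * (v == 2) + b[i] + rnorm(1, 0, resid_sd)
      rows[[length(rows) + 1]] <- data.frame(
        subject = subj[i], sequence = seqs[i], visit = v, device = devs[v],
        y = y, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("the linear mixed model recovers a noiseless device effect exactly", {
  d <- make_crossover(12, effect_cec_minus_mhzc = 10, subj_sd = 3,
                      resid_sd = 1e-6, seed = 301)
  f <- suppressWarnings(fit_lmm(d, "y"))
  expect_equal(f$effect$estimate, 10, tolerance = 1e-4)
  expect_lt(f$p_value, 1e-12)
  expect_lte(f$effect$lwr, f$effect$estimate)
  expect_gte(f$effect$upr, f$effect$estimate)
  m <- f$device_means
  expect_equal(m$estimate[m$device == "CEC"] -
                 m$estimate[m$device == "MHZC"], 10, tolerance = 1e-4)
})

test_that("mixed models collapse onto fixed-effects fits when the subject variance is zero", {
  # no between-subject heterogeneity: the random intercept is estimated at
  # the boundary and the fits must agree with plain lm/glm
  d <- make_crossover(20, effect_cec_minus_mhzc = 4, subj_sd = 0,
                      resid_sd = 2, seed = 302)
  f <- fit_lmm(d, "y")
  expect_true(f$singular)
  ref <- lm(y ~ device + visit, data = transform(
    d, device = factor(device, c("CEC", "MHZC")), visit = factor(visit)))
  expect_equal(-f$effect$estimate, unname(coef(ref)["deviceMHZC"]),
               tolerance = 1e-4)

  set.seed(303)
  d$cnt <- rpois(nrow(d), exp(0.3 - 0.8 * (d$device == "MHZC")))
  fc <- fit_count_glmm(d, "cnt")
  refc <- glm(cnt ~ device + visit, data = transform(
    d, device = factor(device, c("CEC", "MHZC")), visit = factor(visit)),
    family = poisson)
  expect_equal(log(fc$effect$estimate), unname(coef(refc)["deviceMHZC"]),
               tolerance = 1e-4)

  set.seed(304)
  d$bin <- rbinom(nrow(d), 1, plogis(-0.2 - 0.7 * (d$device == "MHZC")))
  fb <- fit_binary_glmm(d, "bin")
  if (fb$singular) {
    refb <- glm(bin ~ device + visit, data = transform(
      d, device = factor(device, c("CEC", "MHZC")), visit = factor(visit)),
      family = binomial)
    expect_equal(log(fb$effect$estimate), unname(coef(refb)["deviceMHZC"]),
                 tolerance = 1e-4)
  }
})

test_that("relabelling the devices flips differences and reciprocates ratios", {
  tr <- simulate_trial(trial_sim_config(n_subjects = 24), seed = 305)
  swapped <- tr
  swapped$device <- ifelse(tr$device == "MHZC", "CEC", "MHZC")

  f1 <- fit_lmm(tr, "rv1")
  f2 <- fit_lmm(swapped, "rv1")
  expect_equal(f1$effect$estimate, -f2$effect$estimate, tolerance = 1e-6)

  c1 <- fit_count_glmm(tr, "n_flow_stops")
  c2 <- fit_count_glmm(swapped, "n_flow_stops")
  expect_equal(c1$effect$estimate, 1 / c2$effect$estimate, tolerance = 1e-4)
})

test_that("symmetric data give null effects", {
  # same counts under both devices for every subject -> rate ratio 1
  d <- data.frame(
    subject = rep(sprintf("S%02d", 1:10), each = 2),
    visit = rep(1:2, 10),
    device = unlist(lapply(1:10, function(i)
      if (i %% 2) c("MHZC", "CEC") else c("CEC", "MHZC"))),
    cnt = rep(c(0, 1, 2, 1, 3), each = 4)[1:20],
    stringsAsFactors = FALSE)
  d$cnt <- ave(d$cnt, d$subject)  # identical within subject
  f <- fit_count_glmm(d, "cnt")
  expect_equal(f$effect$estimate, 1, tolerance = 1e-4)

  d$bin <- as.numeric(d$subject %in% sprintf("S%02d", 1:5))
  fb <- fit_binary_glmm(d, "bin")
  expect_equal(fb$effect$estimate, 1, tolerance = 1e-4)
})

test_that("an unadjusted two-proportion check brackets the adjusted odds ratio", {
  # marginal positive rates of 0.10 vs 0.29 give a crude OR near 0.27,
  # the same order as an adjusted within-subject estimate
  crude <- (0.10 / 0.90) / (0.29 / 0.71)
  expect_equal(crude, 0.272, tolerance = 0.005)
  expect_lt(abs(crude - 0.26), 0.05)
})

test_that("gatekeeping tests endpoints in order and stops at the first failure", {
  fake_fit <- function(endpoint, p) {
    structure(list(endpoint = endpoint, p_value = p), class = "cathflow_fit")
  }
  g <- gatekeep(list(fake_fit("rv1", 0.001), fake_fit("stops", 0.001)))
  expect_equal(g$decision, c("rejected", "rejected"))
  expect_true(attr(g, "pass"))

  g <- gatekeep(list(fake_fit("rv1", 0.2), fake_fit("stops", 0.001)))
  expect_equal(g$decision, c("retained", "not tested"))
  expect_false(attr(g, "pass"))

  g <- gatekeep(list(fake_fit("a", 0.01), fake_fit("b", 0.2),
                     fake_fit("c", 0.01)))
  expect_equal(g$decision, c("rejected", "retained", "not tested"))

  expect_error(gatekeep(list()), class = "cathflow_data_error")
})

test_that("signed-rank p-values match full enumeration of sign assignments", {
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), alternative = "greater")
  expect_equal(w$method, "exact")
  expect_equal(w$p_value, 1 / 32)
  expect_equal(w$p_value, enumerate_signrank_p(c(1, 2, 3, 4, 5), "greater"))

  set.seed(401)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (any(duplicated(abs(d)))) next
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_signed_rank(d, alt)$p_value,
                   enumerate_signrank_p(d, alt), tolerance = 1e-12)
    }
  }
})

test_that("signed-rank handles symmetry, zeros and ties", {
  expect_equal(wilcoxon_signed_rank(c(-2, 2))$p_value, 1)

  w <- wilcoxon_signed_rank(c(0, 0, 1, -2, 3))
  expect_equal(w$n_zero_dropped, 2L)
  expect_equal(w$n_used, 3L)

  w <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_equal(w$p_value, 1)
  expect_equal(w$note, "all differences zero")

  # ties force the corrected normal approximation
  w <- wilcoxon_signed_rank(c(1, 1, -1, 2, 3, 3, 4))
  expect_equal(w$method, "normal approximation")
  ref <- suppressWarnings(stats::wilcox.test(c(1, 1, -1, 2, 3, 3, 4),
                                             correct = TRUE))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("the normal approximation tracks exact enumeration at moderate n", {
  set.seed(402)
  d <- round(rnorm(15, 0.4, 1), 3)
  d <- d[d != 0 & !duplicated(abs(d))]
  exact <- wilcoxon_signed_rank(d)$p_value
  approx <- wilcoxon_signed_rank(d, exact_max_n = 0)$p_value
  expect_lt(abs(exact - approx), 0.02)
  expect_equal(exact, enumerate_signrank_p(d), tolerance = 1e-12)
})

test_that("the summary table carries device means, effects and reduction lines", {
  tr <- simulate_trial(trial_sim_config(n_subjects = 30), seed = 403)
  fits <- list(fit_lmm(tr, "rv1"), fit_count_glmm(tr, "n_flow_stops"),
               fit_binary_glmm(tr, "haematuria_positive"))
  gk <- gatekeep(fits[1:2])
  tab <- summarize_trial(fits, gk)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("mhzc_mean", "cec_mean", "effect", "p_value") %in%
                    names(tab)))
  notes <- attr(tab, "notes")
  expect_length(notes, 2)  # one line per ratio-type effect
  rr <- fits[[2]]$effect$estimate
  expect_match(notes[1], sprintf("%.0f%%", 100 * (1 - rr)))

  # the reported reduction lines for ratios of 0.16 and 0.26
  expect_equal(percent_reduction(0.16), 84)
  expect_equal(percent_reduction(0.26), 74)
})

test_that("fit preconditions are enforced", {
  tr <- simulate_trial(trial_sim_config(n_subjects = 10), seed = 404)
  tr$rv1 <- NA_real_
  expect_error(fit_lmm(tr, "rv1"), class = "cathflow_data_error")
  expect_error(fit_lmm(tr, "nope"), class = "cathflow_data_error")
  one <- simulate_trial(trial_sim_config(n_subjects = 10), seed = 405)
  one <- one[one$visit == 1, ]  # nobody seen under both devices
  expect_error(fit_lmm(one, "rv1"), class = "cathflow_data_error")
})
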