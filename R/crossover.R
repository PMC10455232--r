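#' @importFrom lme4 lmer glmer fixef VarCorr glmerControl lmerControl isSingular
NULL

# common front end: validate the long-format crossover data and build the
# model frame with device (reference = CEC so the coefficient is the MHZC
# effect), visit and subject as factors
prepare_crossover <- function(data, endpoint, covariates = NULL) {
  need <- c("subject", "visit", "device", endpoint, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    cf_data_error(sprintf("data lacks column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  d <- data[!is.na(data[[endpoint]]), , drop = FALSE]
  if (nrow(d) == 0) cf_data_error(sprintf("endpoint '%s' is all missing", endpoint))
  d$subject <- factor(d$subject)
  d$device <- factor(d$device, levels = c("CEC", "MHZC"))
  d$visit <- factor(d$visit)
  if (any(is.na(d$device))) cf_data_error("unknown device label")
  both <- tapply(d$device, d$subject, function(x) length(unique(x)))
  if (sum(both == 2, na.rm = TRUE) < 2)
    cf_data_error("need at least 2 subjects observed under both devices")
  d
}

fixed_formula <- function(endpoint, covariates) {
  rhs <- paste(c("device", "visit", covariates), collapse = " + ")
  list(mixed = as.formula(paste(endpoint, "~", rhs, "+ (1 | subject)")),
       fixed = as.formula(paste(endpoint, "~", rhs)))
}

# device-level means as linear combinations of the fixed effects: the device
# column is forced to each level and every other model-matrix column is
# averaged over the observed rows (visit balanced by design)
device_mean_rows <- function(model, linkinv, crit, se_scale = 1) {
  X <- lme4::getME(model, "X")
  beta <- fixef(model)
  V <- as.matrix(vcov(model))
  dev_col <- grep("^deviceMHZC$", colnames(X))
  L <- colMeans(X)
  out <- lapply(c(CEC = 0, MHZC = 1), function(ind) {
    l <- L; l[dev_col] <- ind
    est <- sum(l * beta)
    se <- sqrt(drop(t(l) %*% V %*% l)) * se_scale
    c(estimate = linkinv(est), lwr = linkinv(est - crit * se),
      upr = linkinv(est + crit * se))
  })
  df <- do.call(rbind, out)
  data.frame(device = rownames(df), df, row.names = NULL)
}

new_model_fit <- function(endpoint, family, device_means, effect_type,
                          effect, lwr, upr, p_value, model, notes = character(0),
                          converged = TRUE, singular = FALSE) {
  structure(list(endpoint = endpoint, family = family,
                 device_means = device_means,
                 effect = list(type = effect_type, estimate = effect,
                               lwr = lwr, upr = upr),
                 p_value = p_value, model = model, notes = notes,
                 converged = converged, singular = singular),
            class = "cathflow_fit")
}

#' @export
print.cathflow_fit <- function(x, ...) {
  cat(sprintf("<cathflow_fit> %s (%s)\n", x$endpoint, x$family))
  print(x$device_means, digits = 4)
  cat(sprintf("  %s: %.4g [%.4g, %.4g], p = %.4g\n", x$effect$type,
              x$effect$estimate, x$effect$lwr, x$effect$upr, x$p_value))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Linear mixed model for a continuous crossover endpoint
#'
#' Fits `y ~ device + visit + (1 | subject)` by REML: subjects enter as a
#' random intercept, device and visit as fixed effects. The device contrast
#' is reported as the CEC-minus-MHZC mean difference (positive when the
#' micro-hole catheter leaves less residual), with a t interval. The default
#' degrees of freedom are the within-subject residual df
#' (`n_obs - n_fixed - (n_subjects - 1)`); Satterthwaite df are available
#' when the lmerTest package is installed. A fit with zero estimated
#' between-subject variance is legitimate (the model collapses onto the
#' fixed-effects model) and is flagged `singular` rather than treated as an
#' error.
#'
#' @param data Long-format crossover data with columns `subject`, `visit`,
#'   `device` and the endpoint.
#' @param endpoint Name of the continuous endpoint column.
#' @param covariates Optional extra fixed-effect column names (e.g.
#'   `"medical_history"`).
#' @param df_method `"residual"` (default) or `"satterthwaite"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A `cathflow_fit` with device-level means, the mean difference
#'   with CI, and a two-sided p-value.
#' @export
fit_lmm <- function(data, endpoint, covariates = NULL,
                    df_method = c("residual", "satterthwaite"),
                    conf_level = 0.95) {
  df_method <- match.arg(df_method)
  d <- prepare_crossover(data, endpoint, covariates)
  ff <- fixed_formula(endpoint, covariates)
  notes <- character(0)

  if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      cf_config_error("df_method = 'satterthwaite' needs the lmerTest package")
    fit <- suppressMessages(lmerTest::lmer(ff$mixed, data = d, REML = TRUE))
    sm <- coef(summary(fit))
    df <- sm["deviceMHZC", "df"]
  } else {
    fit <- suppressMessages(lmer(ff$mixed, data = d, REML = TRUE))
    p_fix <- length(fixef(fit))
    df <- nrow(d) - p_fix - (nlevels(droplevels(d$subject)) - 1)
    df <- max(df, 1)
  }
  singular <- isSingular(fit, tol = 1e-4)
  if (singular)
    notes <- c(notes, "between-subject variance estimated at 0 (singular fit)")

  beta <- fixef(fit)[["deviceMHZC"]]
  se <- sqrt(as.matrix(vcov(fit))["deviceMHZC", "deviceMHZC"])
  crit <- qt(1 - (1 - conf_level) / 2, df)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  # report as CEC - MHZC so a beneficial MHZC effect is positive
  diff <- -beta
  means <- device_mean_rows(fit, identity, crit)
  new_model_fit(endpoint, "gaussian (identity)", means,
                "mean difference (CEC - MHZC)", diff,
                diff - crit * se, diff + crit * se, p, fit,
                notes = notes, singular = singular)
}

# profile-likelihood CI on the device coefficient, used when the Wald
# interval degenerates (e.g. a zero-count arm): the device term is replaced
# by a fixed offset and the deviance profiled over a grid
profile_device_ci <- function(d, endpoint, covariates, family, beta_hat,
                              conf_level, nAGQ) {
  rhs <- paste(c("visit", covariates), collapse = " + ")
  ind <- as.numeric(d$device == "MHZC")
  dev_at <- function(b) {
    d$.off <- b * ind
    f <- as.formula(paste(endpoint, "~", rhs, "+ offset(.off) + (1 | subject)"))
    m <- suppressMessages(suppressWarnings(
      glmer(f, data = d, family = family, nAGQ = nAGQ)))
    -2 * as.numeric(stats::logLik(m))
  }
  target <- stats::qchisq(conf_level, 1)
  b0 <- if (is.finite(beta_hat)) max(min(beta_hat, 20), -20) else 0
  d0 <- dev_at(b0)
  bound <- function(dir) {
    lo <- b0; hi <- b0 + dir
    while (dev_at(hi) - d0 < target && abs(hi - b0) < 30) hi <- hi + dir
    if (abs(hi - b0) >= 30) return(dir * Inf)
    for (i in 1:20) {
      mid <- (lo + hi) / 2
      if (dev_at(mid) - d0 < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  c(bound(-1), bound(1))
}

#' Poisson random-intercept model for the flow-stop count
#'
#' Fits a generalised linear mixed model with a log link,
#' `count ~ device + visit + (1 | subject)`, maximised by adaptive
#' Gauss-Hermite quadrature (15 nodes by default). The exponentiated device
#' coefficient is the rate ratio of flow-stops with the MHZC relative to the
#' CEC, reported with a Wald interval; `100 * (1 - ratio)` is the percent
#' reduction. A negative-binomial family is available for overdispersed
#' counts. When a device arm has no events at all the Wald interval
#' degenerates and a profile-likelihood interval is substituted with a
#' warning.
#'
#' @inheritParams fit_lmm
#' @param endpoint Name of the count endpoint column.
#' @param family `"poisson"` (default) or `"nbinom"`.
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature nodes.
#' @return A `cathflow_fit`; the effect is the MHZC:CEC rate ratio.
#' @export
fit_count_glmm <- function(data, endpoint, covariates = NULL,
                           family = c("poisson", "nbinom"), nAGQ = 15,
                           conf_level = 0.95) {
  family <- match.arg(family)
  d <- prepare_crossover(data, endpoint, covariates)
  if (any(d[[endpoint]] < 0) || any(d[[endpoint]] != round(d[[endpoint]])))
    cf_data_error("count endpoint must hold non-negative integers")
  ff <- fixed_formula(endpoint, covariates)

  if (family == "nbinom") {
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer.nb(ff$mixed, data = d)))
    fam_label <- "negative binomial (log)"
  } else {
    fit <- suppressMessages(suppressWarnings(
      glmer(ff$mixed, data = d, family = poisson, nAGQ = nAGQ)))
    fam_label <- "Poisson (log)"
  }
  singular <- isSingular(fit, tol = 1e-4)
  notes <- if (singular)
    "between-subject variance estimated at 0 (singular fit)" else character(0)

  beta <- fixef(fit)[["deviceMHZC"]]
  se <- sqrt(as.matrix(vcov(fit))["deviceMHZC", "deviceMHZC"])
  z <- qnorm(1 - (1 - conf_level) / 2)
  arm_totals <- tapply(d[[endpoint]], d$device, sum)
  degenerate <- any(arm_totals == 0) || !is.finite(se) || se > 20
  if (degenerate && family == "poisson") {
    warning("a device arm has no events; reporting a profile-likelihood interval")
    ci_log <- profile_device_ci(d, endpoint, covariates, poisson(), beta,
                                conf_level, nAGQ = 1)
    notes <- c(notes, "profile-likelihood CI (degenerate Wald interval)")
    lwr <- exp(ci_log[1]); upr <- exp(ci_log[2])
  } else {
    lwr <- exp(beta - z * se); upr <- exp(beta + z * se)
  }
  p <- 2 * pnorm(-abs(beta / se))
  means <- device_mean_rows(fit, exp, z)
  new_model_fit(endpoint, fam_label, means, "rate ratio (MHZC vs CEC)",
                exp(beta), lwr, upr, p, fit, notes = notes,
                singular = singular)
}

# Firth-penalised logistic regression (Jeffreys-prior score correction),
# used as the separation fallback for the binary endpoint
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XtW <- t(X * w)
    info <- XtW %*% X
    inv <- solve(info)
    h <- rowSums((X %*% inv) * (X * w))
    U <- drop(t(X) %*% (y - mu + h * (0.5 - mu)))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, vcov = inv)
}

#' Logistic random-intercept model for the haematuria assessment
#'
#' Fits `positive ~ device + visit + (1 | subject)` with a logit link by
#' adaptive Gauss-Hermite quadrature. The exponentiated device coefficient
#' is the odds ratio of a positive dipstick with the MHZC relative to the
#' CEC; the subject's bladder-dysfunction history can be added as a fixed
#' covariate. Quasi-complete separation (common with ~40 subjects and a
#' rare outcome) is detected from an exploding coefficient or standard
#' error, in which case a Firth-penalised logistic regression without the
#' random intercept is reported instead, with a warning.
#'
#' @inheritParams fit_lmm
#' @param endpoint Name of the logical/0-1 endpoint column.
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature nodes.
#' @return A `cathflow_fit`; the effect is the MHZC:CEC odds ratio.
#' @export
fit_binary_glmm <- function(data, endpoint, covariates = NULL, nAGQ = 15,
                            conf_level = 0.95) {
  d <- prepare_crossover(data, endpoint, covariates)
  d[[endpoint]] <- as.numeric(d[[endpoint]])
  if (!all(d[[endpoint]] %in% c(0, 1)))
    cf_data_error("binary endpoint must be logical or 0/1")
  ff <- fixed_formula(endpoint, covariates)
  fit <- suppressMessages(suppressWarnings(
    glmer(ff$mixed, data = d, family = binomial, nAGQ = nAGQ)))
  singular <- isSingular(fit, tol = 1e-4)
  notes <- if (singular)
    "between-subject variance estimated at 0 (singular fit)" else character(0)

  beta <- fixef(fit)[["deviceMHZC"]]
  se <- sqrt(as.matrix(vcov(fit))["deviceMHZC", "deviceMHZC"])
  z <- qnorm(1 - (1 - conf_level) / 2)

  if (!is.finite(se) || se > 20 || abs(beta) > 10) {
    warning("separation detected; reporting a Firth-penalised logistic fit")
    X <- stats::model.matrix(ff$fixed, d)
    fl <- firth_logistic(X, d[[endpoint]])
    beta <- fl$beta[colnames(X) == "deviceMHZC"]
    se <- sqrt(diag(fl$vcov))[colnames(X) == "deviceMHZC"]
    notes <- c(notes, "Firth-penalised fixed-effects fallback (separation)")
  }
  p <- 2 * pnorm(-abs(beta / se))
  means <- device_mean_rows(fit, plogis, z)
  new_model_fit(endpoint, "binomial (logit)", means,
                "odds ratio (MHZC vs CEC)", exp(beta),
                exp(beta - z * se), exp(beta + z * se), p, fit,
                notes = notes, singular = singular)
}

#' Fixed-sequence gatekeeping over ordered endpoints
#'
#' Tests the co-primary (and any further) endpoints in a pre-specified
#' order, each at the unadjusted level `alpha`; testing stops at the first
#' endpoint whose null hypothesis is not rejected, and all later endpoints
#' are reported as not tested. The overall pass flag requires every supplied
#' endpoint to reject. Because later hypotheses are only tested after
#' earlier rejections, the family-wise error rate is controlled at `alpha`
#' without any p-value adjustment.
#'
#' @param fits List of `cathflow_fit` objects in hierarchical order (for
#'   this study: residual at first flow-stop, then flow-stop count).
#' @param alpha Significance level, default 0.05.
#' @return A `gatekeeping_result`: data.frame of endpoint, p-value and
#'   decision (`rejected`, `retained`, `not tested`), plus an overall
#'   `pass` attribute.
#' @export
gatekeep <- function(fits, alpha = 0.05) {
  if (length(fits) == 0) cf_data_error("`fits` must contain at least one fit")
  p <- vapply(fits, function(f) f$p_value, numeric(1))
  nm <- vapply(fits, function(f) f$endpoint, character(1))
  decision <- character(length(fits))
  alive <- TRUE
  for (i in seq_along(fits)) {
    if (!alive) {
      decision[i] <- "not tested"
    } else if (p[i] < alpha) {
      decision[i] <- "rejected"
    } else {
      decision[i] <- "retained"
      alive <- FALSE
    }
  }
  out <- data.frame(endpoint = nm, p_value = p, decision = decision,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, pass = all(decision == "rejected"), alpha = alpha,
            class = c("gatekeeping_result", "data.frame"))
}

#' @export
print.gatekeeping_result <- function(x, ...) {
  cat(sprintf("Fixed-sequence gatekeeping at alpha = %.3g\n", attr(x, "alpha")))
  print.data.frame(x, digits = 4)
  cat(if (attr(x, "pass")) "Overall: PASS\n" else "Overall: not passed\n")
  invisible(x)
}

#' Wilcoxon signed-rank test on within-subject differences
#'
#' Robustness check of the normality assumption behind the linear mixed
#' model: the paired within-subject device differences are tested against a
#' symmetric-about-zero null. Zero differences are dropped, tied absolute
#' differences receive average ranks, the statistic is the positive-rank
#' sum. The exact null distribution is used for n <= `exact_max_n` untied
#' differences; otherwise a normal approximation with tie correction and
#' continuity correction.
#'
#' @param differences Numeric vector of per-subject differences
#'   (CEC minus MHZC, one per subject with both visits).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact_max_n Largest n for which the exact distribution is used.
#' @return List with `statistic` (V, positive-rank sum), `p_value`,
#'   `n_used`, `n_zero_dropped`, `method` and `note`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), alternative = "greater")$p_value
#' # exact: 1/32
#' @export
wilcoxon_signed_rank <- function(differences,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_max_n = 25) {
  alternative <- match.arg(alternative)
  d <- differences[!is.na(differences)]
  if (length(d) == 0) cf_data_error("need at least one non-missing difference")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                n_zero_dropped = n_zero, method = "degenerate",
                note = "all differences zero"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))

  if (n <= exact_max_n && !ties) {
    p <- switch(alternative,
      greater = 1 - psignrank(V - 1, n),
      less = psignrank(V, n),
      two.sided = min(1, 2 * min(1 - psignrank(V - 1, n), psignrank(V, n))))
    method <- "exact"
  } else {
    E <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - E
    cc <- switch(alternative, two.sided = sign(z) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z - cc) / sqrt(sigma2)
    p <- switch(alternative,
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z),
      two.sided = min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n_used = n, n_zero_dropped = n_zero,
       method = method, note = NULL)
}

#' Percent reduction implied by a ratio effect
#'
#' `100 * (1 - ratio)`: a rate ratio of 0.16 means the event is 84% less
#' likely with the MHZC.
#'
#' @param ratio A rate or odds ratio (MHZC vs CEC).
#' @return Percent reduction.
#' @export
percent_reduction <- function(ratio) 100 * (1 - ratio)

#' Assemble the trial summary table
#'
#' Collects the per-endpoint model fits into one results table shaped like
#' a clinical performance-outcomes table: device-level means with 95% CI,
#' the device contrast (difference or ratio) with CI and p-value, plus
#' human-readable percent-reduction lines for ratio-type effects and the
#' gatekeeping outcome when supplied.
#'
#' @param fits List of `cathflow_fit` objects.
#' @param gatekeeping Optional [gatekeep()] result.
#' @return A `trial_summary`: data.frame with one row per endpoint and
#'   attributes `notes` (character lines) and `gatekeeping`.
#' @export
summarize_trial <- function(fits, gatekeeping = NULL) {
  if (length(fits) == 0) cf_data_error("`fits` must contain at least one fit")
  rows <- lapply(fits, function(f) {
    m <- f$device_means
    data.frame(
      endpoint = f$endpoint,
      mhzc_mean = m$estimate[m$device == "MHZC"],
      mhzc_lwr = m$lwr[m$device == "MHZC"],
      mhzc_upr = m$upr[m$device == "MHZC"],
      cec_mean = m$estimate[m$device == "CEC"],
      cec_lwr = m$lwr[m$device == "CEC"],
      cec_upr = m$upr[m$device == "CEC"],
      effect_type = f$effect$type,
      effect = f$effect$estimate,
      effect_lwr = f$effect$lwr,
      effect_upr = f$effect$upr,
      p_value = f$p_value,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  notes <- character(0)
  for (f in fits) {
    if (grepl("ratio", f$effect$type)) {
      notes <- c(notes, sprintf(
        "%s: %.0f%% less likely with the MHZC (ratio %.2f)",
        f$endpoint, percent_reduction(f$effect$estimate),
        f$effect$estimate))
    }
  }
  structure(tab, notes = notes, gatekeeping = gatekeeping,
            class = c("trial_summary", "data.frame"))
}

#' @export
print.trial_summary <- function(x, ...) {
  print.data.frame(x, digits = 4)
  for (n in attr(x, "notes")) cat(n, "\n")
  if (!is.null(attr(x, "gatekeeping"))) print(attr(x, "gatekeeping"))
  invisible(x)
}
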