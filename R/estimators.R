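#' Configuration shared by the interval estimators
#'
#' @param level Two-sided confidence level in (0, 1).
#' @param bootstrap_reps Number of bootstrap resamples for the percentile
#'   interval (approach 3).
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @param continuity_correction If `TRUE`, samples with an empty cell are
#'   continuity-corrected (+0.5 on the four nested counts) instead of
#'   raising a degenerate-table or boundary error.
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(level = 0.95, bootstrap_reps = 1000L,
                             seed = NULL, continuity_correction = FALSE) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop_validation("`level` must lie in (0, 1)")
  }
  if (!is_count(bootstrap_reps) || bootstrap_reps < 2) {
    stop_validation("`bootstrap_reps` must be an integer >= 2")
  }
  structure(
    list(level = level, z = stats::qnorm((1 + level) / 2),
         bootstrap_reps = as.integer(bootstrap_reps), seed = seed,
         continuity_correction = isTRUE(continuity_correction)),
    class = "estimator_config"
  )
}

approach_labels <- c(
  "1" = "naive Wald",
  "2" = "sampling-fraction-corrected Wald",
  "3" = "stratified percentile bootstrap",
  "4" = "Se/Sp/prevalence delta method",
  "5" = "weighted logistic regression",
  "6" = "Se/Sp/prevalence delta method, logit scale"
)

new_interval_estimate <- function(target, estimate, lower, upper, se, scale,
                                  approach, level, truncated = FALSE,
                                  continuity_corrected = FALSE, ...) {
  structure(
    list(target = target, estimate = estimate,
         lower = max(0, min(lower, estimate)),
         upper = min(1, max(upper, estimate)),
         se = se, scale = scale, approach = approach, level = level,
         truncated = truncated, continuity_corrected = continuity_corrected,
         ...),
    class = "interval_estimate"
  )
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%s (approach %d, %s)\n", x$target, x$approach,
              approach_labels[[as.character(x$approach)]]))
  cat(sprintf("  estimate %.4f, %.0f%% CI [%.4f, %.4f]%s\n",
              x$estimate, 100 * x$level, x$lower, x$upper,
              if (isTRUE(x$truncated)) " (truncated)" else ""))
  if (!is.na(x$se)) cat(sprintf("  SE (%s scale) %.4f\n", x$scale, x$se))
  invisible(x)
}

#' @export
as.data.frame.interval_estimate <- function(x, ...) {
  data.frame(approach = x$approach, target = x$target, estimate = x$estimate,
             lower = x$lower, upper = x$upper, se = x$se, scale = x$scale,
             level = x$level, truncated = x$truncated,
             continuity_corrected = x$continuity_corrected,
             stringsAsFactors = FALSE)
}

# Apply the opt-in continuity correction when a nested cell is empty;
# otherwise pass the sample through for the approach to validate.
resolve_sample <- function(sample, cfg) {
  cells <- c(sample$a, sample$c, sample$b1, sample$d1)
  if (cfg$continuity_correction && any(cells == 0)) continuity_correct(sample)
  else sample
}

observed_proportion <- function(sample, target) {
  if (target == "PPV") {
    n <- sample$a + sample$b1
    if (n <= 0) stop_degenerate_table("no test-positive subjects observed")
    list(p = sample$a / n, n = n)
  } else {
    n <- sample$c + sample$d1
    if (n <= 0) stop_degenerate_table("no test-negative subjects observed")
    list(p = sample$d1 / n, n = n)
  }
}

wald_interval <- function(target, estimate, se, approach, cfg, sample) {
  lower <- estimate - cfg$z * se
  upper <- estimate + cfg$z * se
  truncated <- lower < 0 || upper > 1
  new_interval_estimate(
    target = target, estimate = estimate,
    lower = max(0, lower), upper = min(1, upper), se = se,
    scale = "natural", approach = approach, level = cfg$level,
    truncated = truncated,
    continuity_corrected = isTRUE(sample$continuity_corrected))
}

#' Approach 1: Wald interval with the naive SE of a proportion
#'
#' The SE uses the standard binomial formula with the uncorrected observed
#' proportion (`a/(a+b1)` for PPV) and the observed denominator, i.e. the
#' number of patients actually tested. The interval is centred on the
#' sampling-fraction-corrected point estimate, which all six approaches
#' share; only the SE ignores the weighting.
#'
#' @param sample A [nested_sample()].
#' @param target `"PPV"` or `"NPV"`.
#' @param cfg An [estimator_config()].
#' @return An `interval_estimate`.
#' @export
ci_naive_wald <- function(sample, target = c("PPV", "NPV"),
                          cfg = estimator_config()) {
  target <- match_target(target)
  sample <- resolve_sample(sample, cfg)
  est <- corrected_predictive_value(sample, target)
  obs <- observed_proportion(sample, target)
  se <- sqrt(obs$p * (1 - obs$p) / obs$n)
  wald_interval(target, est, se, 1L, cfg, sample)
}

#' Approach 2: Wald interval with the sampling-fraction-corrected SE
#'
#' As approach 1, but the proportion inside the binomial SE formula is the
#' corrected predictive value itself; the denominator stays at the observed
#' number of patients (correcting it too would pretend the unobserved
#' controls were measured).
#'
#' @inheritParams ci_naive_wald
#' @return An `interval_estimate`.
#' @export
ci_corrected_wald <- function(sample, target = c("PPV", "NPV"),
                              cfg = estimator_config()) {
  target <- match_target(target)
  sample <- resolve_sample(sample, cfg)
  est <- corrected_predictive_value(sample, target)
  obs <- observed_proportion(sample, target)
  se <- sqrt(est * (1 - est) / obs$n)
  wald_interval(target, est, se, 2L, cfg, sample)
}

#' Approach 3: stratified percentile bootstrap
#'
#' Cases and sampled controls are resampled with replacement within their
#' own stratum (fixed margins: the numbers of cases and of sampled controls
#' are design constants, and the sampling fraction is held at its design
#' value). The corrected predictive value is recomputed in each resample and
#' the empirical `(1-level)/2` and `(1+level)/2` quantiles (linear
#' interpolation between order statistics) form the interval. Resamples with
#' an empty weighted denominator are continuity-corrected within that
#' replicate and counted in the `boot_degenerate` diagnostic.
#'
#' @inheritParams ci_naive_wald
#' @return An `interval_estimate` with `se = NA` and a `boot_degenerate`
#'   tally.
#' @export
ci_bootstrap <- function(sample, target = c("PPV", "NPV"),
                         cfg = estimator_config()) {
  target <- match_target(target)
  sample <- resolve_sample(sample, cfg)
  if (n_controls_sampled(sample) <= 0) {
    stop_invalid_design("bootstrap requires at least one sampled control")
  }
  if (n_cases(sample) <= 0) {
    stop_invalid_design("bootstrap requires at least one case")
  }
  est <- corrected_predictive_value(sample, target)
  sf <- sampling_fraction(sample)
  reps <- cfg$bootstrap_reps
  draws <- with_seed(cfg$seed, {
    n_ca <- n_cases(sample)
    n_co <- n_controls_sampled(sample)
    a_star <- stats::rbinom(reps, round(n_ca), sample$a / n_ca)
    b1_star <- stats::rbinom(reps, round(n_co), sample$b1 / n_co)
    list(a = a_star, c = round(n_ca) - a_star,
         b1 = b1_star, d1 = round(n_co) - b1_star)
  })
  if (target == "PPV") {
    num <- draws$a; other <- draws$b1 / sf
  } else {
    num <- draws$d1 / sf; other <- draws$c
  }
  degenerate <- num + other <= 0
  if (any(degenerate)) {
    # per-replicate continuity correction, sf held at the design value
    if (target == "PPV") {
      num[degenerate] <- draws$a[degenerate] + 0.5
      other[degenerate] <- (draws$b1[degenerate] + 0.5) / sf
    } else {
      num[degenerate] <- (draws$d1[degenerate] + 0.5) / sf
      other[degenerate] <- draws$c[degenerate] + 0.5
    }
  }
  pv <- num / (num + other)
  qs <- stats::quantile(pv, probs = c((1 - cfg$level) / 2,
                                      (1 + cfg$level) / 2),
                        names = FALSE, type = 7)
  new_interval_estimate(
    target = target, estimate = est, lower = qs[1L], upper = qs[2L],
    se = NA_real_, scale = "percentile", approach = 3L, level = cfg$level,
    truncated = FALSE,
    continuity_corrected = isTRUE(sample$continuity_corrected),
    boot_degenerate = sum(degenerate), boot_reps = reps)
}

sample_accuracy <- function(sample, cohort_prevalence) {
  se <- sample$a / n_cases(sample)
  sp <- sample$d1 / n_controls_sampled(sample)
  if (se <= 0 || se >= 1 || sp <= 0 || sp >= 1) {
    stop_boundary(
      "sensitivity or specificity at 0 or 1: delta-method variance undefined (consider continuity_correct())")
  }
  p <- cohort_prevalence
  if (!is_probability(p) || p <= 0 || p >= 1) {
    stop_validation("cohort prevalence must lie strictly inside (0, 1)")
  }
  list(se = se, sp = sp, p = p,
       n_case = n_cases(sample), n_ctrl = n_controls_sampled(sample))
}

#' Approach 4: delta-method interval from Se, Sp and prevalence
#'
#' The predictive value is written as a function of the sensitivity and
#' specificity estimated from the nested sample and the (known) cohort
#' prevalence; its variance follows by first-order Taylor propagation of the
#' two independent binomial variances `Se(1-Se)/n_case` and
#' `Sp(1-Sp)/n_ctrl`:
#' \deqn{Var(PPV) = \frac{p^2(1-p)^2[(1-Sp)^2 Se(1-Se)/n_{case} +
#'   Se^2 Sp(1-Sp)/n_{ctrl}]}{D^4}, \quad D = Se\,p + (1-Sp)(1-p)}
#' and analogously for the NPV with `E = Sp(1-p) + (1-Se)p`. The Wald
#' interval is formed on the probability scale.
#'
#' @inheritParams ci_naive_wald
#' @param cohort_prevalence Disease prevalence of the underlying cohort;
#'   defaults to the sample-implied value `(a+c)/cohort_size`, with which the
#'   point estimate coincides algebraically with
#'   [corrected_predictive_value()].
#' @return An `interval_estimate`.
#' @export
ci_mercaldo <- function(sample, target = c("PPV", "NPV"),
                        cfg = estimator_config(),
                        cohort_prevalence = n_cases(sample) / sample$cohort_size) {
  target <- match_target(target)
  sample <- resolve_sample(sample, cfg)
  acc <- sample_accuracy(sample, cohort_prevalence)
  est <- bayes_predictive_value(acc$se, acc$sp, acc$p, target)
  pq2 <- acc$p^2 * (1 - acc$p)^2
  v_se <- acc$se * (1 - acc$se) / acc$n_case
  v_sp <- acc$sp * (1 - acc$sp) / acc$n_ctrl
  if (target == "PPV") {
    D <- acc$se * acc$p + (1 - acc$sp) * (1 - acc$p)
    v <- pq2 * ((1 - acc$sp)^2 * v_se + acc$se^2 * v_sp) / D^4
  } else {
    E <- acc$sp * (1 - acc$p) + (1 - acc$se) * acc$p
    v <- pq2 * (acc$sp^2 * v_se + (1 - acc$se)^2 * v_sp) / E^4
  }
  wald_interval(target, est, sqrt(v), 4L, cfg, sample)
}

#' Approach 5: weighted logistic regression interval
#'
#' Fits the saturated weighted logistic model of [fit_weighted_logit()] and
#' forms a Wald interval on the logit scale with
#' `SE(logit PPV) = sqrt(var(alpha) + var(beta) + 2 cov(alpha, beta))` and
#' `SE(logit NPV) = sqrt(var(alpha))`, then back-transforms; the bounds are
#' therefore always inside (0, 1).
#'
#' @inheritParams ci_naive_wald
#' @return An `interval_estimate` with `scale = "logit"`.
#' @export
ci_weighted_logistic <- function(sample, target = c("PPV", "NPV"),
                                 cfg = estimator_config()) {
  target <- match_target(target)
  sample <- resolve_sample(sample, cfg)
  fit <- fit_weighted_logit(sample)
  lp <- if (target == "PPV") fit$alpha + fit$beta else -fit$alpha
  est <- invlogit(lp)
  se <- logit_se(fit, target)
  new_interval_estimate(
    target = target, estimate = est,
    lower = invlogit(lp - cfg$z * se), upper = invlogit(lp + cfg$z * se),
    se = se, scale = "logit", approach = 5L, level = cfg$level,
    truncated = FALSE,
    continuity_corrected = isTRUE(sample$continuity_corrected),
    fit = fit)
}

#' Approach 6: delta-method interval on the logit scale
#'
#' The Se/Sp/prevalence representation of approach 4, but with the variance
#' propagated to the logit of the predictive value:
#' `Var(logit PPV) = (1-Se)/(Se n_case) + Sp/((1-Sp) n_ctrl)` and
#' `Var(logit NPV) = Se/((1-Se) n_case) + (1-Sp)/(Sp n_ctrl)`.
#' The Wald interval on the logit scale is back-transformed, keeping the
#' bounds inside (0, 1).
#'
#' @inheritParams ci_mercaldo
#' @return An `interval_estimate` with `scale = "logit"`.
#' @export
ci_mercaldo_logit <- function(sample, target = c("PPV", "NPV"),
                              cfg = estimator_config(),
                              cohort_prevalence = n_cases(sample) / sample$cohort_size) {
  target <- match_target(target)
  sample <- resolve_sample(sample, cfg)
  acc <- sample_accuracy(sample, cohort_prevalence)
  est <- bayes_predictive_value(acc$se, acc$sp, acc$p, target)
  v <- if (target == "PPV") {
    (1 - acc$se) / (acc$se * acc$n_case) + acc$sp / ((1 - acc$sp) * acc$n_ctrl)
  } else {
    acc$se / ((1 - acc$se) * acc$n_case) + (1 - acc$sp) / (acc$sp * acc$n_ctrl)
  }
  se <- sqrt(v)
  lp <- logit(est)
  new_interval_estimate(
    target = target, estimate = est,
    lower = invlogit(lp - cfg$z * se), upper = invlogit(lp + cfg$z * se),
    se = se, scale = "logit", approach = 6L, level = cfg$level,
    truncated = FALSE,
    continuity_corrected = isTRUE(sample$continuity_corrected))
}

ci_fun_for_approach <- function(approach) {
  switch(as.character(approach),
         "1" = ci_naive_wald, "2" = ci_corrected_wald, "3" = ci_bootstrap,
         "4" = ci_mercaldo, "5" = ci_weighted_logistic,
         "6" = ci_mercaldo_logit,
         stop_validation(sprintf("unknown approach %s: must be 1..6",
                                 approach)))
}

#' Estimate one interval with a numbered approach
#'
#' @inheritParams ci_mercaldo
#' @param approach Integer 1 to 6.
#' @return An `interval_estimate`.
#' @export
estimate_interval <- function(sample, approach, target = c("PPV", "NPV"),
                              cfg = estimator_config(),
                              cohort_prevalence = n_cases(sample) / sample$cohort_size) {
  fun <- ci_fun_for_approach(approach)
  if (approach %in% c(4L, 6L)) {
    fun(sample, target, cfg, cohort_prevalence = cohort_prevalence)
  } else {
    fun(sample, target, cfg)
  }
}

#' All six interval approaches for both predictive values
#'
#' Runs approaches 1-6 for the requested targets. The point estimates agree
#' across all approaches for a given target (the approaches differ only in
#' how the confidence interval is built).
#'
#' @inheritParams ci_mercaldo
#' @param targets Character vector, subset of `c("PPV", "NPV")`.
#' @param approaches Integer vector, subset of 1:6.
#' @return A data frame of class `pv_estimates` with one row per approach x
#'   target: columns `approach`, `target`, `estimate`, `lower`, `upper`,
#'   `se`, `scale`, `level`, `truncated`, `continuity_corrected`.
#' @examples
#' ns <- nested_sample(30, 10, 10, 30, cohort_controls = 400)
#' estimate_all(ns, cfg = estimator_config(bootstrap_reps = 200, seed = 1))
#' @export
estimate_all <- function(sample, cfg = estimator_config(),
                         targets = c("PPV", "NPV"), approaches = 1:6,
                         cohort_prevalence = n_cases(sample) / sample$cohort_size) {
  rows <- list()
  for (target in targets) {
    for (ap in approaches) {
      est <- estimate_interval(sample, as.integer(ap), target, cfg,
                               cohort_prevalence = cohort_prevalence)
      rows[[length(rows) + 1L]] <- as.data.frame(est)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pv_estimates", "data.frame")
  out
}

#' Write interval estimates to CSV or JSON
#'
#' @param estimates A `pv_estimates` data frame from [estimate_all()].
#' @param path Destination file; `NULL` writes CSV to stdout.
#' @param format `"csv"` or `"json"`; default follows the file extension.
#' @param digits Optional rounding of the numeric columns for display
#'   parity with 2-decimal reporting; full precision by default.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path = NULL, format = NULL,
                            digits = NULL) {
  df <- as.data.frame(estimates)
  if (!is.null(digits)) {
    for (col in c("estimate", "lower", "upper", "se")) {
      df[[col]] <- round(df[[col]], digits)
    }
  }
  if (is.null(format)) {
    format <- if (!is.null(path) && grepl("\\.json$", path)) "json" else "csv"
  }
  if (format == "json") {
    txt <- jsonlite::toJSON(df, dataframe = "rows", na = "null", digits = NA,
                            pretty = TRUE)
    if (is.null(path)) cat(txt, "\n") else writeLines(txt, path)
  } else {
    if (is.null(path)) utils::write.csv(df, stdout(), row.names = FALSE)
    else utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read interval estimates back from a CSV written by [write_estimates()]
#'
#' @param path CSV file path.
#' @return A `pv_estimates` data frame.
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("pv_estimates", "data.frame")
  df
}
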