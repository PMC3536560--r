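cfg_fast <- estimator_config(bootstrap_reps = 500, seed = 99)

test_that("naive and corrected Wald SEs match direct arithmetic", {
  fx <- figure1_sample()
  a1 <- ci_naive_wald(fx, "PPV")
  expect_equal(a1$se, sqrt(0.75 * 0.25 / 40), tolerance = 1e-12)
  expect_equal(a1$estimate, 30 / 130)
  expect_equal(a1$lower, 30 / 130 - qnorm(0.975) * a1$se)
  a2 <- ci_corrected_wald(fx, "PPV")
  P <- 30 / 130
  expect_equal(a2$se, sqrt(P * (1 - P) / 40), tolerance = 1e-12)
  # symmetric maximum-variance case: P = 0.5 over 100 observed test-positives
  half <- nested_sample(50, 10, 50, 50, cohort_controls = 100)
  expect_equal(ci_corrected_wald(half, "PPV")$se, 0.05)
})

test_that("at full sampling the naive and corrected Wald intervals coincide", {
  full <- nested_sample(30, 10, 100, 300, cohort_controls = 400)
  a1 <- ci_naive_wald(full, "PPV")
  a2 <- ci_corrected_wald(full, "PPV")
  expect_identical(a1[c("estimate", "lower", "upper", "se")],
                   a2[c("estimate", "lower", "upper", "se")])
})

test_that("all six approaches share one point estimate per target", {
  set.seed(51)
  for (i in 1:25) {
    ns <- random_nested_sample()
    for (target in c("PPV", "NPV")) {
      ests <- vapply(1:6, function(ap) {
        estimate_interval(ns, ap, target, cfg_fast)$estimate
      }, numeric(1))
      expect_equal(max(ests) - min(ests), 0, tolerance = 1e-10)
      expect_equal(ests[1], corrected_predictive_value(ns, target),
                   tolerance = 1e-12)
    }
  }
})

test_that("interval bounds always lie in [0,1] around the estimate", {
  set.seed(52)
  samples <- c(list(figure1_sample(),
                    nested_sample(1, 1, 1, 1, cohort_controls = 500),
                    nested_sample(60, 1, 1, 60, cohort_controls = 1000)),
               lapply(1:10, function(i) random_nested_sample()))
  for (ns in samples) {
    for (target in c("PPV", "NPV")) {
      for (ap in 1:6) {
        est <- estimate_interval(ns, ap, target, cfg_fast)
        expect_gte(est$lower, 0)
        expect_lte(est$upper, 1)
        expect_lte(est$lower, est$estimate)
        expect_gte(est$upper, est$estimate)
      }
    }
  }
})

test_that("Wald intervals truncated at [0,1] are flagged", {
  ns <- nested_sample(1, 39, 2, 38, cohort_controls = 400)
  est <- ci_naive_wald(ns, "PPV")
  expect_true(est$truncated)
  expect_equal(est$lower, 0)
})

test_that("bootstrap intervals are seed-reproducible and bracket the estimate", {
  fx <- figure1_sample()
  b1 <- ci_bootstrap(fx, "PPV", estimator_config(bootstrap_reps = 1000, seed = 7))
  b2 <- ci_bootstrap(fx, "PPV", estimator_config(bootstrap_reps = 1000, seed = 7))
  expect_identical(b1[c("lower", "upper")], b2[c("lower", "upper")])
  expect_lte(b1$lower, b1$estimate)
  expect_gte(b1$upper, b1$estimate)
  expect_true(is.na(b1$se))
  b3 <- ci_bootstrap(fx, "PPV", estimator_config(bootstrap_reps = 1000, seed = 8))
  expect_false(identical(b1$lower, b3$lower))
  expect_error(
    ci_bootstrap(nested_sample(5, 5, 0, 0, cohort_controls = 10), "PPV",
                 cfg_fast),
    class = "nccpv_invalid_design_error")
})

test_that("bootstrap percentiles agree with the exact enumeration oracle", {
  fx <- figure1_sample()
  cfg <- estimator_config(bootstrap_reps = 10000, seed = 12)
  for (target in c("PPV", "NPV")) {
    est <- ci_bootstrap(fx, target, cfg)
    exact <- exact_boot_quantile(fx, target, c(0.025, 0.975))
    # absolute slack of one atom of the discrete resampling distribution
    expect_lt(abs(est$lower - exact[1]), 0.02)
    expect_lt(abs(est$upper - exact[2]), 0.02)
  }
})

test_that("delta-method SE matches numerical differentiation of the Bayes form", {
  fx <- figure1_sample()
  expect_equal(ci_mercaldo(fx, "PPV")$se, 0.05124411, tolerance = 1e-7)
  expect_equal(ci_mercaldo(fx, "NPV")$se, 0.00901171, tolerance = 1e-7)
  h <- 1e-6
  set.seed(53)
  for (i in 1:30) {
    ns <- random_nested_sample(min_cell = 2L)
    se_hat <- ns$a / (ns$a + ns$c)
    sp_hat <- ns$d1 / (ns$b1 + ns$d1)
    p <- (ns$a + ns$c) / ns$cohort_size
    for (target in c("PPV", "NPV")) {
      f <- function(se, sp) bayes_predictive_value(se, sp, p, target)
      dse <- (f(se_hat + h, sp_hat) - f(se_hat - h, sp_hat)) / (2 * h)
      dsp <- (f(se_hat, sp_hat + h) - f(se_hat, sp_hat - h)) / (2 * h)
      v <- dse^2 * se_hat * (1 - se_hat) / (ns$a + ns$c) +
        dsp^2 * sp_hat * (1 - sp_hat) / (ns$b1 + ns$d1)
      expect_equal(estimate_interval(ns, 4L, target, cfg_fast)$se, sqrt(v),
                   tolerance = 1e-6)
    }
  }
})

test_that("logit-scale delta interval matches its closed form and stays inside (0,1)", {
  fx <- figure1_sample()
  a6 <- ci_mercaldo_logit(fx, "PPV")
  expect_equal(a6$se, sqrt(0.25 / (0.75 * 40) + 3 / 40), tolerance = 1e-12)
  expect_gt(a6$lower, 0)
  expect_lt(a6$upper, 1)
  # width shrinks towards zero as the sample information grows
  big <- nested_sample(3000, 1000, 1000, 3000, cohort_controls = 40000)
  a6_big <- ci_mercaldo_logit(big, "PPV")
  expect_lt(a6_big$upper - a6_big$lower, (a6$upper - a6$lower) / 5)
})

test_that("weighted-logistic interval uses the fit's logit SE", {
  fx <- figure1_sample()
  a5 <- ci_weighted_logistic(fx, "PPV")
  fit <- fit_weighted_logit(fx)
  expect_equal(a5$se, logit_se(fit, "PPV"))
  lp <- fit$alpha + fit$beta
  expect_equal(a5$lower, plogis(lp - qnorm(0.975) * a5$se))
  expect_equal(a5$upper, plogis(lp + qnorm(0.975) * a5$se))
  a5n <- ci_weighted_logistic(fx, "NPV")
  expect_equal(a5n$se, sqrt(fit$cov[1, 1]))
})

test_that("width shrinks like 1/sqrt(k) when all counts scale by k", {
  # interior estimate so no Wald truncation disturbs the widths
  ns <- nested_sample(30, 30, 10, 30, cohort_controls = 400)
  k <- 4
  big <- nested_sample(30 * k, 30 * k, 10 * k, 30 * k,
                       cohort_controls = 400 * k)
  for (ap in c(1L, 2L, 4L, 6L)) {
    w <- function(s) {
      e <- estimate_interval(s, ap, "PPV", cfg_fast)
      e$upper - e$lower
    }
    expect_equal(w(big) / w(ns), 1 / sqrt(k), tolerance = 0.05)
  }
})

test_that("estimate_all returns the full approach-by-target grid", {
  fx <- figure1_sample()
  est <- estimate_all(fx, cfg_fast)
  expect_s3_class(est, "pv_estimates")
  expect_equal(nrow(est), 12L)
  expect_equal(round(est$estimate[est$target == "PPV"], 2), rep(0.23, 6))
  expect_equal(round(est$estimate[est$target == "NPV"], 2), rep(0.97, 6))
  expect_true(all(is.na(est$se[est$approach == 3])))
  expect_true(all(!is.na(est$se[est$approach != 3])))
  # lower level gives narrower intervals
  est90 <- estimate_all(fx, estimator_config(level = 0.9, bootstrap_reps = 500,
                                             seed = 99))
  expect_true(all(est90$upper - est90$lower <
                    est$upper - est$lower + 1e-12))
})

test_that("the continuity correction lets every approach run on a zero cell", {
  ns <- nested_sample(12, 0, 9, 30, cohort_controls = 400)
  cfg_cc <- estimator_config(bootstrap_reps = 200, seed = 5,
                             continuity_correction = TRUE)
  expect_error(ci_mercaldo(ns, "PPV"), class = "nccpv_boundary_error")
  expect_error(ci_weighted_logistic(ns, "PPV"),
               class = "nccpv_degenerate_table_error")
  est <- estimate_all(ns, cfg_cc)
  expect_equal(nrow(est), 12L)
  expect_true(all(est$continuity_corrected))
})

test_that("estimates round-trip through the CSV serialization", {
  fx <- figure1_sample()
  est <- estimate_all(fx, cfg_fast)
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates(est, path)
  back <- read_estimates(path)
  expect_equal(back$estimate, est$estimate, tolerance = 1e-12)
  expect_equal(back$approach, est$approach)
  expect_equal(back$target, est$target)
  expect_equal(back$lower, est$lower, tolerance = 1e-12)
})
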