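# Random valid nested samples for property-style tests. All four cells are
# kept >= min_cell so that every approach (including the saturated weighted
# logit) is defined.
random_nested_sample <- function(min_cell = 1L, max_cell = 60L) {
  a <- sample(min_cell:max_cell, 1L)
  c <- sample(min_cell:max_cell, 1L)
  b1 <- sample(min_cell:max_cell, 1L)
  d1 <- sample(min_cell:max_cell, 1L)
  # control pool at least as large as the controls sampled
  cohort_controls <- b1 + d1 + sample(0:200, 1L)
  nested_sample(a = a, c = c, b1 = b1, d1 = d1,
                cohort_controls = cohort_controls)
}

figure1_sample <- function() figure1_fixture()$sample

# Independent weighted-logit oracle: stats::glm on the grouped 2x2 data with
# case/control weights (non-integer weighted binomials trigger a harmless
# warning which we silence).
glm_oracle <- function(sample) {
  w <- make_weights(sample)
  df <- data.frame(
    x = c(1, 1, 0, 0),
    y = c(1, 0, 1, 0),
    n = c(sample$a, sample$b1, sample$c, sample$d1),
    w = c(w$w_case, w$w_control, w$w_case, w$w_control)
  )
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(), data = df,
               weights = df$n * df$w,
               control = stats::glm.control(epsilon = 1e-12))
  )
  list(coef = stats::coef(fit), vcov = suppressWarnings(stats::vcov(fit)))
}

# Exact percentile quantiles of the stratified bootstrap distribution of the
# corrected predictive value: the resampled case and control splits are two
# independent binomials, so the bootstrap law of the PV is a finite product
# distribution that can be enumerated outright.
exact_boot_quantile <- function(sample, target, probs) {
  sf <- sampling_fraction(sample)
  n_ca <- sample$a + sample$c
  n_co <- sample$b1 + sample$d1
  a_star <- 0:n_ca
  b1_star <- 0:n_co
  pa <- dbinom(a_star, n_ca, sample$a / n_ca)
  pb <- dbinom(b1_star, n_co, sample$b1 / n_co)
  grid <- expand.grid(a = a_star, b1 = b1_star)
  w <- as.vector(outer(pa, pb))
  if (target == "PPV") {
    num <- grid$a
    other <- grid$b1 / sf
  } else {
    num <- (n_co - grid$b1) / sf
    other <- n_ca - grid$a
  }
  degenerate <- num + other == 0
  if (target == "PPV") {
    num[degenerate] <- num[degenerate] + 0.5
    other[degenerate] <- other[degenerate] + 0.5 / sf
  } else {
    num[degenerate] <- num[degenerate] + 0.5 / sf
    other[degenerate] <- other[degenerate] + 0.5
  }
  pv <- num / (num + other)
  ord <- order(pv)
  pv <- pv[ord]
  cdf <- cumsum(w[ord])
  vapply(probs, function(p) pv[which(cdf >= p)[1L]], numeric(1))
}
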