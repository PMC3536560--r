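#' Case/control weights for the weighted logistic fit
#'
#' Each case gets weight `N1/N` and each sampled control `N1/(N sf)`, where
#' `N1` is the nested sample size, `N` the cohort size and `sf` the sampling
#' fraction. The weights sum to `N1` over the nested sample, so the effective
#' sample size in the information matrix is the number of subjects actually
#' observed, while the weighted cell totals sit on cohort scale up to the
#' common factor `N1/N`.
#'
#' @param sample A [nested_sample()].
#' @return A list with fields `w_case` and `w_control`.
#' @examples
#' ns <- nested_sample(30, 10, 10, 30, cohort_controls = 400)
#' make_weights(ns)
#' @export
make_weights <- function(sample) {
  stopifnot(inherits(sample, "nested_sample"))
  sf <- sampling_fraction(sample)
  w_case <- nested_size(sample) / sample$cohort_size
  structure(list(w_case = w_case, w_control = w_case / sf),
            class = "weight_spec")
}

#' Fit the weighted logistic model on a grouped 2x2 nested sample
#'
#' Maximises the weight-weighted Bernoulli log-likelihood of
#' `logit P(disease) = alpha + beta * x`, `x = 1` for a positive index test,
#' by Newton iteration on the grouped 2x2 data (two covariate patterns, four
#' weighted cells). The model is saturated, so at the optimum the fitted
#' probabilities equal the weighted empirical proportions; the covariance is
#' the inverse of the weighted expected (Fisher) information, whose effective
#' sample size is N1 because the weights sum to N1.
#'
#' @param sample A [nested_sample()]; all four cells must be positive (use
#'   [continuity_correct()] otherwise).
#' @param weights Optional weight spec from [make_weights()]; computed from
#'   the sample by default.
#' @param tol Convergence tolerance on the max-norm of the score (gradient),
#'   relative to the total weight N1; a log-likelihood change criterion is
#'   deliberately not used, since near the optimum it is quadratically
#'   smaller than the score and would stop the iteration while the
#'   coefficients are still several digits short.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `weighted_glm_fit` with fields `alpha`, `beta`,
#'   `cov` (2x2 over (alpha, beta)), `iterations`, `converged`, `deviance`.
#' @export
fit_weighted_logit <- function(sample, weights = make_weights(sample),
                               tol = 1e-12, max_iter = 50L) {
  stopifnot(inherits(sample, "nested_sample"))
  if (min(sample$a, sample$c, sample$b1, sample$d1) <= 0) {
    stop_degenerate_table(
      "weighted logistic fit is separated: a zero cell makes the saturated logit non-identifiable (consider continuity_correct())")
  }
  wc <- weights$w_case
  wk <- weights$w_control
  # weighted successes (diseased) and failures per covariate pattern
  s1 <- wc * sample$a;  f1 <- wk * sample$b1   # x = 1 (test positive)
  s0 <- wc * sample$c;  f0 <- wk * sample$d1   # x = 0 (test negative)

  loglik <- function(alpha, beta) {
    p1 <- invlogit(alpha + beta); p0 <- invlogit(alpha)
    s1 * log(p1) + f1 * log1p(-p1) + s0 * log(p0) + f0 * log1p(-p0)
  }

  gscale <- s1 + f1 + s0 + f0  # = N1 by construction of the weights
  alpha <- logit(s0 / (s0 + f0))
  beta <- 0
  ll <- loglik(alpha, beta)
  converged <- FALSE
  iter <- 0L
  trace <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    p1 <- invlogit(alpha + beta); p0 <- invlogit(alpha)
    m1 <- s1 + f1; m0 <- s0 + f0
    g <- c(alpha = (s1 - m1 * p1) + (s0 - m0 * p0),
           beta  = (s1 - m1 * p1))
    if (max(abs(g)) < tol * gscale) {
      converged <- TRUE
      break
    }
    i1 <- m1 * p1 * (1 - p1); i0 <- m0 * p0 * (1 - p0)
    info <- matrix(c(i1 + i0, i1, i1, i1), 2L, 2L)
    step <- solve(info, g)
    # score at the floating-point floor: the step no longer moves the params
    if (max(abs(step)) < 1e-13 * (1 + max(abs(alpha), abs(beta)))) {
      converged <- TRUE
      break
    }
    # damped Newton: halve the step while it worsens the log-likelihood
    # (beyond floating-point noise, so terminal refinements are not blocked)
    noise <- 1e-12 * (abs(ll) + 1)
    ll_new <- loglik(alpha + step[1L], beta + step[2L])
    halvings <- 0L
    while ((!is.finite(ll_new) || ll_new < ll - noise) && halvings < 30L) {
      step <- step / 2
      halvings <- halvings + 1L
      ll_new <- loglik(alpha + step[1L], beta + step[2L])
    }
    alpha <- alpha + step[1L]
    beta <- beta + step[2L]
    trace <- c(trace, ll_new)
    ll <- ll_new
  }
  if (!converged) {
    stop_convergence(sprintf(
      "weighted logistic fit did not converge in %d iterations", max_iter),
      ll_trace = trace)
  }
  p1 <- invlogit(alpha + beta); p0 <- invlogit(alpha)
  i1 <- (s1 + f1) * p1 * (1 - p1); i0 <- (s0 + f0) * p0 * (1 - p0)
  info <- matrix(c(i1 + i0, i1, i1, i1), 2L, 2L,
                 dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
  # saturated model: deviance relative to the saturated fit is zero up to
  # numerical error; report -2 (loglik - saturated loglik)
  sat <- function(s, f) {
    m <- s + f
    ifelse(s > 0, s * log(s / m), 0) + ifelse(f > 0, f * log(f / m), 0)
  }
  dev <- max(0, -2 * (ll - (sat(s1, f1) + sat(s0, f0))))
  structure(
    list(alpha = unname(alpha), beta = unname(beta), cov = solve(info),
         iterations = iter, converged = converged, deviance = dev,
         loglik = ll, weights = list(w_case = wc, w_control = wk)),
    class = "weighted_glm_fit"
  )
}

#' @export
print.weighted_glm_fit <- function(x, ...) {
  cat("Weighted logistic fit: logit P(D) = alpha + beta * test\n")
  cat(sprintf("  alpha = %.6f, beta = %.6f (%d iterations, converged: %s)\n",
              x$alpha, x$beta, x$iterations, x$converged))
  cat(sprintf("  implied PPV = %.6f, NPV = %.6f\n",
              invlogit(x$alpha + x$beta), 1 - invlogit(x$alpha)))
  invisible(x)
}

#' Standard error of the logit predictive value from a weighted fit
#'
#' `logit(PPV) = alpha + beta`, so `SE = sqrt(var(alpha) + var(beta) +
#' 2 cov(alpha, beta))`; `logit(NPV) = -alpha` (the NPV is the complement of
#' the disease probability among test negatives) and negation preserves the
#' SE, so `SE = sqrt(var(alpha))`.
#'
#' @param fit A [fit_weighted_logit()] result.
#' @param target `"PPV"` or `"NPV"`.
#' @return A non-negative standard error on the logit scale.
#' @export
logit_se <- function(fit, target = c("PPV", "NPV")) {
  stopifnot(inherits(fit, "weighted_glm_fit"))
  if (!isTRUE(fit$converged)) stop_convergence("fit did not converge")
  target <- match_target(target)
  v <- if (target == "PPV") {
    fit$cov[1L, 1L] + fit$cov[2L, 2L] + 2 * fit$cov[1L, 2L]
  } else {
    fit$cov[1L, 1L]
  }
  sqrt(max(v, 0))
}
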