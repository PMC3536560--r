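#' Specify a source population by prevalence, sensitivity and specificity
#'
#' @param prevalence,sensitivity,specificity Probabilities strictly inside
#'   (0, 1).
#' @param population_size Source population size (default 1400).
#' @param label Free-text label.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(prevalence, sensitivity, specificity,
                        population_size = 1400L, label = "") {
  for (nm in c("prevalence", "sensitivity", "specificity")) {
    x <- get(nm)
    if (!is_probability(x) || x <= 0 || x >= 1) {
      stop_validation(sprintf("`%s` must lie strictly inside (0, 1)", nm))
    }
  }
  if (!is_count(population_size) || population_size < 1) {
    stop_validation("`population_size` must be a positive integer")
  }
  structure(list(prevalence = prevalence, sensitivity = sensitivity,
                 specificity = specificity,
                 population_size = as.integer(population_size),
                 label = as.character(label)),
            class = "source_spec")
}

#' Build an integer source population from a specification
#'
#' Cells are constructed by rounding in a fixed order: the number of cases is
#' `round(p N)`, true positives `round(Se cases)`, true negatives
#' `round(Sp controls)`, and the remaining cells follow by subtraction
#' (round-half-even, R's default). The realized prevalence, sensitivity and
#' specificity round back to the specification at 2 decimals.
#'
#' @param spec A [source_spec()].
#' @return A [cohort_table()].
#' @examples
#' dd <- source_spec(0.1, 0.97, 0.33, label = "d_dimer")
#' pop <- build_source_population(dd)
#' round(cohort_predictive_value(pop, "PPV"), 2)  # 0.14
#' @export
build_source_population <- function(spec) {
  stopifnot(inherits(spec, "source_spec"))
  n <- spec$population_size
  cases <- round(spec$prevalence * n)
  controls <- n - cases
  tp <- round(spec$sensitivity * cases)
  fn <- cases - tp
  tn <- round(spec$specificity * controls)
  fp <- controls - tn
  if (min(cases, controls, tp, fn, tn, fp) < 0) {
    stop_invalid_design("rounded specification yields a negative cell")
  }
  ct <- cohort_table(a = tp, b = fp, c = fn, d = tn)
  realized <- c(cohort_prevalence(ct), cohort_sensitivity(ct),
                cohort_specificity(ct))
  stated <- c(spec$prevalence, spec$sensitivity, spec$specificity)
  if (any(abs(round(realized, 2) - round(stated, 2)) > 1e-9)) {
    stop_invalid_design(
      "rounded population does not reproduce the stated parameters at 2 decimals")
  }
  ct
}

#' Draw a bootstrap cohort from a source population
#'
#' One multinomial draw of size `n` with cell probabilities proportional to
#' the source cells: a cross-sectional cohort of `n` patients drawn with
#' replacement from the source population.
#'
#' @param source A [cohort_table()].
#' @param n Cohort size.
#' @return A [cohort_table()].
#' @export
draw_cohort <- function(source, n = cohort_size(source)) {
  stopifnot(inherits(source, "cohort_table"))
  if (!is_count(n) || n < 1) stop_validation("`n` must be a positive integer")
  cells <- c(source$a, source$b, source$c, source$d)
  drawn <- stats::rmultinom(1L, n, cells / sum(cells))[, 1L]
  cohort_table(a = drawn[1L], b = drawn[2L], c = drawn[3L], d = drawn[4L])
}

#' Draw a nested case-control sample from a cohort
#'
#' All cases are kept; `ratio` controls per case are drawn without
#' replacement from the cohort's control pool, so the split of sampled
#' controls over index-test results is hypergeometric. The sampling fraction
#' is recorded as `(b1+d1)/(b+d)`.
#'
#' @param cohort A [cohort_table()].
#' @param ratio Integer number of controls per case (case-control ratio
#'   1:`ratio`).
#' @return A [nested_sample()].
#' @export
draw_nested_sample <- function(cohort, ratio = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!is_count(ratio) || ratio < 1) {
    stop_invalid_design("`ratio` must be a positive integer")
  }
  cases <- cohort$a + cohort$c
  controls <- cohort$b + cohort$d
  if (cases < 1) stop_degenerate_table("cohort has no cases")
  k <- ratio * cases
  if (k > controls) {
    stop_invalid_design(sprintf(
      "cohort has %g controls but ratio 1:%d of %g cases needs %g",
      controls, ratio, cases, k))
  }
  b1 <- stats::rhyper(1L, m = cohort$b, n = cohort$d, k = k)
  nested_sample(a = cohort$a, c = cohort$c, b1 = b1, d1 = k - b1,
                cohort_controls = controls)
}

#' Simulation design for a coverage study
#'
#' @param source A [source_spec()] or explicit [cohort_table()] source
#'   population.
#' @param ratio Controls per case (1, 2, 3 or 4 in the study grid).
#' @param replicates Number of simulated cohorts / nested samples.
#' @param bootstrap_reps Bootstrap resamples inside each replicate when
#'   approach 3 is requested.
#' @param level Confidence level.
#' @param seed Root seed; per-replicate seeds are derived from it so that
#'   replicate r is reproducible independently of which approaches run.
#' @param approaches Subset of 1:6.
#' @param targets Subset of `c("PPV", "NPV")`.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(source, ratio = 1L, replicates = 1000L,
                       bootstrap_reps = 1000L, level = 0.95, seed = NULL,
                       approaches = 1:6, targets = c("PPV", "NPV")) {
  if (inherits(source, "source_spec")) source <- build_source_population(source)
  stopifnot(inherits(source, "cohort_table"))
  if (!is_count(replicates) || replicates < 1) {
    stop_validation("`replicates` must be a positive integer")
  }
  if (!all(approaches %in% 1:6)) {
    stop_validation("`approaches` must be a subset of 1:6")
  }
  targets <- vapply(targets, match_target, character(1), USE.NAMES = FALSE)
  expected_cases <- cohort_prevalence(source) * cohort_size(source)
  expected_controls <- cohort_size(source) - expected_cases
  if (ratio * expected_cases > expected_controls) {
    stop_invalid_design(sprintf(
      "ratio 1:%d needs %.0f controls on average but the cohort carries %.0f",
      ratio, ratio * expected_cases, expected_controls))
  }
  structure(list(source = source, ratio = as.integer(ratio),
                 replicates = as.integer(replicates),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 level = level, seed = seed,
                 approaches = as.integer(approaches), targets = targets),
            class = "sim_design")
}

#' Monte-Carlo acceptability interval for empirical coverage
#'
#' With nominal non-coverage `p = 1 - level` and `B` simulation replicates,
#' the Monte-Carlo standard error of the coverage estimate is
#' `sqrt(p (1 - p) / B)`; coverage outside `level +/- 2 SE` is under- or
#' over-coverage.
#'
#' @param level Nominal confidence level.
#' @param replicates Number of simulation replicates `B`.
#' @return A list with `lower`, `upper`, `se`.
#' @examples
#' acceptability_interval(0.95, 1000)  # se 0.0069, range (0.936, 0.964)
#' @export
acceptability_interval <- function(level = 0.95, replicates = 1000L) {
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop_validation("`level` must lie in (0, 1)")
  }
  if (!is_count(replicates) || replicates < 1) {
    stop_validation("`replicates` must be a positive integer")
  }
  nominal <- 1 - level
  se <- sqrt(nominal * (1 - nominal) / replicates)
  list(lower = level - 2 * se, upper = level + 2 * se, se = se)
}

#' Run a coverage study over simulated nested case-control samples
#'
#' For each replicate a cohort is drawn with replacement from the source
#' population, a nested case-control sample is drawn from the cohort, and
#' each requested approach's confidence interval is computed using the
#' realized prevalence of that cohort. The truth against which coverage is
#' judged is the source-population predictive value. Cohorts with no cases
#' or with too few controls for the requested ratio are redrawn and counted.
#'
#' @param design A [sim_design()].
#' @return An object of class `coverage_result`: a data frame with one row
#'   per approach x target (`coverage`, `mean_width`, `mean_estimate`,
#'   `replicates_used`, `degenerate_replicates`, `truth`) and attributes
#'   `redraws` (discarded degenerate cohorts) and `design`.
#' @export
run_coverage_study <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  source <- design$source
  n <- cohort_size(source)
  B <- design$replicates
  truth <- vapply(design$targets,
                  function(t) cohort_predictive_value(source, t), numeric(1))
  names(truth) <- design$targets

  keys <- as.vector(outer(design$approaches, design$targets, paste, sep = ":"))
  cover <- stats::setNames(rep(0L, length(keys)), keys)
  width_sum <- est_sum <- stats::setNames(rep(0, length(keys)), keys)
  used <- stats::setNames(rep(0L, length(keys)), keys)
  degen <- stats::setNames(rep(0L, length(keys)), keys)
  redraws <- 0L

  run <- function() {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
    for (r in seq_len(B)) {
      set.seed(rep_seeds[r])
      repeat {
        cohort <- draw_cohort(source, n)
        cases <- cohort$a + cohort$c
        controls <- cohort$b + cohort$d
        if (cases >= 1 && design$ratio * cases <= controls &&
            cases < cohort_size(cohort)) break
        redraws <<- redraws + 1L
      }
      ns <- draw_nested_sample(cohort, design$ratio)
      p_cohort <- cohort_prevalence(cohort)
      cfg <- estimator_config(level = design$level,
                              bootstrap_reps = design$bootstrap_reps)
      for (target in design$targets) {
        for (ap in design$approaches) {
          key <- paste(ap, target, sep = ":")
          est <- tryCatch(
            estimate_interval(ns, ap, target, cfg,
                              cohort_prevalence = p_cohort),
            nccpv_error = function(e) NULL)
          if (is.null(est)) {
            degen[key] <<- degen[key] + 1L
            next
          }
          used[key] <<- used[key] + 1L
          tv <- truth[[target]]
          if (est$lower <= tv && tv <= est$upper) {
            cover[key] <<- cover[key] + 1L
          }
          width_sum[key] <<- width_sum[key] + (est$upper - est$lower)
          est_sum[key] <<- est_sum[key] + est$estimate
        }
      }
    }
  }
  with_seed(design$seed, run())

  rows <- do.call(rbind, lapply(keys, function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
    data.frame(approach = as.integer(parts[1L]), target = parts[2L],
               coverage = cover[[key]] / used[[key]],
               mean_width = width_sum[[key]] / used[[key]],
               mean_estimate = est_sum[[key]] / used[[key]],
               replicates_used = used[[key]],
               degenerate_replicates = degen[[key]],
               truth = truth[[parts[2L]]],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  structure(rows, class = c("coverage_result", "data.frame"),
            redraws = redraws, design = design)
}

#' The worked toy example: a cohort of 440 with a 10% control sample
#'
#' A cohort with 40 diseased (30 test-positive) and 400 non-diseased
#' (100 test-positive) subjects, and the nested case-control sample that
#' keeps all 40 cases and samples 10% of the controls (10 test-positive, 30
#' test-negative). Cohort and corrected nested estimates agree: PPV 0.23,
#' NPV 0.97, sampling fraction 0.1.
#'
#' @return A list with elements `cohort` ([cohort_table()]) and `sample`
#'   ([nested_sample()]).
#' @export
figure1_fixture <- function() {
  list(cohort = cohort_table(a = 30, b = 100, c = 10, d = 300),
       sample = nested_sample(a = 30, c = 10, b1 = 10, d1 = 30,
                              cohort_controls = 400, cohort_size = 440))
}

# Published accuracy of the two index tests in the N = 1400 source
# populations, by prevalence.
accuracy_grid <- list(
  d_dimer = list(
    "0.05" = c(se = 0.96, sp = 0.32),
    "0.1"  = c(se = 0.97, sp = 0.33),
    "0.2"  = c(se = 0.96, sp = 0.33)
  ),
  calf_difference = list(
    "0.05" = c(se = 0.69, sp = 0.65),
    "0.1"  = c(se = 0.68, sp = 0.64),
    "0.2"  = c(se = 0.67, sp = 0.65)
  )
)

#' Source-population specifications for the two DVT index tests
#'
#' Sensitivity and specificity of the D-dimer test and the calf-difference
#' test in N = 1400 source populations at prevalence 0.05, 0.1 or 0.2 of
#' deep venous thrombosis.
#'
#' @param test `"d_dimer"` or `"calf_difference"`.
#' @param prevalence One of 0.05, 0.1, 0.2.
#' @return A [source_spec()].
#' @examples
#' table1_fixture("d_dimer", 0.1)
#' @export
table1_fixture <- function(test = c("d_dimer", "calf_difference"),
                           prevalence = c(0.05, 0.1, 0.2)) {
  test <- match.arg(test)
  if (length(prevalence) > 1L) prevalence <- prevalence[1L]
  key <- format(prevalence, trim = TRUE)
  acc <- accuracy_grid[[test]][[key]]
  if (is.null(acc)) {
    stop_validation("`prevalence` must be one of 0.05, 0.1, 0.2")
  }
  source_spec(prevalence = prevalence, sensitivity = acc[["se"]],
              specificity = acc[["sp"]], population_size = 1400L,
              label = test)
}
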