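#' Construct a full-cohort 2x2 table (disease x index test)
#'
#' A `cohort_table` holds the complete cross-classification of a cohort or
#' source population by true disease status (reference test) and index test
#' result: `a` true positives, `b` false positives, `c` false negatives and
#' `d` true negatives.
#'
#' @param a Number of diseased subjects with a positive index test.
#' @param b Number of non-diseased subjects with a positive index test.
#' @param c Number of diseased subjects with a negative index test.
#' @param d Number of non-diseased subjects with a negative index test.
#' @return An object of class `cohort_table` with fields `a`, `b`, `c`, `d`.
#' @examples
#' ct <- cohort_table(a = 30, b = 100, c = 10, d = 300)
#' cohort_predictive_value(ct, "PPV")
#' @export
cohort_table <- function(a, b, c, d) {
  for (nm in c("a", "b", "c", "d")) {
    x <- get(nm)
    if (!is_count(x)) {
      stop_validation(sprintf("cell `%s` must be a non-negative integer, got %s",
                              nm, deparse(x)))
    }
  }
  n <- a + b + c + d
  if (n <= 0) stop_validation("cohort table is empty: a+b+c+d must be > 0")
  structure(
    list(a = as.numeric(round(a)), b = as.numeric(round(b)),
         c = as.numeric(round(c)), d = as.numeric(round(d))),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("test +", "test -"),
                              c("diseased", "non-diseased")))
  cat("Cohort 2x2 table (N =", sum(unlist(x[c("a", "b", "c", "d")])), ")\n")
  print(m)
  invisible(x)
}

cohort_size <- function(cohort) cohort$a + cohort$b + cohort$c + cohort$d

cohort_prevalence <- function(cohort) {
  (cohort$a + cohort$c) / cohort_size(cohort)
}

cohort_sensitivity <- function(cohort) {
  m <- cohort$a + cohort$c
  if (m <= 0) stop_degenerate_table("sensitivity undefined: no diseased subjects")
  cohort$a / m
}

cohort_specificity <- function(cohort) {
  m <- cohort$b + cohort$d
  if (m <= 0) stop_degenerate_table("specificity undefined: no non-diseased subjects")
  cohort$d / m
}

#' Construct a nested case-control sample
#'
#' In a nested case-control design all diseased subjects (cases) of a fully
#' enumerated cohort are kept, while only a random fraction of the
#' non-diseased subjects (controls) is sampled and tested with the index
#' test. The cohort context (number of cohort controls and cohort size) is
#' what makes absolute post-test probabilities estimable.
#'
#' @param a Cases with a positive index test.
#' @param c Cases with a negative index test.
#' @param b1 Sampled controls with a positive index test.
#' @param d1 Sampled controls with a negative index test.
#' @param cohort_controls Total number of non-diseased subjects in the cohort.
#' @param cohort_size Total cohort size; defaults to `a + c + cohort_controls`
#'   and must equal it (all cases are in the sample).
#' @return An object of class `nested_sample`.
#' @examples
#' ns <- nested_sample(a = 30, c = 10, b1 = 10, d1 = 30, cohort_controls = 400)
#' sampling_fraction(ns)
#' corrected_predictive_value(ns, "PPV")
#' @export
nested_sample <- function(a, c, b1, d1, cohort_controls,
                          cohort_size = a + c + cohort_controls) {
  for (nm in c("a", "c", "b1", "d1", "cohort_controls", "cohort_size")) {
    x <- get(nm)
    if (!is_count(x)) {
      stop_validation(sprintf("`%s` must be a non-negative integer, got %s",
                              nm, deparse(x)))
    }
  }
  if (a + c < 1) {
    stop_validation("a + c must be >= 1: the nested sample contains all cohort cases")
  }
  if (b1 + d1 > cohort_controls) {
    stop_validation("b1 + d1 exceeds cohort_controls: cannot sample more controls than the cohort holds")
  }
  if (cohort_size != a + c + cohort_controls) {
    stop_validation("cohort_size must equal (a + c) + cohort_controls")
  }
  new_nested_sample(a, c, b1, d1, cohort_controls, cohort_size)
}

# Internal constructor that skips integer validation, used by the continuity
# correction (which makes counts fractional) and by bootstrap replicates.
new_nested_sample <- function(a, c, b1, d1, cohort_controls, cohort_size,
                              continuity_corrected = FALSE,
                              sampling_fraction = NULL) {
  structure(
    list(a = as.numeric(a), c = as.numeric(c),
         b1 = as.numeric(b1), d1 = as.numeric(d1),
         cohort_controls = as.numeric(cohort_controls),
         cohort_size = as.numeric(cohort_size),
         continuity_corrected = continuity_corrected,
         sampling_fraction = sampling_fraction),
    class = "nested_sample"
  )
}

#' @export
print.nested_sample <- function(x, ...) {
  cat("Nested case-control sample\n")
  cat(sprintf("  cases:    a = %g (test +), c = %g (test -)\n", x$a, x$c))
  cat(sprintf("  controls: b1 = %g (test +), d1 = %g (test -) of %g in cohort\n",
              x$b1, x$d1, x$cohort_controls))
  cat(sprintf("  cohort size N = %g, nested size N1 = %g, sampling fraction = %.4g\n",
              x$cohort_size, nested_size(x), sampling_fraction(x)))
  if (isTRUE(x$continuity_corrected)) cat("  (continuity corrected)\n")
  invisible(x)
}

nested_size <- function(sample) sample$a + sample$c + sample$b1 + sample$d1

n_cases <- function(sample) sample$a + sample$c

n_controls_sampled <- function(sample) sample$b1 + sample$d1

#' Sampling fraction of a nested case-control sample
#'
#' The proportion of the cohort's controls that was included in the nested
#' sample, `(b1 + d1) / cohort_controls`. Its inverse re-weights the sampled
#' control counts back to cohort scale.
#'
#' @param sample A [nested_sample()].
#' @return A fraction in (0, 1].
#' @export
sampling_fraction <- function(sample) {
  stopifnot(inherits(sample, "nested_sample"))
  if (!is.null(sample$sampling_fraction)) return(sample$sampling_fraction)
  if (sample$cohort_controls <= 0) {
    stop_invalid_design("sampling fraction undefined: cohort has no controls")
  }
  if (sample$b1 + sample$d1 <= 0) {
    stop_invalid_design("sampling fraction undefined: no controls were sampled")
  }
  (sample$b1 + sample$d1) / sample$cohort_controls
}

#' Haldane-Anscombe continuity correction for a nested sample
#'
#' Adds 0.5 to each of the four nested counts (a, c, b1, d1), for use when a
#' cell of the sampled 2x2 table is empty and a predictive value or its SE
#' would otherwise be degenerate. The sampling fraction is frozen at the
#' design value of the uncorrected sample: the correction perturbs the
#' counts, not the sampling design.
#'
#' @param sample A [nested_sample()].
#' @return A `nested_sample` with fractional counts and
#'   `continuity_corrected = TRUE`.
#' @export
continuity_correct <- function(sample) {
  stopifnot(inherits(sample, "nested_sample"))
  if (isTRUE(sample$continuity_corrected)) return(sample)
  new_nested_sample(sample$a + 0.5, sample$c + 0.5,
                    sample$b1 + 0.5, sample$d1 + 0.5,
                    sample$cohort_controls, sample$cohort_size,
                    continuity_corrected = TRUE,
                    sampling_fraction = sampling_fraction(sample))
}

#' Predictive values from a full cohort table
#'
#' PPV = a / (a + b), the probability of disease given a positive index test;
#' NPV = d / (c + d), the probability of no disease given a negative test.
#'
#' @param cohort A [cohort_table()].
#' @param target `"PPV"` or `"NPV"`.
#' @return A probability.
#' @export
cohort_predictive_value <- function(cohort, target = c("PPV", "NPV")) {
  stopifnot(inherits(cohort, "cohort_table"))
  target <- match_target(target)
  if (target == "PPV") {
    denom <- cohort$a + cohort$b
    if (denom <= 0) stop_degenerate_table("PPV undefined: no test-positive subjects in cohort")
    cohort$a / denom
  } else {
    denom <- cohort$c + cohort$d
    if (denom <= 0) stop_degenerate_table("NPV undefined: no test-negative subjects in cohort")
    cohort$d / denom
  }
}

#' Sampling-fraction-corrected predictive values from a nested sample
#'
#' Control counts are inflated by the inverse sampling fraction so the
#' denominator is on cohort scale:
#' `PPV = a / (a + b1/sf)` and `NPV = (d1/sf) / (c + d1/sf)`.
#' When the whole control pool is sampled (sf = 1) this reduces to the raw
#' cohort proportion. PPV and NPV share one code path: the NPV is computed by
#' swapping the roles of the case and control cells (a <-> d1, b1 <-> c) with
#' the sf weight applied to the control cell.
#'
#' @inheritParams sampling_fraction
#' @param target `"PPV"` or `"NPV"`.
#' @return A probability.
#' @export
corrected_predictive_value <- function(sample, target = c("PPV", "NPV")) {
  stopifnot(inherits(sample, "nested_sample"))
  target <- match_target(target)
  sf <- sampling_fraction(sample)
  # shared path: numerator cell, other cell; control cells carry weight 1/sf
  if (target == "PPV") {
    num <- sample$a; other <- sample$b1 / sf
  } else {
    num <- sample$d1 / sf; other <- sample$c
  }
  denom <- num + other
  if (denom <= 0) {
    stop_degenerate_table(sprintf(
      "%s undefined: weighted denominator is zero (consider continuity_correct())",
      target))
  }
  num / denom
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Bayes' theorem:
#' `PPV = Se p / (Se p + (1 - Sp)(1 - p))` and
#' `NPV = Sp (1 - p) / (Sp (1 - p) + (1 - Se) p)`.
#'
#' @param se Sensitivity in \[0, 1\].
#' @param sp Specificity in \[0, 1\].
#' @param p Disease prevalence in \[0, 1\].
#' @param target `"PPV"` or `"NPV"`.
#' @return A probability.
#' @export
bayes_predictive_value <- function(se, sp, p, target = c("PPV", "NPV")) {
  for (nm in c("se", "sp", "p")) {
    if (!is_probability(get(nm))) {
      stop_validation(sprintf("`%s` must be a probability in [0, 1]", nm))
    }
  }
  target <- match_target(target)
  if (target == "PPV") {
    denom <- se * p + (1 - sp) * (1 - p)
    if (denom <= 0) stop_degenerate_table("PPV undefined: P(test positive) is zero")
    se * p / denom
  } else {
    denom <- sp * (1 - p) + (1 - se) * p
    if (denom <= 0) stop_degenerate_table("NPV undefined: P(test negative) is zero")
    sp * (1 - p) / denom
  }
}

#' Read a nested sample from CSV or JSON
#'
#' The CSV dialect is a single record with header columns
#' `a, c, b1, d1, cohort_controls, cohort_size`; the JSON form is an object
#' with the same fields.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A [nested_sample()].
#' @export
read_nested_sample <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) != 1L) {
      stop_validation(sprintf("expected exactly one record in %s, found %d",
                              path, nrow(df)))
    }
    rec <- as.list(df[1L, ])
  }
  need <- c("a", "c", "b1", "d1", "cohort_controls")
  missing <- setdiff(need, names(rec))
  if (length(missing)) {
    stop_validation(sprintf("missing required field(s): %s",
                            paste(missing, collapse = ", ")))
  }
  args <- rec[intersect(c(need, "cohort_size"), names(rec))]
  do.call(nested_sample, args)
}

#' Write a nested sample to CSV or JSON
#'
#' @param sample A [nested_sample()].
#' @param path Destination; format chosen by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_nested_sample <- function(sample, path) {
  stopifnot(inherits(sample, "nested_sample"))
  rec <- sample[c("a", "c", "b1", "d1", "cohort_controls", "cohort_size")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  }
  invisible(path)
}

#' Thin a cohort into a nested sample deterministically
#'
#' Keeps all cases and exactly `sf * b` / `sf * d` controls per test stratum
#' (must be integers). Mainly useful for algebraic checks: with exact
#' thinning the corrected predictive values equal the cohort values exactly.
#'
#' @param cohort A [cohort_table()].
#' @param sf Sampling fraction in (0, 1] with `sf * b` and `sf * d` integral.
#' @return A [nested_sample()].
#' @export
thin_cohort <- function(cohort, sf) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!is.numeric(sf) || sf <= 0 || sf > 1) {
    stop_invalid_design("`sf` must lie in (0, 1]")
  }
  b1 <- cohort$b * sf
  d1 <- cohort$d * sf
  if (!is_count(b1) || !is_count(d1)) {
    stop_invalid_design("exact thinning requires sf * b and sf * d to be integers")
  }
  nested_sample(a = cohort$a, c = cohort$c, b1 = round(b1), d1 = round(d1),
                cohort_controls = cohort$b + cohort$d)
}
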