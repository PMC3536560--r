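---
title: "Predictive values and their confidence intervals from nested case-control samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive values and their confidence intervals from nested case-control samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nccpv)
```

## The design and the estimand

A diagnostic accuracy study classifies every subject by true disease status
(reference test) and by the index test under evaluation, giving the familiar
2x2 table with cells $a$ (true positive), $b$ (false positive), $c$ (false
negative) and $d$ (true negative). The clinically decisive quantities are
the post-test probabilities
$$\mathrm{PPV} = \frac{a}{a+b}, \qquad \mathrm{NPV} = \frac{d}{c+d}.$$

When the index test is expensive — a biomarker assayed on frozen biobank
material, say — it is often measured only in a *nested case-control
sample*: all $a+c$ cases, plus a random subset of the controls, $b_1$
test-positive and $d_1$ test-negative. Because the cohort is fully
enumerated, the *sampling fraction* $sf = (b_1+d_1)/(b+d)$ is known, and
absolute probabilities remain estimable by weighting the sampled controls
back to cohort scale:
$$\widehat{\mathrm{PPV}} = \frac{a}{a + b_1/sf}, \qquad
  \widehat{\mathrm{NPV}} = \frac{d_1/sf}{c + d_1/sf}.$$
At $sf = 1$ these reduce to the cohort proportions. `nccpv` computes PPV and
NPV through one shared code path (swapping the roles of the case and
control cells) so the two targets cannot drift apart algebraically.

The estimand is a probability, but the *effective* information is the
number of subjects actually tested, $N_1 = a + c + b_1 + d_1$, not the
weighted pseudo-count. That tension is exactly why the interval estimators
below differ.

## The six interval estimators

All six center on the same weighted point estimate; they differ only in the
uncertainty assessment. Writing $z$ for the standard-normal quantile at
$(1+\gamma)/2$ (confidence level $\gamma$, default 0.95, never a hard-coded
1.96):

1. **Naive Wald.** $SE = \sqrt{p_{obs}(1-p_{obs})/n_{obs}}$ with the
   *unweighted* observed proportion $p_{obs} = a/(a+b_1)$ and observed
   denominator $n_{obs} = a+b_1$. The interval is centered on the corrected
   point estimate: the six approaches share their point estimate by
   construction, and only the SE ignores the weighting. On the probability
   scale, truncated to $[0,1]$ and flagged when truncation bites.
2. **Corrected Wald.** Same denominator, but the corrected predictive value
   $P$ inside the variance: $SE = \sqrt{P(1-P)/n_{obs}}$. Correcting the
   denominator as well would pretend the unobserved controls were measured.
3. **Stratified percentile bootstrap.** Cases are resampled with
   replacement among cases, sampled controls among sampled controls, with
   the stratum sizes and the sampling fraction held at their design values
   (the design fixes both margins; joint resampling would perturb $sf$).
   The corrected estimate is recomputed per resample and the empirical
   $(1\pm\gamma)/2$ quantiles form the interval. Quantiles use linear
   interpolation between order statistics (R's default type 7) — the
   convention is a free choice and is fixed and documented here. Resamples
   with an empty weighted denominator are continuity-corrected within that
   resample and tallied in the `boot_degenerate` diagnostic.
4. **Delta method from Se/Sp/prevalence.** With
   $\mathrm{PPV} = Se\,p / D$, $D = Se\,p + (1-Sp)(1-p)$, first-order
   propagation of the two independent binomial variances gives
   $$\mathrm{Var}(\mathrm{PPV}) = \frac{p^2(1-p)^2\left[(1-Sp)^2
   \frac{Se(1-Se)}{a+c} + Se^2 \frac{Sp(1-Sp)}{b_1+d_1}\right]}{D^4},$$
   and the NPV analogue with $E = Sp(1-p) + (1-Se)p$. The prevalence is
   treated as known (it comes from the enumerated cohort), so it
   contributes no variance term. Each squared partial-derivative factor
   carries its square; the implementation is cross-checked in the tests by
   numerical differentiation of the Bayes formula.
5. **Weighted logistic regression** (next section). The Wald interval is
   formed on the logit scale and back-transformed — the construction that
   uses $SE(\mathrm{logit\,PPV})$ directly and keeps the bounds inside
   $(0,1)$.
6. **Delta method on the logit scale.**
   $\mathrm{Var}(\mathrm{logit\,PPV}) = \frac{1-Se}{Se\,(a+c)} +
   \frac{Sp}{(1-Sp)(b_1+d_1)}$, with the NPV analogue obtained by
   $Se \leftrightarrow$ its complement role; interval built on the logit
   scale and back-transformed.

With the cohort-implied prevalence $p = (a+c)/N$, the Bayes representation
in approaches 4 and 6 is an algebraic rearrangement of the weighted
estimator, which is why all six point estimates coincide exactly.

Approaches 5 and 6 both produce a logit-scale SE, but they are *not* the
same variance: approach 6 conditions on the prevalence and treats Se and Sp
as independent binomials, while approach 5's variance is the inverse
information of the weighted saturated logit (at $sf=1$:
$1/a + 1/b_1$ versus $c/(a(a+c)) + d_1/(b_1(b_1+d_1))$). The package
deliberately tests each against its own closed form rather than against
each other.

## The weighted logistic model

Approach 5 fits $\operatorname{logit} P(D=1) = \alpha + \beta x$, $x = 1$
for a positive index test, by maximum likelihood with per-subject weights
$$w_{case} = \frac{N_1}{N}, \qquad w_{control} = \frac{N_1}{N}\cdot\frac{1}{sf},$$
which sum to $N_1$ over the sample: the weighted cell totals sit on cohort
scale up to a common factor, while the Fisher information carries the
effective sample size actually observed. The fit operates on the grouped
2x2 representation (four weighted binomial cells, two covariate patterns) —
the likelihood is identical to per-subject rows at $O(1)$ cost per
iteration.

Numerics: damped Newton iteration, starting from $\alpha$ at the logit of
the weighted test-negative disease proportion and $\beta = 0$. The step is
halved while it worsens the log-likelihood *beyond floating-point noise*
($10^{-12}$ relative); without that allowance the guard can block the final
refinement steps and stall the score at around $10^{-8}$. Convergence is
declared on the score max-norm below $10^{-12} \cdot N_1$ (or a step at the
floating-point floor), never on the log-likelihood change, which near the
optimum is quadratically smaller than the score and would stop the
iteration while the coefficients are still several digits short of the
$10^{-8}$-to-$10^{-10}$ agreement the saturated closed form allows. A zero
cell is reported as a separation error; the opt-in continuity correction
(below) restores identifiability. The covariance is the model-based
(expected-information) covariance; a robust/sandwich variant is out of
scope, and which of the two the original analyses used is not documented —
the model-based choice is stated here as the package's.

Because the model is saturated, the fitted probabilities equal the weighted
empirical proportions exactly; this identity (to $10^{-8}$ over thousands
of random tables) is the module's primary oracle, with `stats::glm`
(binomial family, case weights) as an independent cross-check in the test
suite.

## Degenerate tables and the continuity correction

Empty denominators (no observed test-positives for the PPV, or Se/Sp at 0
or 1 for the delta methods) raise typed errors naming the violated
invariant. Opting in to `continuity_correction` adds 0.5 to each of the
four *nested* counts, with the sampling fraction frozen at its design
value: the correction perturbs counts, not the design. Counts are validated
as integers at the user boundary; continuity-corrected and weighted
intermediates are real-valued internally. Display rounding is two decimals
in the CLI's `--round` option; all internal computation is full precision.

## The simulation engine

`run_coverage_study()` replays the two-stage design of the DVT study the
built-in populations come from:

1. **Source population.** `build_source_population()` turns (prevalence,
   Se, Sp, $N$) into integer cells by rounding in a fixed order — cases =
   `round(p N)`, TP = `round(Se * cases)`, TN = `round(Sp * controls)`,
   remaining cells by subtraction (round-half-even). For the
   prevalence-0.1 D-dimer population this gives 140 cases / 1260 controls
   and cells 136/844/4/416, and the realized accuracy of every built-in
   population reproduces its stated parameters at two decimals. The
   built-in grid (`table1_fixture()`) covers the D-dimer test
   (Se ≈ 0.96–0.97, Sp ≈ 0.32–0.33; positive in ~70% of patients) and the
   calf-difference test (Se ≈ 0.67–0.69, Sp ≈ 0.64–0.65; positive in ~40%)
   at prevalences 0.05, 0.1 and 0.2 with $N = 1400$.
2. **Cohort.** One multinomial draw of size 1400 from the source cells —  a
   cross-sectional cohort drawn with replacement, so the cohort prevalence
   varies binomially around the source value (SD ≈ 0.008 at $p=0.1$).
3. **Nested sample.** All cohort cases, plus `ratio` controls per case
   drawn *without replacement* from the cohort's control pool (the split
   over test results is hypergeometric). Without-replacement sampling is
   standard nested case-control practice; the alternative is not
   distinguishable from the study description and is noted as a design
   choice. Cohorts with zero cases or too few controls for the ratio are
   redrawn with a logged counter, so exactly $B$ usable replicates enter
   every approach.
4. **Estimation and scoring.** Each requested approach builds its interval
   using the realized prevalence of that replicate's cohort; coverage is
   scored against the *source-population* predictive value, and mean
   interval width, mean estimate, degenerate-replicate counts and the
   redraw counter are aggregated.

Per-replicate RNG streams are derived from the root seed up front, so a
replicate's data do not depend on which approaches are requested, and the
whole `CoverageResult` is bit-for-bit reproducible under a fixed seed.

The Monte-Carlo *acceptability interval* for empirical coverage is
$\gamma \pm 2\sqrt{(1-\gamma)\gamma^{*}/B}$ evaluated with the nominal
non-coverage: at $\gamma = 0.95$, $B = 1000$, the SE is 0.0069 and the band
(0.936, 0.964). Coverage below/above it is under-/over-coverage.

### What the generator emulates — and what passing tests do not show

The generator reproduces the *published design*: reconstructed integer
populations from rounded accuracy parameters, two-stage resampling, and
realized-prevalence estimation. It does not emulate features of real data
such as spectrum effects, verification bias, correlated tests, or the
original patient-level measurements (which are not public); coverage
statements are therefore statements about the design, not about any
particular clinical dataset.

One empirical property deserves emphasis, because it constrains what any
estimator conditioned on the observed sample can achieve. Against the
fixed source-population value, the error of the point estimate includes the
cohort-level prevalence draw, whose contribution
($\partial\mathrm{PPV}/\partial p \approx 1.3$ times an SD of ~0.008 at low
prevalence) is comparable to or larger than the within-cohort sampling
error. Approaches whose variance conditions on the realized prevalence
(3, 4 and 6) cannot see that term, and their coverage of the fixed source
value sits well below nominal in this package's simulations (≈0.72–0.75 at
prevalence 0.05–0.1, ratio 1:1, for the D-dimer populations) — consistent
with closed-form delta analysis of the design, while the conservative
approaches (1, 2, 5) over-cover, the under-coverage of approaches 4 and 6
deepens with the case-control ratio, and the prevalence-0.2, ratio-1:4 cell
shows the most severe under-coverage. Simulation studies elsewhere have
reported milder absolute under-coverage for the delta-method estimators at
low prevalence; the difference is attributable to how the truth and the
per-replicate prevalence interact in the design, and the qualitative
ordering of the approaches is the robust finding.

Scale choices: the package's own test suite runs the simulation cells at
$B = 500$ replicates with 500 bootstrap resamples, and the reproduction
script at $B = 1000$; these sizes give Monte-Carlo SEs of ~0.010–0.014 on a
coverage proportion, adequate for the qualitative bands being checked.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `level` | 0.95 | two-sided confidence level; $z$ from `qnorm((1+level)/2)` |
| `bootstrap_reps` | 1000 | bootstrap resamples (approach 3) |
| `continuity_correction` | off | +0.5 on the four nested counts when a cell is empty |
| `replicates` | 1000 | simulated cohorts per design cell |
| `ratio` | 1 | controls sampled per case (1:1 … 1:4 in the study grid) |
| `population_size` | 1400 | source population and cohort size |
| `tol` (GLM) | 1e-12 | score max-norm per unit weight at convergence |

## Known limitations

* Matched or stratified control sampling, multiple covariates in the
  weighted model, and sandwich variances are out of scope.
* Exact (Clopper-Pearson), Wilson and Bayesian intervals are deliberately
  not provided; the six approaches above are the package's scope.
* The diagnostic odds ratio of the built-in populations is not exposed: it
  is not reconstructible from the rounded published accuracy parameters.
* Wald intervals on the probability scale (approaches 1, 2, 4) may require
  truncation at the unit interval; truncation is flagged, not hidden.
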