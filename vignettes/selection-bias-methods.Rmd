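---
title: "Evaluating selection bias in EHR-based child weight-status prevalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating selection bias in EHR-based child weight-status prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrprev)
```

## The problem

Primary-care electronic health records (EHRs) capture children's height and
weight opportunistically: measurements accumulate at scheduled well-child
visits and at whatever other visits happen to occur. When weight-status
prevalence (underweight / normal / overweight / obese) is estimated from
these records, children without a usable measurement are simply absent from
the estimate. If the probability of being measured depends on
characteristics that are themselves associated with weight status — household
income, sex, residence, or the child's own earlier weight status — the
complete-case estimate is selection-biased.

`ehrprev` implements the standard toolkit for quantifying and correcting this
bias on a single pediatric cohort:

1. a **logistic missingness model** for the measured/not-measured indicator,
   reported as adjusted odds ratios with Wald intervals;
2. **stabilized inverse-probability weights** (IPW),
   $SW_i = \hat f(\text{measured}) / \hat f(\text{measured}\mid x_i)$, applied
   to measured children with a linearized ("robust", weights-as-fixed)
   variance for the weighted prevalence;
3. **multiple imputation** (MI) of the missing four-level status from the
   same predictors, pooled by Rubin's rules; and
4. a **synthetic cohort generator** whose covariate marginals, baseline
   weight-status distribution, missingness odds ratios and marginal measured
   rates are calibrated to a published regional cohort of 10,811 children,
   so that all three estimators can be compared against a known estimand.

Because individual-level records from the original cohort are not publicly
available, the generator is the package's test bed: it reproduces the
*statistical structure* the analysis assumes, not any real child's data.

## Data model

One row per child: sex (boy/girl), residence (rural/urban), annual household
income in four ordinal bands (basic assistance, <18k, 18k–<100k, ≥100k
euros), a baseline BMI z-score `z_base` measured at ages 2–5 with its
four-category classification (`at_risk_overweight` / `overweight_obese`
labels in the young scheme), a follow-up age (6–9 or 10–14 years), a
`measured` flag, and — if measured — a follow-up z-score `z_follow` with its
older-scheme classification (`overweight` / `obese`). The cutoffs are the
usual growth-standard ones: underweight below −2 SD, normal from −2 to +1 SD
(both boundaries included), then +1 to +2 SD and above +2 SD. Exactly +1 is
normal and exactly +2 is the middle category; only strictly greater values
cross each boundary.

BMI z-scores come from the LMS parameterization,
$z = ((x/M)^L - 1)/(LS)$ with the $L \to 0$ limit $\log(x/M)/S$ (switched at
$|L| < 10^{-8}$). The package ships a small **synthetic** LMS table for
examples and tests; it is constructed, with analytic round-trip checks, and
is *not* a copy of any growth-standard release. Users with real data should
supply their reference table via `read_lms_reference()`.

Records with $|z| \ge 5$ are removed by `filter_implausible()` before any
estimation, the usual plausibility screen for EHR anthropometrics (the
screen is symmetric: at or beyond 5 SD in either direction).

## The synthetic cohort generator

`navarra_config()` encodes the published cohort's structure as the default
study conditions:

* marginals: 5313/10,811 girls, 4364/10,811 urban, income counts
  510/4657/5546/97 (renormalized; the published income column is one child
  short of the cohort total), baseline status counts 78/7628/2291/814;
* measurement odds ratios per age group (e.g. at 6–9 years: basic income
  0.40, income 18k–<100k 1.70, girls 1.18, urban 0.79, baseline at-risk
  1.29) with marginal measured rates 95.1% (6–9) and 88.9% (10–14).

Generation is category-first: each child's baseline category is drawn from
the configured four-vector, then `z_base` is drawn uniformly on the normal
quantile interval of that category (a truncated standard normal), so the
category label and the z-score are consistent by construction. Tails are
truncated at $|z| = 4.99$ so every generated record survives the
plausibility screen. The follow-up z-score is
$z_{f} = \rho\, z_{b} + \sqrt{1-\rho^2}\,\varepsilon$ with standard-normal
noise. The baseline–follow-up correlation $\rho$ is not reported for the
original cohort; the default $\rho = 0.6$ is a moderate BMI-tracking value
chosen once as the simulation condition, not a published quantity.

Missingness is applied as an inverted logistic model:
$P(\text{measured}_i) = \operatorname{expit}(\beta_0 + \sum \log OR \cdot
x_i)$, with $\beta_0$ calibrated by monotone root finding on $[-20, 20]$ so
the mean measurement probability equals the target rate to within $10^{-6}$
(the expit is monotone in $\beta_0$, so the root is unique). By default the
mechanism depends only on the four observed covariates — missing at random
(MAR) given covariates, which is exactly the assumption IPW and MI need. An
optional `mnar_log_ors` term adds dependence on the *latent follow-up
status*, producing a missing-not-at-random mechanism for negative-control
experiments.

`true_follow_prevalence()` computes the generator's super-population
category distribution by numerical integration over the truncated-normal
mixture — the estimand ("generator truth") for all bias and coverage
experiments, independent of any simulation.

What the generator does **not** emulate: longitudinal growth trajectories
(one follow-up slot per analysis window), household clustering, migration,
secular BMI drift with age, and measurement error in height/weight. Passing
tests therefore show that the estimators behave correctly under the assumed
missingness structure, not that any particular real EHR satisfies that
structure.

## Estimators

All three estimators share one multinomial indicator construction, so the
four category estimates of each method sum to one by construction.

**Complete case.** Category proportions among measured children, variance
$p(1-p)/(n-1)$. The $n/(n-1)$ finite-sample factor is applied throughout so
the IPW variance reduces *exactly* to the complete-case form under equal
weights.

**Stabilized IPW.** The numerator is the unconditional empirical measured
proportion (taken directly from the data, not from a model); the denominator
is the fitted conditional probability from the logistic missingness model
with reference levels boy, normal weight, income <18k, rural — the layout of
the published odds-ratio tables. Weighted prevalence
$\hat p = \sum w_i y_i / \sum w_i$ carries the linearized variance
$\frac{n}{n-1}\sum w_i^2 (y_i - \hat p)^2 / (\sum w_i)^2$, which treats the
weights as fixed (the convention of survey-style `pweight` analyses; no
correction for weight-estimation uncertainty is attempted, and in practice
this makes the intervals mildly conservative — see the coverage experiment
below). Weights are not truncated by default; a fitted measurement
probability below $10^{-6}$ raises a positivity error rather than silently
producing an extreme weight.

**Multiple imputation.** A multinomial logistic model of the observed
follow-up status on the same four predictors (baseline category: normal
weight), then proper imputation: for each of $m$ imputations a coefficient
vector is drawn from $\mathcal N(\hat\beta, \hat V)$ and each missing child's
category is sampled at the drawn coefficients. This approximates the usual
MCMC-based MI of a single categorical variable without needing chains; with
one target variable the posterior-draw scheme is the standard "proper"
shortcut. $m = 10$ by default. Pooling follows Rubin's rules:
$\bar q$, $T = W + (1 + 1/m)B$, the classic large-sample degrees of freedom
$(m-1)(1 + W/((1+1/m)B))^2$ (no small-sample correction — cohort sizes here
dwarf $m$), and a $t$ interval clamped to $[0,1]$.

With four sparse outcome categories, some outcome-by-predictor cells are
routinely empty (e.g. no obese follow-up among the ~80 baseline-underweight
children), which drives the unpenalized multinomial MLE to infinity. The
imputation model therefore applies a small ridge penalty (`decay = 0.01`)
by default; at cohort sizes in the thousands its effect on well-populated
cells is negligible, while empty cells get large-but-finite log-odds and a
well-conditioned covariance. `decay = 0` requests the raw MLE, which errors
on separation.

**Confidence intervals** for complete-case and IPW prevalences are Wald on
the logit scale, back-transformed — they respect $(0,1)$ and match the
convention of survey packages; a plain Wald interval is available via
`ci_method = "wald"`. Degenerate estimates of exactly 0 or 1 are reported
with collapsed intervals. The original analysis does not state its CI
method; this is the package's own choice.

**Age standardization.** `prevalence_age_adjusted()` implements direct
standardization, $p_{adj} = \sum_a \pi_a \hat p_a$ with variance
$\sum_a \pi_a^2 v_a$. How the original "age-adjusted" figures were computed
is not stated; direct standardization over the full cohort's age
distribution (measured plus unmeasured) is the natural internal standard and
is the default recommendation.

## Experimental design of the test suite

The acceptance-level experiments fix their problem sizes as the package's
study conditions:

* **Parameter recovery**: one cohort of n = 50,000; every generator odds
  ratio must fall inside its fitted 95% Wald interval.
* **Bias correction**: 200 replicates of n = 5,000 under a status-dependent
  MAR mechanism ($\rho = 0.85$; baseline overweight/obese measurement OR
  0.05, at-risk OR 0.20; marginal rate 0.80). These conditions were designed
  to give the complete-case estimator a bias above 2 percentage points in
  obesity prevalence; IPW and MI must land within 3 Monte-Carlo standard
  errors of the analytic truth, and IPW must remove at least 80% of the
  induced bias.
* **Concordance**: at the published size n = 10,811 under the published
  odds-ratio calibration, the three obesity estimates agree within 1.5
  percentage points — the qualitative finding that motivated the original
  comparison (under its mild, partially offsetting selection forces, the
  complete-case estimate is already close).
* **Negative control**: 60 replicates of n = 5,000 under MNAR (measurement
  odds depending on the latent follow-up status, OR 0.08 for obese). All
  three estimators stay biased by design; this documents that IPW/MI correct
  only what the observed covariates can explain.
* **Interval coverage**: 500 replicates of n = 5,000 under the published MAR
  calibration; the IPW logit-Wald interval for obesity prevalence must cover
  the analytic truth 93–97% of the time. (Under the stronger
  status-dependent scenario coverage is conservative, ≈97%, the expected
  consequence of treating estimated weights as fixed.)

Two reproducibility caveats discovered while wiring the published tables
into fixtures: the coverage table's 12-year one-year cell prints 30.4% where
its own counts give 1978/6518 = 30.3%, and two measured/not-measured
percentage cells are typographically inconsistent with their counts; the
package works from the counts, which are internally consistent.

## Numerical choices and degenerate inputs

* z within a baseline category: truncated-normal draw via the uniform
  quantile interval — exact category consistency with a continuous z.
* Intercept calibration: `uniroot` on $[-20, 20]$, tolerance $10^{-9}$;
  boundary target rates (0 or 1) are honored exactly when all log odds
  ratios are zero and rejected as infeasible otherwise.
* Separation in the missingness model (a covariate level with only one
  outcome) raises an error naming the coefficient rather than returning
  explosive odds ratios.
* Tie-breaking at category boundaries follows the published wording:
  intervals are closed where the text says "≥/≤" and open where it says
  strict inequality.
* Empty cohorts, all-measured cohorts (the three estimators then coincide by
  construction and no model is fitted), and header-only CSV files are all
  legal inputs with defined behavior.

## Limitations

The package evaluates estimators under an assumed missingness model; it
cannot verify MAR on real data (no statistical method can). The MI
implementation imputes the categorical status directly — if the scientific
target were the continuous z-score distribution, a continuous imputation
model would be preferable. The linearized IPW variance ignores
weight-estimation uncertainty, which is conservative for prevalence but not
universally so for other functionals. And the generator's independence
assumptions (covariates drawn independently of each other) mean interactions
between, say, income and residence are absent from the test bed.
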