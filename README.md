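# ehrprev

Selection-bias evaluation for child weight-status prevalence estimated from
incomplete electronic health records (EHRs).

## The problem

Children's height and weight accumulate in primary-care EHRs
opportunistically — at scheduled well-child visits and whenever else a child
happens to be measured. Prevalence of underweight, normal weight, overweight
and obesity computed from measured children only (the *complete-case*
estimate) is biased whenever the probability of being measured is associated
with characteristics that also predict weight status: household income, sex,
rural/urban residence, or the child's own earlier weight status.

`ehrprev` implements the comparison of three estimators on one cohort:

* **Complete case** — category proportions among measured children, variance
  `p(1-p)/(n-1)`, logit-scale Wald intervals.
* **Stabilized inverse-probability weighting (IPW)** — a logistic model of
  the measured/not-measured indicator on the four covariates gives each
  measured child the weight

  ```
  SW_i = P(measured) / P(measured | sex_i, baseline status_i, income_i, residence_i)
  ```

  (marginal probability over fitted conditional probability); weighted
  prevalence `sum(w*y)/sum(w)` carries the linearized, weights-as-fixed
  variance `(n/(n-1)) * sum(w^2 (y - p)^2) / (sum w)^2`.
* **Multiple imputation (MI)** — a multinomial logistic model of the
  four-level status on the same predictors; `m = 10` proper imputations
  (coefficients redrawn from their asymptotic normal posterior for every
  imputation) pooled by Rubin's rules, `T = W + (1 + 1/m) B`.

Around these sit the building blocks: LMS growth-standard z-scores
(`z = ((x/M)^L - 1)/(L*S)` with the log-form limit at `L = 0`), the
four-category classification with its two age schemes, the `|z| >= 5`
plausibility screen, a measurement-coverage table builder, direct age
standardization, and CSV/YAML/JSON I/O for cohorts and configurations.

Because the original cohort's individual records are not public, the package
includes a first-class **synthetic cohort generator** calibrated to the
published structure of a regional cohort of 10,811 children (covariate
marginals, baseline status distribution, measurement odds ratios, marginal
measured rates of 95.1% at ages 6–9 and 88.9% at 10–14). The generator's
analytic category distribution (`true_follow_prevalence()`) is the known
estimand against which all three estimators are evaluated, under both MAR
and MNAR missingness mechanisms.

## Worked example

```r
library(ehrprev)

cfg    <- navarra_config("6-9", seed = 2026)  # published calibration, ages 6-9
cohort <- simulate_cohort(cfg)                # 10,811 children, ~95% measured

fit <- fit_missingness(cohort)                # measured/not-measured logistic model
fit$or_table[fit$or_table$level == "basic", c("level", "odds_ratio", "ci_low", "ci_high")]
#>  level odds_ratio ci_low ci_high
#>  basic       0.39   0.29    0.51

stabilized_weights(fit, cohort)
#> Stabilized weights: n = 10265, numerator = 0.9495, mean = 1.0000, SD = 0.0304, range = [0.9598, 1.2233]

run_comparison(cohort, m = 10, seed = 2027)
#>         method    category           prevalence
#>  complete_case underweight    1.66% (1.43-1.92)
#>  complete_case      normal 75.48% (74.64-76.30)
#>  complete_case  overweight 18.35% (17.62-19.11)
#>  complete_case       obese    4.51% (4.13-4.93)
#>            ipw underweight    1.67% (1.43-1.93)
#>            ipw      normal 75.52% (74.68-76.34)
#>            ipw  overweight 18.32% (17.58-19.08)
#>            ipw       obese    4.50% (4.12-4.92)
#>             mi underweight    1.67% (1.41-1.93)
#>             mi      normal 75.51% (74.69-76.33)
#>             mi  overweight 18.32% (17.58-19.06)
#>             mi       obese    4.49% (4.10-4.89)
```

Reading the output: children from basic-income families are measured far
less often (fitted OR 0.39, generator truth 0.40), yet because the
calibrated selection forces partially offset, the three obesity estimates
agree within 0.05 percentage points here — the concordance the method
comparison is designed to detect. Under a missingness mechanism that
strongly tracks baseline weight status the complete-case estimate separates
from IPW/MI by several points while the adjusted estimators stay at the
generator truth; see the vignette (`vignettes/selection-bias-methods.Rmd`)
for those experiments.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ehrprev_cli.R` (subcommands `simulate`, `missingness`,
`prevalence`, `compare`).

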