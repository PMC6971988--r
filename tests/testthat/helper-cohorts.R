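# Shared fixture builders. All fixtures are constructed in code.

# Two-stratum toy cohort: 100 rural children (80 measured, 8 of them obese)
# and 100 urban children (60 measured, 30 of them obese). The true
# equal-strata obesity prevalence is (10% + 50%) / 2 = 30%, while the
# complete-case figure is 38/140 = 27.143%.
toy_stratified_cohort <- function() {
  mk <- function(n, residence, measured, obese, offset) {
    z <- ifelse(seq_len(n) <= obese, 2.5, 0) # obese first, then normal
    z[!measured] <- NA
    data.frame(child_id = sprintf("t%03d", offset + seq_len(n)),
               sex = factor("boy", levels = c("boy", "girl")),
               residence = factor(residence, levels = c("rural", "urban")),
               income = factor("lt_18k",
                               levels = c("basic", "lt_18k", "18k_to_100k",
                                          "ge_100k")),
               z_base = 0,
               status_base = classify_weight_status(0, "young"),
               age_years = 7L,
               measured = measured,
               z_follow = z,
               status_follow = classify_weight_status(z, "older"),
               stringsAsFactors = FALSE)
  }
  rbind(mk(100, "rural", c(rep(TRUE, 80), rep(FALSE, 20)), 8, 0),
        mk(100, "urban", c(rep(TRUE, 60), rep(FALSE, 40)), 30, 100))
}

# Cohort realizing a sex-only measured/not-measured 2x2 table.
two_by_two_cohort <- function(boys_meas, boys_not, girls_meas, girls_not) {
  n <- boys_meas + boys_not + girls_meas + girls_not
  sex <- c(rep("boy", boys_meas + boys_not), rep("girl", girls_meas + girls_not))
  measured <- c(rep(TRUE, boys_meas), rep(FALSE, boys_not),
                rep(TRUE, girls_meas), rep(FALSE, girls_not))
  z <- ifelse(measured, 0, NA)
  data.frame(child_id = sprintf("s%06d", seq_len(n)),
             sex = factor(sex, levels = c("boy", "girl")),
             residence = factor("rural", levels = c("rural", "urban")),
             income = factor("lt_18k",
                             levels = c("basic", "lt_18k", "18k_to_100k",
                                        "ge_100k")),
             z_base = 0,
             status_base = classify_weight_status(0, "young"),
             age_years = 7L,
             measured = measured,
             z_follow = z,
             status_follow = classify_weight_status(z, "older"),
             stringsAsFactors = FALSE)
}

# Study conditions of the bias-correction experiment: missingness depends on
# the observed covariates AND the baseline status, baseline status is
# strongly predictive of follow-up status (high tracking correlation), so the
# complete-case estimator carries a designed obesity bias above 2 percentage
# points while IPW/MI (which condition on the baseline status) stay unbiased.
bias_scenario_config <- function(n_children = 5000L, seed = 1L) {
  cfg <- navarra_config("6-9", n_children = n_children,
                        z_correlation = 0.85, seed = seed)
  ors <- cfg$missingness_log_ors
  ors[["status_owob"]] <- log(0.05)
  ors[["status_at_risk"]] <- log(0.20)
  cfg$missingness_log_ors <- ors
  cfg$target_measured_rate <- 0.80
  cfg
}

# Negative-control conditions: missingness depends on the *unobserved*
# follow-up status (MNAR), so no estimator using only the observed
# covariates can remove the bias.
mnar_scenario_config <- function(n_children = 5000L, seed = 1L) {
  cfg <- navarra_config("6-9", n_children = n_children,
                        z_correlation = 0.6, seed = seed)
  cfg$mnar_log_ors <- c(follow_obese = log(0.08),
                        follow_overweight = log(0.4))
  cfg$target_measured_rate <- 0.85
  cfg
}
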