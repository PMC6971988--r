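test_that("configuration validation rejects non-probability inputs", {
  expect_error(cohort_config(10, 0.5, 0.5, c(0.3, 0.3, 0.3, 0.3),
                             rep(0.25, 4)), "summing to 1")
  expect_error(cohort_config(10, 1.5, 0.5, rep(0.25, 4), rep(0.25, 4)),
               "probability")
  expect_error(cohort_config(10, 0.5, 0.5, rep(0.25, 4), rep(0.25, 4),
                             z_correlation = 1.2), "z_correlation")
  expect_error(cohort_config(10, 0.5, 0.5, rep(0.25, 4), rep(0.25, 4),
                             missingness_log_ors = c(nope = 1)), "unknown")
})

test_that("generation is deterministic given the seed", {
  cfg <- navarra_config("6-9", n_children = 500L, seed = 42L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- navarra_config("6-9", n_children = 500L, seed = 43L)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("baseline status is exactly consistent with z_base and ages stay in window", {
  cfg <- navarra_config("10-14", n_children = 3000L, seed = 3L)
  co <- generate_cohort(cfg)
  expect_identical(co$status_base, classify_weight_status(co$z_base, "young"))
  expect_true(all(abs(co$z_base) < 5) && all(abs(co$z_follow) < 5.2))
  expect_true(all(co$age_years >= 10 & co$age_years <= 14))
})

test_that("covariate and baseline-status marginals match the configuration", {
  n <- 100000L
  cfg <- navarra_config("6-9", n_children = n, seed = 5L)
  co <- generate_cohort(cfg)
  # ten margins are checked simultaneously, so the per-margin bound is set
  # at 3.5 SE to keep the family-wise tolerance near the 3-SE spirit
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(co$sex == "girl") - cfg$p_girl), 3.5 * se(cfg$p_girl))
  expect_lt(abs(mean(co$residence == "urban") - cfg$p_urban),
            3.5 * se(cfg$p_urban))
  inc <- as.numeric(table(co$income)) / n
  stat <- as.numeric(table(co$status_base)) / n
  for (k in 1:4) {
    expect_lt(abs(inc[k] - cfg$income_probs[k]), 3.5 * se(cfg$income_probs[k]))
    expect_lt(abs(stat[k] - cfg$baseline_status_probs[k]),
              3.5 * se(cfg$baseline_status_probs[k]))
  }
  expect_gt(chisq.test(table(co$income), p = cfg$income_probs)$p.value, 1e-4)
})

test_that("perfect correlation reproduces the baseline z exactly", {
  cfg <- navarra_config("6-9", n_children = 1000L, z_correlation = 1, seed = 2L)
  co <- generate_cohort(cfg)
  expect_equal(co$z_follow, co$z_base)
  # identical z means the follow-up category boundaries fall at the same z
  expect_identical(as.integer(co$status_follow), as.integer(co$status_base))
})

test_that("missingness intercept calibration hits the target rate", {
  n <- 100000L
  cfg <- navarra_config("6-9", n_children = n, seed = 9L)
  co <- generate_cohort(cfg)
  # intercept-only: every child has the same probability
  co0 <- apply_missingness(co, numeric(0), 0.951, seed = 10L)
  expect_lt(abs(mean(co0$measured) - 0.951),
            3 * sqrt(0.951 * 0.049 / n))
  # covariate-dependent: marginal rate still calibrated (within 1e-3 of the
  # target at this n, combining calibration and binomial noise)
  co1 <- apply_missingness(co, cfg$missingness_log_ors, 0.951, seed = 10L)
  expect_lt(abs(mean(co1$measured) - 0.951), 1e-3)
  # unmeasured children carry no follow-up data
  expect_true(all(is.na(co1$z_follow[!co1$measured])))
  expect_true(all(!is.na(co1$z_follow[co1$measured])))
})

test_that("boundary target rates behave as specified", {
  cfg <- navarra_config("6-9", n_children = 200L, seed = 1L)
  co <- generate_cohort(cfg)
  all_meas <- apply_missingness(co, numeric(0), 1.0, seed = 1L)
  expect_true(all(all_meas$measured))
  expect_error(apply_missingness(co, cfg$missingness_log_ors, 1.0, seed = 1L),
               "cannot be calibrated")
})

test_that("the analytic follow-up prevalence matches closed forms at the correlation extremes", {
  cfg0 <- navarra_config("6-9", z_correlation = 0)
  # rho = 0: follow-up z is standard normal regardless of baseline
  expect_equal(unname(true_follow_prevalence(cfg0)),
               c(pnorm(-2), pnorm(1) - pnorm(-2), pnorm(2) - pnorm(1),
                 pnorm(2, lower.tail = FALSE)),
               tolerance = 1e-8)
  # rho = 1: the follow-up category distribution is the baseline one
  cfg1 <- navarra_config("6-9", z_correlation = 1)
  expect_equal(unname(true_follow_prevalence(cfg1)),
               unname(cfg1$baseline_status_probs), tolerance = 1e-8)
  expect_equal(sum(true_follow_prevalence(navarra_config("10-14"))), 1,
               tolerance = 1e-10)
})

test_that("the analytic prevalence agrees with a large simulated cohort", {
  n <- 200000L
  cfg <- navarra_config("6-9", n_children = n, seed = 21L)
  co <- generate_cohort(cfg)
  truth <- true_follow_prevalence(cfg)
  emp <- as.numeric(table(co$status_follow)) / n
  for (k in 1:4) {
    expect_lt(abs(emp[k] - truth[k]), 3 * sqrt(truth[k] * (1 - truth[k]) / n))
  }
})
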