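test_that("Rubin pooling reproduces the hand-worked example", {
  pool <- rubin_pool(c(0.10, 0.12), c(0.001, 0.001))
  expect_equal(pool$q_bar, 0.11)
  expect_equal(pool$within_var, 0.001)
  expect_equal(pool$between_var, 0.0002, tolerance = 1e-12)
  expect_equal(pool$total_var, 0.0013, tolerance = 1e-12)
  expect_equal(pool$df, (2 - 1) * (1 + 0.001 / (1.5 * 0.0002))^2)
  expect_error(rubin_pool(0.1, 0.001), "m >= 2")
})

test_that("Rubin pooling handles degenerate variance components", {
  # identical estimates: no between variance, normal quantile, T = W
  p0 <- rubin_pool(rep(0.2, 5), rep(4e-4, 5))
  expect_equal(p0$between_var, 0)
  expect_equal(p0$total_var, p0$within_var)
  expect_equal(p0$df, Inf)
  expect_equal(p0$ci_high - p0$ci_low, 2 * qnorm(0.975) * sqrt(4e-4),
               tolerance = 1e-10)
  # zero within-variance: T is exactly (1 + 1/m) B
  est <- c(0.1, 0.15, 0.2)
  p1 <- rubin_pool(est, rep(0, 3))
  expect_equal(p1$total_var, (1 + 1 / 3) * var(est), tolerance = 1e-12)
})

test_that("intercept-only imputation model recovers observed frequencies", {
  cfg <- navarra_config("6-9", n_children = 4000L, seed = 91L)
  co <- simulate_cohort(cfg)
  model <- fit_imputation_model(co, predictors = "sex", decay = 0)
  # score a single boy and girl: probabilities should match the measured
  # children's category frequencies by sex
  for (s in c("boy", "girl")) {
    sel <- co$measured & co$sex == s
    freq <- as.numeric(table(co$status_follow[sel])) / sum(sel)
    X <- stats::model.matrix(model$terms,
                             data.frame(sex = factor(s, c("boy", "girl"))))
    probs <- ehrprev:::.multinom_probs(model$coefficients, X, model$categories)
    probs <- probs[, levels(co$status_follow)]
    expect_equal(as.numeric(probs), freq, tolerance = 2e-3)
  }
})

test_that("the imputation model recovers known multinomial coefficients", {
  cfg <- navarra_config("6-9", n_children = 50000L, seed = 101L)
  co <- simulate_cohort(cfg)
  model <- fit_imputation_model(co, predictors = c("sex", "status_base"))
  # oracle: an independent multinomial fit on the same measured children must
  # agree with the packaged coefficient vector (same likelihood optimum)
  dat <- co[co$measured, ]
  dat$status_follow <- stats::relevel(dat$status_follow, "normal")
  ref <- nnet::multinom(status_follow ~ sex + status_base, dat, trace = FALSE,
                        maxit = 500, decay = 0.01, Hess = FALSE)
  expect_equal(unname(model$coefficients),
               unname(ehrprev:::.multinom_stack(coef(ref))), tolerance = 1e-4)
  # and a well-populated association is recovered within its Wald CI:
  # girls vs boys should carry a near-zero log OR for obesity
  se <- sqrt(diag(model$covariance))
  b <- model$coefficients["obese:sexgirl"]
  expect_lt(abs(b), 3 * se["obese:sexgirl"] + 0.05)
})

test_that("empty outcome categories and separation are reported", {
  co <- toy_stratified_cohort() # only normal and obese observed
  expect_error(fit_imputation_model(co, predictors = "residence"),
               "category empty")
})

test_that("with no missing data all imputations are identical and B = 0", {
  cfg <- navarra_config("6-9", n_children = 1500L, seed = 111L)
  co <- generate_cohort(cfg) # fully measured
  model <- fit_imputation_model(co)
  imps <- draw_imputations(model, co, m = 4L, seed = 5L)
  for (t in 2:4) {
    expect_identical(imps$completed_status[[t]], imps$completed_status[[1]])
  }
  ests <- vapply(imps$per_imputation_estimates,
                 function(e) e$estimate[e$category == "obese"], numeric(1))
  expect_equal(var(ests), 0)
  mi <- prevalence_mi(co, m = 4L, seed = 5L)
  cc <- prevalence_complete_case(co)
  expect_equal(mi$estimate, cc$estimate, tolerance = 1e-12)
})

test_that("imputations only vary in the originally missing slots", {
  cfg <- navarra_config("6-9", n_children = 3000L, seed = 121L)
  co <- simulate_cohort(cfg)
  model <- fit_imputation_model(co)
  imps <- draw_imputations(model, co, m = 3L, seed = 7L)
  obs <- which(co$measured)
  for (t in 1:3) {
    expect_identical(imps$completed_status[[t]][obs], co$status_follow[obs])
    expect_false(anyNA(imps$completed_status[[t]]))
  }
  expect_identical(draw_imputations(model, co, m = 3L, seed = 7L)$completed_status,
                   imps$completed_status)
})

test_that("pooled MI prevalence tracks the generator truth on MAR cohorts", {
  cfg <- bias_scenario_config(n_children = 30000L, seed = 131L)
  co <- simulate_cohort(cfg)
  truth <- true_follow_prevalence(cfg)[["obese"]]
  mi <- prevalence_mi(co, m = 10L, seed = 8L)
  row <- mi[mi$category == "obese", ]
  expect_lt(abs(row$estimate - truth), 3 * sqrt(row$variance))
  expect_equal(sum(mi$estimate), 1, tolerance = 1e-9)
  # complete case misses by the designed margin on the same cohort
  cc <- prevalence_complete_case(co)
  expect_gt(abs(cc$estimate[cc$category == "obese"] - truth), 0.015)
})

test_that("fixed coefficients reduce between-imputation noise to sampling only", {
  cfg <- navarra_config("6-9", n_children = 8000L, seed = 141L)
  co <- simulate_cohort(cfg)
  model <- fit_imputation_model(co)
  model$covariance <- model$covariance * 0 # freeze the coefficients
  imps <- draw_imputations(model, co, m = 40L, seed = 9L)
  ests <- vapply(imps$per_imputation_estimates,
                 function(e) e$estimate[e$category == "obese"], numeric(1))
  n_miss <- sum(!co$measured)
  # between-imputation variance of the prevalence is binomial draw noise of
  # the imputed slots alone: p_miss*(1-p_miss)*n_miss / n^2, bounded loosely
  p_imp <- mean(ests)
  upper <- 3 * p_imp * n_miss / nrow(co)^2 # generous bound ~ p(1-p) n_m / n^2
  expect_lt(var(ests), upper)
})
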