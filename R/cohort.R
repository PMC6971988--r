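# Internal label sets shared across the package.
.sex_levels <- c("boy", "girl")
.residence_levels <- c("rural", "urban")
.income_levels <- c("basic", "lt_18k", "18k_to_100k", "ge_100k")
# z intervals of the four categories, truncated at |z| = 4.99 so every
# generated record survives the plausibility filter.
.category_bounds <- cbind(lower = c(-4.99, -2, 1, 2),
                          upper = c(-2, 1, 2, 4.99))

#' Cohort simulation configuration
#'
#' Bundles the marginal covariate distribution, the baseline weight-status
#' distribution, the baseline-to-follow-up z-score correlation and the
#' missingness mechanism of a simulated pediatric cohort.
#'
#' @param n_children Number of children.
#' @param p_girl Probability of being a girl.
#' @param p_urban Probability of urban residence.
#' @param income_probs Probability 4-vector over annual household income
#'   categories (basic, <18k, 18k-<100k, >=100k euros); must sum to 1.
#' @param baseline_status_probs Probability 4-vector over baseline (2-5 y)
#'   weight status (underweight, normal, at-risk, overweight/obese); must sum
#'   to 1.
#' @param z_correlation Correlation between the baseline and follow-up BMI
#'   z-scores, in [-1, 1].
#' @param missingness_log_ors Named numeric vector of log odds ratios for
#'   being measured, one per non-reference covariate level (reference levels:
#'   boy, normal weight, income <18k, rural). Recognised names:
#'   `sex_girl`, `status_underweight`, `status_at_risk`, `status_owob`,
#'   `income_basic`, `income_18k_100k`, `income_ge_100k`, `residence_urban`.
#' @param mnar_log_ors Optional named log odds ratios on the *unobserved*
#'   follow-up status (names among `follow_underweight`, `follow_overweight`,
#'   `follow_obese`), which make the mechanism missing-not-at-random; used for
#'   negative-control experiments. Default `NULL` keeps the mechanism MAR
#'   given the four observed covariates.
#' @param target_measured_rate Marginal probability of being measured to which
#'   the missingness intercept is calibrated.
#' @param age_window Integer vector `c(min, max)` of follow-up ages in years;
#'   each child's age is drawn uniformly on this window.
#' @param seed Integer seed controlling all randomness of the generator.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_children,
                          p_girl,
                          p_urban,
                          income_probs,
                          baseline_status_probs,
                          z_correlation = 0.6,
                          missingness_log_ors = numeric(0),
                          mnar_log_ors = NULL,
                          target_measured_rate = 1,
                          age_window = c(6L, 9L),
                          seed = 1L) {
  stopifnot(length(n_children) == 1L, n_children >= 1)
  .check_prob <- function(p, what) {
    if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
      stop("cohort_config(): ", what, " must be a probability", call. = FALSE)
    }
  }
  .check_prob(p_girl, "p_girl")
  .check_prob(p_urban, "p_urban")
  # tolerate write/read precision loss up to 1e-6, then renormalize so the
  # stored vector is an exact simplex
  .check_simplex <- function(p, what) {
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("cohort_config(): ", what, " must be a probability 4-vector summing to 1",
           call. = FALSE)
    }
    p / sum(p)
  }
  income_probs <- .check_simplex(income_probs, "income_probs")
  baseline_status_probs <- .check_simplex(baseline_status_probs,
                                          "baseline_status_probs")
  if (abs(z_correlation) > 1) {
    stop("cohort_config(): z_correlation must lie in [-1, 1]", call. = FALSE)
  }
  if (target_measured_rate < 0 || target_measured_rate > 1) {
    stop("cohort_config(): target_measured_rate must lie in [0, 1]", call. = FALSE)
  }
  known <- c("sex_girl", "status_underweight", "status_at_risk", "status_owob",
             "income_basic", "income_18k_100k", "income_ge_100k",
             "residence_urban")
  if (length(missingness_log_ors)) {
    bad <- setdiff(names(missingness_log_ors), known)
    if (length(bad)) {
      stop("cohort_config(): unknown missingness_log_ors names: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(mnar_log_ors)) {
    bad <- setdiff(names(mnar_log_ors),
                   c("follow_underweight", "follow_overweight", "follow_obese"))
    if (length(bad)) {
      stop("cohort_config(): unknown mnar_log_ors names: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_children = as.integer(n_children),
                 p_girl = p_girl, p_urban = p_urban,
                 income_probs = income_probs,
                 baseline_status_probs = baseline_status_probs,
                 z_correlation = z_correlation,
                 missingness_log_ors = missingness_log_ors,
                 mnar_log_ors = mnar_log_ors,
                 target_measured_rate = target_measured_rate,
                 age_window = as.integer(age_window),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Navarra-calibrated cohort configuration
#'
#' Returns a [cohort_config()] whose covariate marginals, baseline
#' weight-status distribution, missingness odds ratios and marginal measured
#' rate match the published regional cohort of 10,811 children used to study
#' selection bias in EHR-based prevalence estimation: sex 5498/5313
#' boys/girls, residence 6447/4364 rural/urban, income 510/4657/5546/97,
#' baseline status 78/7628/2291/814, and the age-group-specific adjusted odds
#' ratios of being measured (e.g. basic income OR 0.40 and income 18k-<100k
#' OR 1.70 at 6-9 years) with marginal measured rates 95.1% (6-9 y) and
#' 88.9% (10-14 y).
#'
#' @param age_group `"6-9"` or `"10-14"`.
#' @param n_children Cohort size; defaults to the published 10,811.
#' @param z_correlation Baseline-to-follow-up z-score correlation (a free
#'   simulation parameter; the default 0.6 is a moderate tracking value).
#' @param seed Integer seed.
#' @return A `cohort_config` object.
#' @export
navarra_config <- function(age_group = c("6-9", "10-14"),
                           n_children = 10811L,
                           z_correlation = 0.6,
                           seed = 1L) {
  age_group <- match.arg(age_group)
  income_counts <- c(510, 4657, 5546, 97) # published table; sums to 10,810
  if (age_group == "6-9") {
    log_ors <- log(c(sex_girl = 1.18,
                     status_underweight = 0.52,
                     status_at_risk = 1.29,
                     status_owob = 0.99,
                     income_basic = 0.40,
                     income_18k_100k = 1.70,
                     income_ge_100k = 1.45,
                     residence_urban = 0.79))
    target <- 10278 / 10811
    window <- c(6L, 9L)
  } else {
    log_ors <- log(c(sex_girl = 1.15,
                     status_underweight = 0.53,
                     status_at_risk = 1.14,
                     status_owob = 1.13,
                     income_basic = 0.57,
                     income_18k_100k = 1.38,
                     income_ge_100k = 0.66,
                     residence_urban = 0.99))
    target <- 9610 / 10811
    window <- c(10L, 14L)
  }
  cohort_config(n_children = n_children,
                p_girl = 5313 / 10811,
                p_urban = 4364 / 10811,
                income_probs = income_counts / sum(income_counts),
                baseline_status_probs = c(78, 7628, 2291, 814) / 10811,
                z_correlation = z_correlation,
                missingness_log_ors = log_ors,
                target_measured_rate = target,
                age_window = window,
                seed = seed)
}

#' Generate a synthetic cohort
#'
#' Draws one record per child: covariates independently from the configured
#' marginals; a baseline BMI z-score drawn category-first (the category from
#' `baseline_status_probs`, then z uniform on the normal-quantile interval of
#' that category, i.e. a truncated standard normal), so baseline status is
#' exactly consistent with `z_base`; and a follow-up z-score
#' `z_follow = rho * z_base + sqrt(1 - rho^2) * eps` with standard-normal
#' noise. All children start fully measured; apply
#' [apply_missingness()] to introduce missing follow-up measurements.
#'
#' @param config A [cohort_config()].
#' @return A data frame of child records with columns `child_id`, `sex`,
#'   `residence`, `income`, `z_base`, `status_base`, `age_years`, `measured`,
#'   `z_follow`, `status_follow`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("generate_cohort(): config must be a cohort_config", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_children
  sex <- factor(ifelse(stats::runif(n) < config$p_girl, "girl", "boy"),
                levels = .sex_levels)
  residence <- factor(ifelse(stats::runif(n) < config$p_urban, "urban", "rural"),
                      levels = .residence_levels)
  income <- factor(sample(.income_levels, n, replace = TRUE,
                          prob = config$income_probs),
                   levels = .income_levels)
  cat_idx <- sample.int(4L, n, replace = TRUE,
                        prob = config$baseline_status_probs)
  lo <- stats::pnorm(.category_bounds[cat_idx, "lower"])
  hi <- stats::pnorm(.category_bounds[cat_idx, "upper"])
  z_base <- stats::qnorm(lo + stats::runif(n) * (hi - lo))
  rho <- config$z_correlation
  z_follow <- rho * z_base + sqrt(1 - rho^2) * stats::rnorm(n)
  age <- sample(seq(config$age_window[1], config$age_window[2]), n,
                replace = TRUE)
  data.frame(child_id = sprintf("c%06d", seq_len(n)),
             sex = sex,
             residence = residence,
             income = income,
             z_base = z_base,
             status_base = classify_weight_status(z_base, "young"),
             age_years = as.integer(age),
             measured = TRUE,
             z_follow = z_follow,
             status_follow = classify_weight_status(z_follow, "older"),
             stringsAsFactors = FALSE)
}

# Linear predictor (without intercept) of the measurement model implied by a
# named log-OR vector, evaluated on a cohort. Follow-up-status terms (MNAR)
# use the latent status before masking.
.missingness_lp <- function(cohort, log_ors, mnar_log_ors = NULL) {
  g <- function(nm) if (!is.null(log_ors) && nm %in% names(log_ors)) log_ors[[nm]] else 0
  lp <- rep(0, nrow(cohort))
  lp <- lp + g("sex_girl") * (cohort$sex == "girl")
  lp <- lp + g("status_underweight") * (cohort$status_base == "underweight")
  lp <- lp + g("status_at_risk") * (cohort$status_base == "at_risk_overweight")
  lp <- lp + g("status_owob") * (cohort$status_base == "overweight_obese")
  lp <- lp + g("income_basic") * (cohort$income == "basic")
  lp <- lp + g("income_18k_100k") * (cohort$income == "18k_to_100k")
  lp <- lp + g("income_ge_100k") * (cohort$income == "ge_100k")
  lp <- lp + g("residence_urban") * (cohort$residence == "urban")
  if (!is.null(mnar_log_ors)) {
    h <- function(nm) if (nm %in% names(mnar_log_ors)) mnar_log_ors[[nm]] else 0
    lp <- lp + h("follow_underweight") * (cohort$status_follow == "underweight")
    lp <- lp + h("follow_overweight") * (cohort$status_follow == "overweight")
    lp <- lp + h("follow_obese") * (cohort$status_follow == "obese")
  }
  lp
}

#' Apply a covariate-dependent missingness mechanism
#'
#' Sets each child's `measured` flag by a Bernoulli draw with
#' `P(measured) = plogis(beta0 + lp_i)`, where `lp_i` accumulates the
#' configured log odds ratios over the child's covariate levels (and, if MNAR
#' terms are present, over the latent follow-up status). The intercept
#' `beta0` is calibrated by root finding so the mean measurement probability
#' equals `target_measured_rate` to within 1e-6. Unmeasured children have
#' `z_follow` and `status_follow` set to `NA`.
#'
#' @param cohort Data frame from [generate_cohort()] (with `z_follow` intact).
#' @param log_ors Named log-OR vector (see [cohort_config()]).
#' @param target_measured_rate Marginal measurement probability.
#' @param seed Integer seed for the Bernoulli draws.
#' @param mnar_log_ors Optional log ORs on the latent follow-up status.
#' @return The cohort with `measured`, `z_follow`, `status_follow` updated.
#' @export
apply_missingness <- function(cohort, log_ors = numeric(0),
                              target_measured_rate = 1,
                              seed = 1L,
                              mnar_log_ors = NULL) {
  lp <- .missingness_lp(cohort, log_ors, mnar_log_ors)
  boundary <- target_measured_rate <= 0 || target_measured_rate >= 1
  if (boundary && any(lp != 0)) {
    stop("apply_missingness(): target rate 0 or 1 cannot be calibrated with ",
         "non-zero log odds ratios", call. = FALSE)
  }
  if (boundary) {
    p <- rep(target_measured_rate, nrow(cohort))
  } else {
    f <- function(b0) mean(stats::plogis(b0 + lp)) - target_measured_rate
    b0 <- stats::uniroot(f, c(-20, 20), tol = 1e-9)$root
    p <- stats::plogis(b0 + lp)
  }
  set.seed(seed)
  cohort$measured <- stats::runif(nrow(cohort)) < p
  cohort$z_follow[!cohort$measured] <- NA_real_
  cohort$status_follow[!cohort$measured] <- NA
  cohort
}

#' Simulate a cohort with missingness in one call
#'
#' Convenience wrapper: [generate_cohort()] followed by [apply_missingness()]
#' with the mechanism stored in the configuration. Randomness is controlled
#' entirely by `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Cohort data frame with measured flags set.
#' @export
simulate_cohort <- function(config) {
  cohort <- generate_cohort(config)
  apply_missingness(cohort, config$missingness_log_ors,
                    config$target_measured_rate,
                    seed = config$seed + 1L,
                    mnar_log_ors = config$mnar_log_ors)
}

#' True follow-up category prevalence implied by a configuration
#'
#' The super-population distribution of the follow-up weight status under a
#' configuration, computed by numerical integration (no simulation): baseline
#' z is a mixture of truncated standard normals over the four categories, and
#' conditional on `z_base = z` the follow-up z-score is normal with mean
#' `rho * z` and SD `sqrt(1 - rho^2)`. Serves as the estimand ("generator
#' truth") in bias and coverage experiments.
#'
#' @param config A [cohort_config()].
#' @return Named numeric vector of the four older-scheme category
#'   probabilities (sums to 1).
#' @export
true_follow_prevalence <- function(config) {
  rho <- config$z_correlation
  sd_eps <- sqrt(1 - rho^2)
  cuts <- c(-Inf, -2, 1, 2, Inf)
  p_upper_given_z <- function(z, cut) {
    if (sd_eps == 0) as.numeric(rho * z > cut)
    else stats::pnorm((cut - rho * z) / sd_eps, lower.tail = FALSE)
  }
  # P(z_follow > cut) marginally, mixing over the truncated-normal categories
  p_upper <- function(cut) {
    tot <- 0
    for (k in 1:4) {
      a <- .category_bounds[k, "lower"]; b <- .category_bounds[k, "upper"]
      mass <- stats::pnorm(b) - stats::pnorm(a)
      dens <- function(z) stats::dnorm(z) / mass
      tot <- tot + config$baseline_status_probs[k] *
        stats::integrate(function(z) dens(z) * p_upper_given_z(z, cut),
                         a, b, rel.tol = 1e-10)$value
    }
    tot
  }
  up <- vapply(c(-2, 1, 2), p_upper, numeric(1))
  p <- c(underweight = 1 - up[1],
         normal = up[1] - up[2],
         overweight = up[2] - up[3],
         obese = up[3])
  p / sum(p)
}
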