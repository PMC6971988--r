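# Shared constructor for a four-category prevalence table. Variances use the
# finite-sample factor n/(n-1); confidence intervals are Wald on the logit
# scale, back-transformed (so they stay inside (0,1)), with degenerate
# estimates of 0 or 1 reported with a collapsed interval.
.prevalence_rows <- function(method, categories, est, var, n_eff,
                             ci_method = c("logit", "wald"), level = 0.95) {
  ci_method <- match.arg(ci_method)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  lo <- hi <- numeric(length(est))
  for (k in seq_along(est)) {
    p <- est[k]; v <- var[k]
    if (p <= 0 || p >= 1 || v == 0) {
      lo[k] <- p; hi[k] <- p
    } else if (ci_method == "logit") {
      se_l <- sqrt(v) / (p * (1 - p))
      lo[k] <- stats::plogis(stats::qlogis(p) - zq * se_l)
      hi[k] <- stats::plogis(stats::qlogis(p) + zq * se_l)
    } else {
      lo[k] <- max(0, p - zq * sqrt(v))
      hi[k] <- min(1, p + zq * sqrt(v))
    }
  }
  structure(data.frame(method = method,
                       category = categories,
                       estimate = unname(est),
                       variance = unname(var),
                       ci_low = lo,
                       ci_high = hi,
                       n_effective = n_eff,
                       stringsAsFactors = FALSE),
            class = c("prevalence_estimate", "data.frame"))
}

#' Complete-case prevalence
#'
#' Prevalence of each follow-up weight-status category among measured
#' children only, with variance `p(1-p)/(n-1)` and a logit-scale Wald
#' confidence interval. The four categories are estimated jointly from one
#' multinomial indicator set, so they sum to exactly 1.
#'
#' @param records Cohort data frame; only rows with `measured == TRUE` and a
#'   non-missing `status_follow` enter the estimate.
#' @param ci_method `"logit"` (default) or `"wald"`.
#' @return A `prevalence_estimate` data frame with one row per category.
#' @export
prevalence_complete_case <- function(records, ci_method = "logit") {
  y <- records$status_follow[records$measured & !is.na(records$status_follow)]
  n <- length(y)
  if (n == 0L) stop("prevalence_complete_case(): no measured children", call. = FALSE)
  lv <- levels(records$status_follow)
  p <- as.numeric(table(factor(y, levels = lv))) / n
  v <- if (n > 1) p * (1 - p) / (n - 1) else rep(0, length(p))
  .prevalence_rows("complete_case", lv, p, v, n, ci_method)
}

#' IPW prevalence with linearized variance
#'
#' Weighted prevalence of each follow-up category among measured children,
#' `p_hat = sum(w * y) / sum(w)`, with the linearized (robust, weights-fixed)
#' variance `(n/(n-1)) * sum(w^2 (y - p_hat)^2) / (sum w)^2` and a
#' logit-scale Wald interval. With all weights equal this reproduces the
#' complete-case estimate and its variance exactly.
#'
#' @param records Cohort data frame.
#' @param weights Either an `sw_set` from [stabilized_weights()] or a numeric
#'   vector of weights aligned to the measured children in cohort order.
#' @param ci_method `"logit"` (default) or `"wald"`.
#' @return A `prevalence_estimate` data frame with one row per category.
#' @export
prevalence_ipw <- function(records, weights, ci_method = "logit") {
  idx <- which(records$measured & !is.na(records$status_follow))
  if (inherits(weights, "sw_set")) {
    if (!identical(weights$measured_idx, which(records$measured))) {
      stop("prevalence_ipw(): weights are not aligned to these records",
           call. = FALSE)
    }
    w <- weights$weights[match(idx, weights$measured_idx)]
  } else {
    if (length(weights) != length(idx)) {
      stop("prevalence_ipw(): need one weight per measured child", call. = FALSE)
    }
    w <- as.numeric(weights)
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("prevalence_ipw(): weights must be positive and finite", call. = FALSE)
  }
  sw <- sum(w)
  if (sw == 0) stop("prevalence_ipw(): weights sum to zero", call. = FALSE)
  y <- records$status_follow[idx]
  lv <- levels(records$status_follow)
  n <- length(w)
  p <- v <- numeric(length(lv))
  for (k in seq_along(lv)) {
    ind <- as.numeric(y == lv[k])
    p[k] <- sum(w * ind) / sw
    v[k] <- if (n > 1) (n / (n - 1)) * sum(w^2 * (ind - p[k])^2) / sw^2 else 0
  }
  .prevalence_rows("ipw", lv, p, v, n, ci_method)
}

#' Directly age-standardized prevalence
#'
#' Combines age-specific prevalence estimates into an age-adjusted figure by
#' direct standardization: `p_adj = sum(pi_a * p_a)` with variance
#' `sum(pi_a^2 * var_a)` over a fixed standard age distribution `pi`.
#'
#' @param per_age_estimates Named list of `prevalence_estimate` data frames,
#'   one per age stratum (all with the same categories and method).
#' @param standard_age_weights Named numeric vector of standard-population
#'   weights, one per age stratum, summing to 1; names must match
#'   `per_age_estimates`.
#' @param ci_method `"logit"` (default) or `"wald"`.
#' @return A `prevalence_estimate` data frame with one row per category.
#' @export
prevalence_age_adjusted <- function(per_age_estimates, standard_age_weights,
                                    ci_method = "logit") {
  ages <- names(per_age_estimates)
  gap <- setdiff(names(standard_age_weights), ages)
  if (length(gap)) {
    stop("prevalence_age_adjusted(): missing age strata: ",
         paste(gap, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(standard_age_weights) - 1) > 1e-9) {
    stop("prevalence_age_adjusted(): standard weights must sum to 1",
         call. = FALSE)
  }
  pis <- standard_age_weights[ages]
  cats <- per_age_estimates[[1]]$category
  method <- per_age_estimates[[1]]$method[1]
  p <- v <- numeric(length(cats))
  for (a in seq_along(ages)) {
    est <- per_age_estimates[[a]]
    stopifnot(identical(est$category, cats))
    p <- p + pis[a] * est$estimate
    v <- v + pis[a]^2 * est$variance
  }
  n_eff <- sum(vapply(per_age_estimates, function(e) e$n_effective[1], numeric(1)))
  .prevalence_rows(method, cats, p, v, n_eff, ci_method)
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  out <- data.frame(method = x$method,
                    category = x$category,
                    prevalence = sprintf("%.2f%% (%.2f-%.2f)",
                                         100 * x$estimate, 100 * x$ci_low,
                                         100 * x$ci_high))
  print(out, row.names = FALSE)
  invisible(x)
}
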