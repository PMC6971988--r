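#' Fit the measured/not-measured logistic model
#'
#' Fits a maximum-likelihood logistic regression of the `measured` indicator
#' on the missingness predictors (by default sex, baseline weight status,
#' household income and residence, with reference levels boy, normal weight,
#' income <18k and rural) and summarizes each non-reference level as an
#' adjusted odds ratio with a 95% Wald confidence interval, alongside the
#' measured/not-measured counts of every level.
#'
#' @param records Cohort data frame with a logical `measured` column.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `missingness_fit` with elements `model` (the
#'   `glm` fit), `coefficients`, `covariance`, `or_table`, `n_measured`,
#'   `n_total` and `converged`.
#' @export
fit_missingness <- function(records,
                            predictors = c("sex", "status_base", "income",
                                           "residence")) {
  miss <- setdiff(predictors, names(records))
  if (length(miss)) {
    stop("fit_missingness(): missing predictor columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  y <- records$measured
  if (all(y) || !any(y)) {
    stop("fit_missingness(): outcome is degenerate (all children ",
         if (all(y)) "measured" else "unmeasured", ")", call. = FALSE)
  }
  dat <- records[, c("measured", predictors), drop = FALSE]
  for (p in predictors) dat[[p]] <- droplevels(as.factor(dat[[p]]))
  display_levels <- lapply(dat[predictors], levels)
  # reference levels mirror the published table layout: normal weight and
  # income <18k (the second level) are the baselines
  if ("income" %in% predictors && "lt_18k" %in% levels(dat$income)) {
    dat$income <- stats::relevel(dat$income, ref = "lt_18k")
  }
  if ("status_base" %in% predictors && "normal" %in% levels(dat$status_base)) {
    dat$status_base <- stats::relevel(dat$status_base, ref = "normal")
  }
  form <- stats::as.formula(paste("measured ~", paste(predictors, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = dat)
  cf <- stats::coef(fit)
  if (!fit$converged || any(abs(cf[-1]) > 15)) {
    off <- if (any(abs(cf[-1]) > 15)) names(cf[-1])[which.max(abs(cf[-1]))] else "model"
    stop("fit_missingness(): non-convergence or separation involving ", off,
         call. = FALSE)
  }
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  # per-level count and OR table in the published layout
  rows <- list()
  for (p in predictors) {
    lv <- display_levels[[p]]
    for (l in lv) {
      sel <- dat[[p]] == l
      nm <- paste0(p, l)
      is_ref <- !(nm %in% names(cf))
      or <- if (is_ref) 1 else exp(cf[[nm]])
      lo <- if (is_ref) NA_real_ else exp(cf[[nm]] - 1.96 * se[[nm]])
      hi <- if (is_ref) NA_real_ else exp(cf[[nm]] + 1.96 * se[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = p, level = l,
        n_total = sum(sel),
        n_measured = sum(sel & y),
        pct_measured = round(100 * sum(sel & y) / sum(sel), 1),
        n_not_measured = sum(sel & !y),
        pct_not_measured = round(100 * sum(sel & !y) / sum(sel), 1),
        odds_ratio = unname(or), ci_low = unname(lo), ci_high = unname(hi),
        reference = is_ref,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(model = fit,
                 coefficients = cf,
                 covariance = V,
                 or_table = do.call(rbind, rows),
                 n_measured = sum(y),
                 n_total = length(y),
                 converged = TRUE),
            class = "missingness_fit")
}

#' @export
print.missingness_fit <- function(x, ...) {
  cat("Missingness model (logistic):", x$n_measured, "measured of",
      x$n_total, sprintf("(%.1f%%)\n", 100 * x$n_measured / x$n_total))
  tab <- x$or_table
  tab$odds_ratio <- round(tab$odds_ratio, 2)
  tab$ci_low <- round(tab$ci_low, 2)
  tab$ci_high <- round(tab$ci_high, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Stabilized inverse-probability weights
#'
#' Computes the stabilized weight of every measured child:
#' the marginal probability of being measured (taken directly from the data
#' as `n_measured / n_total`) divided by the child's fitted conditional
#' probability of being measured given its covariates. Children missing their
#' measurement receive no weight.
#'
#' @param fit A [fit_missingness()] result.
#' @param records The full cohort (measured and unmeasured children).
#' @return An object of class `sw_set` with `weights` (for measured children,
#'   in cohort order), `numerator_prob`, `denominator_probs`, `measured_idx`
#'   and summary statistics `mean` and `sd`.
#' @export
stabilized_weights <- function(fit, records) {
  if (!inherits(fit, "missingness_fit")) {
    stop("stabilized_weights(): fit must be a missingness_fit", call. = FALSE)
  }
  num <- fit$n_measured / fit$n_total
  p_hat <- stats::predict(fit$model, newdata = records, type = "response")
  idx <- which(records$measured)
  denom <- unname(p_hat[idx])
  if (any(denom < 1e-6)) {
    stop("stabilized_weights(): fitted measurement probability below 1e-6 ",
         "(positivity violation)", call. = FALSE)
  }
  w <- num / denom
  structure(list(weights = w,
                 numerator_prob = num,
                 denominator_probs = denom,
                 measured_idx = idx,
                 mean = mean(w),
                 sd = stats::sd(w)),
            class = "sw_set")
}

#' @export
print.sw_set <- function(x, ...) {
  cat(sprintf("Stabilized weights: n = %d, numerator = %.4f, mean = %.4f, SD = %.4f, range = [%.4f, %.4f]\n",
              length(x$weights), x$numerator_prob, x$mean, x$sd,
              min(x$weights), max(x$weights)))
  invisible(x)
}
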