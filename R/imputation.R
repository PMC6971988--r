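#' Fit the weight-status imputation model
#'
#' Multinomial logistic regression of the observed follow-up weight status
#' (four categories, baseline category "normal") on the missingness
#' predictors, fitted by maximum likelihood on measured children. The
#' coefficient vector and its asymptotic covariance feed proper multiple
#' imputation in [draw_imputations()].
#'
#' With four sparse outcome categories some outcome-by-predictor cells are
#' routinely empty, which sends the corresponding log-odds to infinity
#' (quasi-separation). A small ridge penalty (`decay`, the L2 weight decay of
#' the underlying optimizer) keeps those coefficients finite and the
#' coefficient covariance well conditioned; set `decay = 0` for the
#' unpenalized MLE, which errors on separation.
#'
#' @param records Cohort data frame; measured children must have a complete
#'   `status_follow`.
#' @param predictors Character vector of predictor column names.
#' @param decay Ridge penalty passed to [nnet::multinom()]; default 0.01.
#' @return An object of class `imputation_model` with the fitted `nnet`
#'   model, `coefficients` (stacked vector), `covariance`, the outcome
#'   `categories` and the model `terms`/`xlevels` needed to score new data.
#' @export
fit_imputation_model <- function(records,
                                 predictors = c("sex", "status_base", "income",
                                                "residence"),
                                 decay = 0.01) {
  dat <- records[records$measured & !is.na(records$status_follow),
                 c("status_follow", predictors), drop = FALSE]
  if (nrow(dat) == 0L) {
    stop("fit_imputation_model(): no measured children", call. = FALSE)
  }
  lv <- levels(records$status_follow)
  # baseline category: normal weight
  dat$status_follow <- stats::relevel(factor(dat$status_follow, levels = lv),
                                      ref = "normal")
  empty <- lv[!(lv %in% unique(as.character(dat$status_follow)))]
  if (length(empty)) {
    stop("fit_imputation_model(): outcome category empty among measured ",
         "children: ", paste(empty, collapse = ", "),
         " (collapse categories or supply more data)", call. = FALSE)
  }
  for (p in predictors) dat[[p]] <- droplevels(as.factor(dat[[p]]))
  form <- stats::as.formula(paste("status_follow ~",
                                  paste(predictors, collapse = " + ")))
  fit <- nnet::multinom(form, data = dat, trace = FALSE, maxit = 500,
                        Hess = TRUE, decay = decay)
  cf <- stats::coef(fit)
  if (any(abs(cf[, -1, drop = FALSE]) > 15)) {
    stop("fit_imputation_model(): separation in the imputation model",
         call. = FALSE)
  }
  V <- stats::vcov(fit)
  beta <- .multinom_stack(cf)
  if (!identical(names(beta), colnames(V))) {
    # fall back to the covariance ordering
    beta <- beta[colnames(V)]
  }
  structure(list(model = fit,
                 coefficients = beta,
                 covariance = V,
                 categories = c("normal", setdiff(lv, "normal")),
                 levels_out = lv,
                 terms = stats::delete.response(stats::terms(form)),
                 xlevels = lapply(dat[predictors], levels),
                 predictors = predictors),
            class = "imputation_model")
}

# Stack a multinom coefficient matrix (rows = non-baseline outcome
# categories) into the named vector ordering used by vcov(multinom):
# "category:(Intercept)", "category:x", ... grouped by category.
.multinom_stack <- function(cf) {
  if (is.null(dim(cf))) stop("expected >2 outcome categories", call. = FALSE)
  nm <- as.vector(t(outer(rownames(cf), colnames(cf), paste, sep = ":")))
  stats::setNames(as.vector(t(cf)), nm)
}

# Category probabilities at a stacked coefficient vector for a design matrix.
.multinom_probs <- function(beta, X, categories) {
  k1 <- length(categories) - 1L
  p <- ncol(X)
  B <- matrix(beta, nrow = k1, ncol = p, byrow = TRUE)
  eta <- X %*% t(B)                       # n x (K-1), baseline first category
  expeta <- exp(cbind(0, eta))
  probs <- expeta / rowSums(expeta)
  colnames(probs) <- categories
  probs
}

#' Draw proper multiple imputations of weight status
#'
#' For each of `m` imputations, draws a coefficient vector from the
#' approximate posterior `MVN(beta_hat, V_hat)` of the imputation model,
#' computes each unmeasured child's category probabilities at the drawn
#' coefficients, and samples one category per child. Observed statuses are
#' copied through unchanged, so the `m` completed datasets differ only in the
#' originally missing slots.
#'
#' @param model An [fit_imputation_model()] result.
#' @param records Full cohort data frame.
#' @param m Number of imputations (default 10).
#' @param seed Integer seed.
#' @return An object of class `imputation_result`: `m`, `completed_status`
#'   (a list of `m` factors over all children), `per_imputation_estimates`
#'   (list of `prevalence_estimate` data frames) and `seed`.
#' @export
draw_imputations <- function(model, records, m = 10L, seed = 1L) {
  if (!inherits(model, "imputation_model")) {
    stop("draw_imputations(): model must be an imputation_model", call. = FALSE)
  }
  if (m < 1L) stop("draw_imputations(): m must be >= 1", call. = FALSE)
  ev <- eigen(model$covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("draw_imputations(): coefficient covariance is not positive ",
         "semi-definite; consider ridge-regularizing the imputation model",
         call. = FALSE)
  }
  lv <- model$levels_out
  miss_idx <- which(!records$measured | is.na(records$status_follow))
  set.seed(seed)
  completed <- vector("list", m)
  ests <- vector("list", m)
  n <- nrow(records)
  if (length(miss_idx)) {
    mf <- stats::model.frame(model$terms, records[miss_idx, , drop = FALSE],
                             xlev = model$xlevels)
    X <- stats::model.matrix(model$terms, mf)
    betas <- MASS::mvrnorm(m, mu = model$coefficients,
                           Sigma = model$covariance)
    if (m == 1L) betas <- matrix(betas, nrow = 1)
  }
  for (t in seq_len(m)) {
    status <- factor(as.character(records$status_follow), levels = lv)
    if (length(miss_idx)) {
      probs <- .multinom_probs(betas[t, ], X, model$categories)
      u <- stats::runif(length(miss_idx))
      cum <- t(apply(probs, 1, cumsum))
      pick <- 1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
      status[miss_idx] <- factor(model$categories[pick], levels = lv)
    }
    completed[[t]] <- status
    p <- as.numeric(table(status)) / n
    v <- if (n > 1) p * (1 - p) / (n - 1) else rep(0, 4)
    ests[[t]] <- .prevalence_rows("mi", lv, p, v, n)
  }
  structure(list(m = as.integer(m),
                 completed_status = completed,
                 per_imputation_estimates = ests,
                 seed = as.integer(seed)),
            class = "imputation_result")
}

#' Pool estimates across imputations (Rubin's rules)
#'
#' Pools `m` point estimates and their within-imputation variances:
#' `q_bar = mean(q)`, within-variance `W = mean(v)`, between-variance
#' `B = var(q)` (divisor `m - 1`), total `T = W + (1 + 1/m) B`, degrees of
#' freedom `(m - 1) (1 + W / ((1 + 1/m) B))^2`, and a t interval
#' `q_bar +/- t_{df, 0.975} sqrt(T)` clamped to [0, 1]. When `B = 0` the df
#' are infinite and the normal quantile is used.
#'
#' @param estimates Numeric vector of `m` point estimates (proportions).
#' @param variances Numeric vector of `m` within-imputation variances.
#' @param level Confidence level (default 0.95).
#' @return An object of class `pooled_estimate`: `q_bar`, `within_var`,
#'   `between_var`, `total_var`, `df`, `ci_low`, `ci_high`, `m`.
#' @export
rubin_pool <- function(estimates, variances, level = 0.95) {
  m <- length(estimates)
  if (m < 2L) stop("rubin_pool(): need m >= 2 imputations", call. = FALSE)
  if (length(variances) != m) {
    stop("rubin_pool(): estimates and variances must have equal length",
         call. = FALSE)
  }
  q_bar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    tq <- stats::qt(1 - (1 - level) / 2, df)
  } else {
    df <- Inf
    tq <- stats::qnorm(1 - (1 - level) / 2)
  }
  half <- tq * sqrt(Tv)
  structure(list(q_bar = q_bar, within_var = W, between_var = B,
                 total_var = Tv, df = df,
                 ci_low = max(0, q_bar - half),
                 ci_high = min(1, q_bar + half),
                 m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (m = %d): %.4f (%.4f-%.4f); W = %.3g, B = %.3g, T = %.3g, df = %.1f\n",
              x$m, x$q_bar, x$ci_low, x$ci_high, x$within_var, x$between_var,
              x$total_var, x$df))
  invisible(x)
}

#' Multiple-imputation prevalence
#'
#' Full MI path: fit the imputation model on measured children, draw `m`
#' completed datasets, estimate each category's prevalence over the whole
#' cohort in every completed dataset, and pool with Rubin's rules.
#'
#' @param records Full cohort data frame.
#' @param predictors Predictor columns for the imputation model.
#' @param m Number of imputations (default 10).
#' @param seed Integer seed.
#' @return A `prevalence_estimate` data frame (method `"mi"`) whose variance
#'   column holds the Rubin total variance and whose interval is the pooled t
#'   interval; the `imputation_result` is attached as attribute `"imputations"`.
#' @export
prevalence_mi <- function(records,
                          predictors = c("sex", "status_base", "income",
                                         "residence"),
                          m = 10L, seed = 1L) {
  model <- fit_imputation_model(records, predictors)
  imps <- draw_imputations(model, records, m = m, seed = seed)
  lv <- levels(records$status_follow)
  rows <- vector("list", length(lv))
  for (k in seq_along(lv)) {
    q <- vapply(imps$per_imputation_estimates,
                function(e) e$estimate[e$category == lv[k]], numeric(1))
    v <- vapply(imps$per_imputation_estimates,
                function(e) e$variance[e$category == lv[k]], numeric(1))
    if (m >= 2L) {
      pool <- rubin_pool(q, v)
      rows[[k]] <- data.frame(method = "mi", category = lv[k],
                              estimate = pool$q_bar, variance = pool$total_var,
                              ci_low = pool$ci_low, ci_high = pool$ci_high,
                              n_effective = nrow(records),
                              stringsAsFactors = FALSE)
    } else {
      e <- imps$per_imputation_estimates[[1]]
      rows[[k]] <- e[e$category == lv[k], ]
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("prevalence_estimate", "data.frame")
  attr(out, "imputations") <- imps
  rownames(out) <- NULL
  out
}
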