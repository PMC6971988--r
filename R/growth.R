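#' Body mass index
#'
#' BMI in kg/m^2 from weight in kilograms and height in meters.
#'
#' @param weight_kg Numeric vector of weights in kilograms; must be positive.
#' @param height_m Numeric vector of heights in meters; must be positive.
#' @return Numeric vector of BMI values (kg/m^2).
#' @examples
#' bmi(30, 1.25) # 19.2
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_m))) {
    stop("bmi(): weight and height must be finite", call. = FALSE)
  }
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("bmi(): weight and height must be positive", call. = FALSE)
  }
  weight_kg / height_m^2
}

#' LMS z-score
#'
#' Standardizes a measurement against an LMS growth reference
#' (Box-Cox power `L`, median `M`, coefficient of variation `S`):
#' `z = ((x/M)^L - 1) / (L * S)`, with the continuous limit
#' `z = log(x/M) / S` used when `|L|` is numerically zero.
#'
#' @param value Positive numeric vector of measurements (e.g. BMI).
#' @param L Box-Cox power of the reference stratum.
#' @param M Median of the reference stratum; must be positive.
#' @param S Coefficient of variation of the reference stratum; must be positive.
#' @return Numeric vector of z-scores.
#' @examples
#' lms_zscore(18, L = 1, M = 16, S = 0.1) # 1.25
#' @export
lms_zscore <- function(value, L, M, S) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("lms_zscore(): value must be positive and finite", call. = FALSE)
  }
  if (any(M <= 0) || any(S <= 0)) {
    stop("lms_zscore(): M and S must be positive", call. = FALSE)
  }
  r <- value / M
  ifelse(abs(L) < 1e-8, log(r) / S, (r^L - 1) / (L * S))
}

#' Read an LMS reference table
#'
#' Reads a CSV with columns `sex`, `age_months`, `L`, `M`, `S` giving the LMS
#' parameters of each sex/age stratum.
#'
#' @param path Path to the CSV file.
#' @return A data frame with the five columns, validated.
#' @export
read_lms_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_months", "L", "M", "S")
  miss <- setdiff(need, names(ref))
  if (length(miss)) {
    stop("LMS reference is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(ref$sex %in% c("boy", "girl"))) {
    stop("LMS reference: sex must be 'boy' or 'girl'", call. = FALSE)
  }
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    stop("LMS reference: M and S must be positive", call. = FALSE)
  }
  ref
}

#' Z-score against a reference table
#'
#' Looks up the LMS row for each child's sex and age in months and returns the
#' LMS z-score of the supplied value.
#'
#' @param value Positive numeric vector (e.g. BMI).
#' @param sex Character vector, `"boy"` or `"girl"`.
#' @param age_months Integer vector of ages in months; must match a reference row.
#' @param reference Data frame from [read_lms_reference()].
#' @return Numeric vector of z-scores.
#' @export
lms_reference_zscore <- function(value, sex, age_months, reference) {
  key <- paste(sex, age_months)
  ref_key <- paste(reference$sex, reference$age_months)
  idx <- match(key, ref_key)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("No LMS reference row for: ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  lms_zscore(value, reference$L[idx], reference$M[idx], reference$S[idx])
}

# Category labels for the two age schemes. Cutoffs are shared
# (-2, 1, 2 SD); only the naming of the upper two categories differs.
.status_levels <- function(scheme) {
  switch(scheme,
    young = c("underweight", "normal", "at_risk_overweight", "overweight_obese"),
    older = c("underweight", "normal", "overweight", "obese"),
    stop("unknown scheme: ", scheme, call. = FALSE)
  )
}

#' Classify weight status from a BMI z-score
#'
#' Applies the four-category weight-status classification: underweight
#' (z < -2), normal (-2 <= z <= 1), then `at_risk_overweight` /
#' `overweight_obese` under the young (2-5 y) scheme or `overweight` / `obese`
#' under the older (> 5 y) scheme, with boundaries at z > 1 and z > 2
#' (both strict on the left, so z = 1 is normal and z = 2 is the middle
#' category).
#'
#' @param z Numeric vector of BMI z-scores (expected |z| < 5 after filtering).
#' @param scheme `"young"` for ages 2-5, `"older"` for ages above 5.
#' @return A factor with the four scheme-specific category levels; `NA` in
#'   maps to `NA` out.
#' @examples
#' classify_weight_status(c(-2.5, 0, 1.5, 2.5), "older")
#' @export
classify_weight_status <- function(z, scheme = c("young", "older")) {
  scheme <- match.arg(scheme)
  lv <- .status_levels(scheme)
  idx <- 1L + (z >= -2) + (z > 1) + (z > 2)
  factor(lv[idx], levels = lv)
}

#' Remove implausible z-scores
#'
#' Drops records whose BMI z-score lies at or beyond 5 SD in either direction
#' (|z| >= 5), the standard plausibility screen for EHR anthropometrics.
#' Missing z values are kept untouched.
#'
#' @param records Data frame of child records.
#' @param z_cols Character vector of z-score columns to screen.
#' @return A list with `records` (the kept rows) and `n_excluded`.
#' @export
filter_implausible <- function(records, z_cols = intersect(c("z_base", "z_follow"),
                                                           names(records))) {
  if (nrow(records) == 0L) {
    return(list(records = records, n_excluded = 0L))
  }
  bad <- rep(FALSE, nrow(records))
  for (col in z_cols) {
    z <- records[[col]]
    bad <- bad | (!is.na(z) & abs(z) >= 5)
  }
  list(records = records[!bad, , drop = FALSE], n_excluded = sum(bad))
}
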