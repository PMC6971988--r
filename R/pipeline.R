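#' Measurement coverage by age
#'
#' For each age, the number and percentage of children with at least one
#' measurement event carrying both weight and height at the same time point
#' inside a short (one-year) and a long (four-year) window. A child with
#' weight but no height (or vice versa) at a time point does not count as
#' measured there.
#'
#' @param events Data frame of measurement events: `child_id`, `date`
#'   (`Date` or ISO-8601 string), `weight_kg`, `height_m` (either may be NA).
#' @param population Data frame of the census population: `child_id`,
#'   `age_years`, and optionally logical `scheduled_visit`.
#' @param window_1y,window_4y Length-2 `Date` (or ISO string) vectors
#'   `c(start, end)`, inclusive.
#' @return Data frame with one row per age plus a `"total"` row: `age_years`,
#'   `n_total`, `n_measured_1y`, `pct_1y`, `n_measured_4y`, `pct_4y`,
#'   `scheduled_visit`. Percentages are rounded to 1 decimal.
#' @export
coverage_table <- function(events, population, window_1y, window_4y) {
  unknown <- setdiff(events$child_id, population$child_id)
  if (length(unknown)) {
    stop("coverage_table(): events reference unknown children: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  dates <- as.Date(events$date)
  ok <- !is.na(events$weight_kg) & !is.na(events$height_m) &
    events$weight_kg > 0 & events$height_m > 0
  in_win <- function(win) {
    win <- as.Date(win)
    ids <- unique(events$child_id[ok & dates >= win[1] & dates <= win[2]])
    population$child_id %in% ids
  }
  m1 <- in_win(window_1y)
  m4 <- in_win(window_4y)
  sched <- if ("scheduled_visit" %in% names(population)) {
    population$scheduled_visit
  } else rep(NA, nrow(population))
  ages <- sort(unique(population$age_years))
  rows <- lapply(ages, function(a) {
    sel <- population$age_years == a
    data.frame(age_years = as.character(a),
               n_total = sum(sel),
               n_measured_1y = sum(sel & m1),
               pct_1y = round(100 * sum(sel & m1) / sum(sel), 1),
               n_measured_4y = sum(sel & m4),
               pct_4y = round(100 * sum(sel & m4) / sum(sel), 1),
               scheduled_visit = sched[sel][1],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tot <- data.frame(age_years = "total",
                    n_total = nrow(population),
                    n_measured_1y = sum(m1),
                    pct_1y = round(100 * sum(m1) / nrow(population), 1),
                    n_measured_4y = sum(m4),
                    pct_4y = round(100 * sum(m4) / nrow(population), 1),
                    scheduled_visit = NA,
                    stringsAsFactors = FALSE)
  rbind(tab, tot)
}

#' Coverage percentages from printed counts
#'
#' Recomputes the one- and four-year coverage percentages of a published
#' coverage table from its counts (`n / N`, rounded to 1 decimal), e.g. to
#' check a table's internal consistency.
#'
#' @param counts Data frame with columns `n_total`, `n_measured_1y`,
#'   `n_measured_4y` (any other columns are carried through).
#' @return The input with `pct_1y` and `pct_4y` recomputed.
#' @export
coverage_from_counts <- function(counts) {
  counts$pct_1y <- round(100 * counts$n_measured_1y / counts$n_total, 1)
  counts$pct_4y <- round(100 * counts$n_measured_4y / counts$n_total, 1)
  counts
}

#' Compare complete-case, IPW and MI prevalence on one cohort
#'
#' Runs the three estimator paths on the identical cohort: complete-case
#' prevalence among measured children; stabilized-IPW prevalence after
#' fitting the missingness model on the four covariates; and multiple
#' imputation with Rubin pooling. Records failing the plausibility screen
#' (|z| >= 5) are removed first.
#'
#' @param cohort Cohort data frame (see [generate_cohort()] /
#'   [read_cohort()] for the schema).
#' @param predictors Missingness/imputation predictor columns.
#' @param m Number of imputations.
#' @param seed Integer seed (drives the MI draws).
#' @param ci_method `"logit"` (default) or `"wald"` for CC and IPW intervals.
#' @return A `prevalence_estimate` data frame with 12 rows (3 methods x 4
#'   categories); the missingness fit and weight diagnostics are attached as
#'   attributes `"missingness_fit"` and `"weights"`.
#' @export
run_comparison <- function(cohort,
                           predictors = c("sex", "status_base", "income",
                                          "residence"),
                           m = 10L, seed = 1L, ci_method = "logit") {
  flt <- filter_implausible(cohort)
  cohort <- flt$records
  if (!any(cohort$measured)) {
    stop("run_comparison() [complete_case]: no measured children", call. = FALSE)
  }
  cc <- prevalence_complete_case(cohort, ci_method)
  if (all(cohort$measured)) {
    # no missingness: the three estimators coincide by construction
    ipw <- cc; ipw$method <- "ipw"
    mi <- cc; mi$method <- "mi"
    fit <- NULL; sw <- NULL
  } else {
    fit <- tryCatch(fit_missingness(cohort, predictors),
                    error = function(e) stop("run_comparison() [missingness]: ",
                                             conditionMessage(e), call. = FALSE))
    sw <- tryCatch(stabilized_weights(fit, cohort),
                   error = function(e) stop("run_comparison() [weights]: ",
                                            conditionMessage(e), call. = FALSE))
    ipw <- prevalence_ipw(cohort, sw, ci_method)
    mi <- tryCatch(prevalence_mi(cohort, predictors, m = m, seed = seed),
                   error = function(e) stop("run_comparison() [mi]: ",
                                            conditionMessage(e), call. = FALSE))
  }
  out <- rbind(cc, ipw, mi)
  class(out) <- c("prevalence_estimate", "data.frame")
  rownames(out) <- NULL
  attr(out, "missingness_fit") <- fit
  attr(out, "weights") <- sw
  attr(out, "n_excluded_implausible") <- flt$n_excluded
  out
}

# Cohort CSV schema: one row per child.
.cohort_columns <- c("child_id", "sex", "residence", "income", "z_base",
                     "status_base", "age_years", "measured", "z_follow")

#' Write a cohort to CSV
#'
#' Writes the wide one-row-per-child schema: `child_id`,
#' `sex` (boy/girl), `residence` (rural/urban), `income` (1-4),
#' `z_base`, `status_base`, `age_years`, `measured` (0/1), `z_follow`
#' (empty iff unmeasured). `status_follow` is derived on read, not stored.
#'
#' @param records Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  out <- data.frame(child_id = records$child_id,
                    sex = as.character(records$sex),
                    residence = as.character(records$residence),
                    income = match(as.character(records$income), .income_levels),
                    z_base = records$z_base,
                    status_base = as.character(records$status_base),
                    age_years = records$age_years,
                    measured = as.integer(records$measured),
                    z_follow = records$z_follow,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Reads and validates the cohort schema written by [write_cohort()];
#' validation failures report the offending data row. `status_follow` is
#' rederived from `z_follow` under the older-age cutoffs.
#'
#' @param path CSV path.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(child_id = "character"))
  miss <- setdiff(.cohort_columns, names(raw))
  if (length(miss)) {
    stop("read_cohort(): missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  .bad_rows <- function(bad, what) {
    if (any(bad)) {
      stop("read_cohort(): ", what, " at row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(raw) == 0L) {
    empty <- generate_cohort(cohort_config(1, 0.5, 0.5, rep(0.25, 4),
                                           rep(0.25, 4)))[0, ]
    return(empty)
  }
  .bad_rows(!(raw$sex %in% .sex_levels), "invalid sex label")
  .bad_rows(!(raw$residence %in% .residence_levels), "invalid residence label")
  .bad_rows(!(raw$income %in% 1:4), "invalid income category")
  .bad_rows(!(raw$status_base %in% .status_levels("young")),
            "invalid status_base label")
  .bad_rows(!is.numeric(raw$z_base) | is.na(raw$z_base), "non-numeric z_base")
  .bad_rows(!(raw$measured %in% 0:1), "invalid measured flag")
  .bad_rows(raw$measured == 1 & is.na(raw$z_follow),
            "measured child without z_follow")
  .bad_rows(raw$measured == 0 & !is.na(raw$z_follow),
            "unmeasured child with z_follow")
  data.frame(child_id = raw$child_id,
             sex = factor(raw$sex, levels = .sex_levels),
             residence = factor(raw$residence, levels = .residence_levels),
             income = factor(.income_levels[raw$income],
                             levels = .income_levels),
             z_base = raw$z_base,
             status_base = factor(raw$status_base,
                                  levels = .status_levels("young")),
             age_years = as.integer(raw$age_years),
             measured = raw$measured == 1,
             z_follow = raw$z_follow,
             status_follow = classify_weight_status(raw$z_follow, "older"),
             stringsAsFactors = FALSE)
}

#' Read a cohort configuration file
#'
#' Reads a YAML or JSON file whose keys are the [cohort_config()] arguments.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (nm in c("missingness_log_ors", "mnar_log_ors")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  do.call(cohort_config, cfg)
}
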