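#' Binary MS-activity outcome for each patient
#'
#' Derives the binary outcome used in the contingency analyses:
#' \describe{
#'   \item{cdms}{conversion to clinically definite MS (a second clinical
#'     attack under the Poser criteria), taken from `converted_cdms`;}
#'   \item{attacks}{one or more clinical attacks during follow-up
#'     (`n_attacks >= 1`);}
#'   \item{new_lesions}{one or more surveillance MRIs showing new lesions
#'     (`n_mris_with_new_lesions >= 1`). Patients with no MRIs performed
#'     count as outcome-negative.}
#' }
#'
#' @param cohort A validated cohort data frame.
#' @param outcome One of `"cdms"`, `"attacks"`, `"new_lesions"`.
#' @return A logical vector, one element per patient.
#' @export
outcome_predicate <- function(cohort,
                              outcome = c("cdms", "attacks", "new_lesions")) {
  outcome <- match.arg(outcome)
  validate_cohort(cohort)
  switch(outcome,
    cdms = cohort$converted_cdms,
    attacks = cohort$n_attacks >= 1L,
    new_lesions = cohort$n_mris_with_new_lesions >= 1L)
}

#' Confusion table of CXCL13 stratification versus an outcome
#'
#' Cross-tabulates the high/low stratification (prediction: high group =
#' positive) against a binary MS-activity outcome. Indeterminate patients
#' are excluded; every non-indeterminate patient lands in exactly one
#' cell, so `tp + fp + tn + fn` equals the number of high- or low-group
#' patients.
#'
#' @param cohort A validated cohort data frame.
#' @param strata Stratification from [stratify_cohort()]; must cover every
#'   patient in `cohort`.
#' @param outcome Outcome name, see [outcome_predicate()].
#' @return An object of class `confusion_table` with fields `tp`, `fp`,
#'   `tn`, `fn`, `outcome`, `n_excluded` (indeterminate count).
#' @export
build_confusion <- function(cohort, strata,
                            outcome = c("cdms", "attacks", "new_lesions")) {
  outcome <- match.arg(outcome)
  validate_cohort(cohort)
  pos <- match(cohort$patient_id, strata$patient_id)
  if (anyNA(pos)) {
    stop("no stratum for patient_id: ",
         cohort$patient_id[which(is.na(pos))[1]])
  }
  group <- strata$group[pos]
  truth <- outcome_predicate(cohort, outcome)
  keep <- group %in% c("high", "low")
  pred <- group[keep] == "high"
  obs <- truth[keep]
  structure(list(
    tp = sum(pred & obs), fp = sum(pred & !obs),
    tn = sum(!pred & !obs), fn = sum(!pred & obs),
    outcome = outcome, n_excluded = sum(!keep)
  ), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("Confusion table (%s): TP=%d FP=%d TN=%d FN=%d", x$outcome,
              x$tp, x$fp, x$tn, x$fn))
  if (x$n_excluded > 0) cat(sprintf("  [%d indeterminate excluded]",
                                    x$n_excluded))
  cat("\n")
  invisible(x)
}

# Clopper-Pearson exact binomial interval via the beta quantile closed form.
clopper_pearson <- function(x, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic performance of a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each
#' with a two-sided exact (Clopper-Pearson) confidence interval. A measure
#' whose denominator is zero is flagged undefined (`defined = FALSE`,
#' estimate `NA`) rather than propagating NaN.
#'
#' @param table A `confusion_table` from [build_confusion()].
#' @param conf_level Confidence level for the exact intervals. Default 0.95.
#' @return A data frame with columns `measure`, `estimate`, `lower`,
#'   `upper`, `defined`.
#' @export
diagnostic_performance <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  cells <- c(table$tp, table$fp, table$tn, table$fn)
  if (any(cells < 0)) stop("confusion table cells must be non-negative")
  one <- function(x, n) {
    if (n == 0) {
      return(data.frame(estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, defined = FALSE))
    }
    ci <- clopper_pearson(x, n, conf_level)
    data.frame(estimate = x / n, lower = ci[["lower"]],
               upper = ci[["upper"]], defined = TRUE)
  }
  rows <- rbind(
    one(table$tp, table$tp + table$fn),
    one(table$tn, table$tn + table$fp),
    one(table$tp, table$tp + table$fp),
    one(table$tn, table$tn + table$fn))
  cbind(data.frame(measure = c("sensitivity", "specificity", "ppv", "npv")),
        rows)
}

#' Percentage of surveillance MRIs showing new lesions
#'
#' The screening-adjusted MRI activity measure: the number of MRIs in
#' which a new lesion was identified divided by the total number of MRI
#' visits. Undefined (`NA`) for patients with no MRIs performed; such
#' patients are excluded from group medians of this measure.
#'
#' @param n_mris_with_new_lesions Number of MRIs showing new lesions.
#' @param n_mris Total number of MRIs performed.
#' @return A numeric vector of proportions in `[0, 1]`, `NA` where
#'   `n_mris == 0`.
#' @export
percent_mris_with_new_lesions <- function(n_mris_with_new_lesions, n_mris) {
  if (any(n_mris_with_new_lesions > n_mris, na.rm = TRUE)) {
    stop("n_mris_with_new_lesions exceeds n_mris")
  }
  ifelse(n_mris > 0, n_mris_with_new_lesions / n_mris, NA_real_)
}
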