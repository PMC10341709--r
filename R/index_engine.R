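#' Threshold policy for CXCL13 stratification
#'
#' The dual threshold system used to stratify patients. When the CXCL13
#' index is computable, values above `index_high` are classified high and
#' values below `index_low` are classified low. When serum CXCL13 is
#' unavailable and the index cannot be computed, the CSF concentration
#' alone is used: above `csf_high` pg/mL is high, below `csf_low` pg/mL is
#' low. Anything between the cuts (including values exactly equal to a
#' cut) is indeterminate.
#'
#' @param index_high Upper index cut (dimensionless). Default 30.
#' @param index_low Lower index cut (dimensionless). Default 20.
#' @param csf_high Upper CSF CXCL13 cut in pg/mL. Default 14.
#' @param csf_low Lower CSF CXCL13 cut in pg/mL. Default 5.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(index_high = 30, index_low = 20,
                             csf_high = 14, csf_low = 5) {
  cuts <- c(index_high = index_high, index_low = index_low,
            csf_high = csf_high, csf_low = csf_low)
  if (any(!is.finite(cuts)) || any(cuts <= 0)) {
    stop("all threshold cuts must be finite and > 0")
  }
  if (index_low >= index_high) stop("index_low must be < index_high")
  if (csf_low >= csf_high) stop("csf_low must be < csf_high")
  structure(as.list(cuts), class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("CXCL13 threshold policy\n")
  cat(sprintf("  index:      low < %g, high > %g\n", x$index_low,
              x$index_high))
  cat(sprintf("  CSF (pg/mL): low < %g, high > %g (serum unavailable)\n",
              x$csf_low, x$csf_high))
  invisible(x)
}

#' Compute CXCL13 quotients and the CXCL13 index
#'
#' The CXCL13 index measures intrathecal CXCL13 production: the CSF/serum
#' CXCL13 quotient `Q_CXCL13 = csf_cxcl13 / serum_cxcl13` is normalised by
#' the albumin quotient `Q_albumin = csf_albumin / serum_albumin` to
#' correct for blood-CSF barrier permeability, giving
#' `index = Q_CXCL13 / Q_albumin`. All three are dimensionless; each is
#' `NA` exactly when one of its inputs is missing. No classification is
#' performed here (see [classify_index()]).
#'
#' @param csf_cxcl13 CSF CXCL13 concentration, pg/mL. Required, > 0.
#' @param serum_cxcl13 Serum CXCL13 concentration, pg/mL, or `NA`.
#' @param csf_albumin,serum_albumin Albumin concentrations in any
#'   consistent common unit, or `NA` (both together).
#' @return A data frame with columns `q_cxcl13`, `q_albumin`, `index`.
#' @export
compute_index <- function(csf_cxcl13, serum_cxcl13 = NA_real_,
                          csf_albumin = NA_real_,
                          serum_albumin = NA_real_) {
  n <- length(csf_cxcl13)
  serum_cxcl13 <- rep_len(serum_cxcl13, n)
  csf_albumin <- rep_len(csf_albumin, n)
  serum_albumin <- rep_len(serum_albumin, n)
  if (anyNA(csf_cxcl13) || any(csf_cxcl13 <= 0)) {
    stop("csf_cxcl13 must be present and > 0")
  }
  for (nm in c("serum_cxcl13", "csf_albumin", "serum_albumin")) {
    x <- get(nm)
    if (any(!is.na(x) & x <= 0)) stop(nm, " must be > 0 where present")
  }
  q_cxcl13 <- csf_cxcl13 / serum_cxcl13
  q_albumin <- csf_albumin / serum_albumin
  data.frame(q_cxcl13 = q_cxcl13, q_albumin = q_albumin,
             index = q_cxcl13 / q_albumin)
}

#' Classify patients as CXCL13 high, low or indeterminate
#'
#' Applies the dual threshold system of a [threshold_policy()]. When an
#' index value is available the index rule is used (`basis = "index"`);
#' the CSF-only rule (`basis = "csf_only"`) is a fallback for patients
#' whose index could not be computed. Values strictly between the cuts, or
#' exactly on a cut, are indeterminate.
#'
#' @param index CXCL13 index values (`NA` where not computable).
#' @param csf_cxcl13 CSF CXCL13 in pg/mL (used only where `index` is `NA`).
#' @param policy A [threshold_policy()].
#' @return A data frame with columns `group` (factor: high, low,
#'   indeterminate) and `basis` (factor: index, csf_only).
#' @export
classify_index <- function(index, csf_cxcl13,
                           policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  n <- length(index)
  csf_cxcl13 <- rep_len(csf_cxcl13, n)
  if (anyNA(csf_cxcl13)) stop("csf_cxcl13 must be present for every patient")
  group <- rep("indeterminate", n)
  basis <- ifelse(is.na(index), "csf_only", "index")

  by_index <- !is.na(index)
  group[by_index & index > policy$index_high] <- "high"
  group[by_index & index < policy$index_low] <- "low"
  group[!by_index & csf_cxcl13 > policy$csf_high] <- "high"
  group[!by_index & csf_cxcl13 < policy$csf_low] <- "low"

  data.frame(
    group = factor(group, levels = c("low", "high", "indeterminate")),
    basis = factor(basis, levels = c("index", "csf_only"))
  )
}

#' Stratify a cohort by intrathecal CXCL13 production
#'
#' Runs [compute_index()] and [classify_index()] over a validated cohort.
#' Indeterminate patients are retained in the result, flagged by
#' `group == "indeterminate"`, and are excluded from downstream
#' contingency analyses by [build_confusion()].
#'
#' @param cohort A validated cohort data frame (see [read_cohort()]).
#' @param policy A [threshold_policy()].
#' @return A data frame with one row per patient: `patient_id`,
#'   `q_cxcl13`, `q_albumin`, `index`, `group`, `basis`.
#' @export
stratify_cohort <- function(cohort, policy = threshold_policy()) {
  validate_cohort(cohort)
  idx <- tryCatch(
    compute_index(cohort$csf_cxcl13, cohort$serum_cxcl13,
                  cohort$csf_albumin, cohort$serum_albumin),
    error = function(e) {
      stop("stratify_cohort: ", conditionMessage(e), call. = FALSE)
    })
  cls <- classify_index(idx$index, cohort$csf_cxcl13, policy)
  cbind(data.frame(patient_id = cohort$patient_id), idx, cls)
}

#' Agreement between the CSF-only rule and the index rule
#'
#' The CSF-only fallback thresholds (5 and 14 pg/mL) rest on an observed
#' near-perfect concordance: elevated indices were not seen below
#' 5 pg/mL of CSF CXCL13 and were always seen above 14 pg/mL. This
#' function measures that concordance on a cohort: among patients with
#' full data (index computable) whose CSF CXCL13 lies outside
#' `[csf_low, csf_high]`, the proportion whose CSF-only classification
#' matches their index classification.
#'
#' @param cohort A validated cohort data frame.
#' @param policy A [threshold_policy()].
#' @return A list with `n_eligible` (full-data patients outside the CSF
#'   band), `n_agree`, `agreement` and `disagreement` proportions.
#' @export
harmonization_agreement <- function(cohort, policy = threshold_policy()) {
  validate_cohort(cohort)
  idx <- compute_index(cohort$csf_cxcl13, cohort$serum_cxcl13,
                       cohort$csf_albumin, cohort$serum_albumin)
  full <- !is.na(idx$index)
  outside <- cohort$csf_cxcl13 < policy$csf_low |
    cohort$csf_cxcl13 > policy$csf_high
  eligible <- full & outside
  by_index <- classify_index(idx$index[eligible], cohort$csf_cxcl13[eligible],
                             policy)$group
  by_csf <- classify_index(rep(NA_real_, sum(eligible)),
                           cohort$csf_cxcl13[eligible], policy)$group
  n_agree <- sum(as.character(by_index) == as.character(by_csf))
  n <- sum(eligible)
  list(n_eligible = n, n_agree = n_agree,
       agreement = if (n > 0) n_agree / n else NA_real_,
       disagreement = if (n > 0) 1 - n_agree / n else NA_real_)
}
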