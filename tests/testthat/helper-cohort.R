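# Shared fixtures, built in code.

# A minimal hand-built cohort: patient 1 has full data, patient 2 lacks
# serum CXCL13 (CSF-only pathway), patient 3 lacks TNC.
small_cohort <- function() {
  data.frame(
    patient_id = c("A1", "A2", "A3"),
    diagnosis = c("CIS", "RIS", "CIS"),
    age = c(35, 42, 29),
    sex = c("female", "male", "female"),
    treatment = c("None", "Interferon", NA),
    csf_cxcl13 = c(10, 2.02, 17.83),
    serum_cxcl13 = c(100, NA, 60),
    csf_albumin = c(20, 25, 18),
    serum_albumin = c(4000, 4100, 3900),
    albumin_unit = "mg/dL",
    tnc = c(4, 2, NA),
    converted_cdms = c(TRUE, FALSE, TRUE),
    ocb_positive = c(TRUE, FALSE, TRUE),
    n_attacks = c(2L, 0L, 1L),
    n_mris = c(6L, 0L, 4L),
    n_mris_with_new_lesions = c(2L, 0L, 1L),
    n_new_or_enhancing_lesions = c(3L, 0L, 1L),
    followup_years = c(6.5, 7.1, 5.2),
    study_eligible = TRUE,
    stringsAsFactors = FALSE)
}

# Drop row names so frames from different construction paths compare equal.
strip_rownames <- function(df) {
  rownames(df) <- NULL
  df
}

# Brute-force two-sided Fisher oracle: enumerate every 2x2 table with the
# observed margins via dhyper and sum the probabilities not exceeding the
# observed table's (same tie slack as the implementation under test).
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || k == n) return(1)
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[log(probs) <= log(p_obs) + 1e-7]))
}
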