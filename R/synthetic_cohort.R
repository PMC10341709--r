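# Spread of a log-normal on the log scale, back-solved from a printed
# interquartile range: log(q75/q25) = 2 * qnorm(0.75) * sigma.
iqr_to_log_sigma <- function(q25, q75) log(q75 / q25) / (2 * stats::qnorm(0.75))

#' Configuration for the synthetic CIS/RIS cohort generator
#'
#' Defaults emulate the group structure of the five-year CIS/RIS
#' follow-up cohort this package models: 17 index-high and 20 index-low
#' patients; log-normal CXCL13 index distributions with group medians
#' 67.07 / 5.99 and log-scale spreads back-solved from the printed IQRs;
#' CSF CXCL13 medians 17.83 / 2.02 pg/mL; Bernoulli outcomes with group
#' rates CDMS 82.4% / 10.0%, one-or-more attacks 52.9% / 5.0%, OCB
#' positivity 94.1% / 65.0%; Poisson MRI surveillance; and a weak positive
#' CSF-CXCL13 to total-nucleated-cell relationship. The latent log index
#' and log CSF concentration are drawn with correlation
#' `index_csf_corr`, reflecting the near-perfect concordance between the
#' two classification rules outside the 5-14 pg/mL band that motivates
#' the CSF-only fallback.
#'
#' Per-group parameters are length-2 vectors named `low`, `high`.
#' Indeterminate patients (default none) draw their index uniformly
#' inside the indeterminate zone (20, 30), CSF CXCL13 uniformly in
#' (5, 14) pg/mL, and outcome rates midway between the two groups.
#'
#' @param n_low,n_high,n_indeterminate Group sizes.
#' @param index_median,index_log_sigma Per-group log-normal parameters of
#'   the CXCL13 index (median on the natural scale, SD on the log scale).
#' @param csf_median,csf_log_sigma Same for CSF CXCL13 (pg/mL).
#' @param index_csf_corr Correlation of latent log index and log CSF
#'   CXCL13 within a group.
#' @param serum_avail_prob Per-group probability that serum CXCL13 was
#'   banked (drives the CSF-only classification pathway).
#' @param qalb_median,qalb_log_sigma Log-normal albumin quotient.
#' @param serum_albumin_median,serum_albumin_log_sigma Log-normal serum
#'   albumin, mg/dL.
#' @param cdms_prob,attack_prob,ocb_prob Per-group Bernoulli outcome rates.
#' @param attack_extra_mean Poisson mean of attacks beyond the first,
#'   given at least one attack.
#' @param followup_median Per-group median follow-up, years; follow-up is
#'   5 + Gamma(shape 2) so every patient meets the 5-year eligibility.
#' @param mri_rate Per-group expected MRIs per patient-year.
#' @param lesion_prob_per_mri Per-group probability an MRI shows new
#'   lesions.
#' @param lesion_count_extra Poisson mean of lesions beyond the first on
#'   a lesion-positive MRI.
#' @param tnc_intercept,tnc_slope,tnc_noise_sd Total nucleated cell count
#'   model: `tnc = intercept + slope * csf_cxcl13 + N(0, sd)`, truncated
#'   at 0 and rounded (cells/uL).
#' @param age_mean,age_sd,male_prob,cis_prob Per-group demographics.
#' @param seed Integer seed; the generator derives an independent
#'   substream per patient so enlarging a group never perturbs
#'   previously drawn patients.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_low = 20L, n_high = 17L, n_indeterminate = 0L,
    index_median = c(low = 5.99, high = 67.07),
    index_log_sigma = c(low = iqr_to_log_sigma(4.25, 10.42),
                        high = iqr_to_log_sigma(47.86, 83.76)),
    csf_median = c(low = 2.02, high = 17.83),
    csf_log_sigma = c(low = iqr_to_log_sigma(0.78, 4.77),
                      high = iqr_to_log_sigma(12.50, 28.55)),
    index_csf_corr = 0.9,
    serum_avail_prob = c(low = 0.30, high = 0.412),
    qalb_median = 0.005, qalb_log_sigma = 0.4,
    serum_albumin_median = 4100, serum_albumin_log_sigma = 0.08,
    cdms_prob = c(low = 0.100, high = 0.824),
    attack_prob = c(low = 0.050, high = 0.529),
    ocb_prob = c(low = 0.650, high = 0.941),
    attack_extra_mean = 0.7,
    followup_median = c(low = 6.81, high = 6.35),
    mri_rate = c(low = 0.44, high = 0.63),
    lesion_prob_per_mri = c(low = 0.02, high = 0.33),
    lesion_count_extra = c(low = 0, high = 0.6),
    tnc_intercept = 2, tnc_slope = 0.3, tnc_noise_sd = 12,
    age_mean = c(low = 41.89, high = 35.51),
    age_sd = c(low = 12.27, high = 10.51),
    male_prob = c(low = 0.15, high = 0.176),
    cis_prob = c(low = 0.80, high = 1.0),
    seed = 1L) {
  cfg <- mget(names(formals()))
  pg <- function(x) {  # per-group parameter: recycle and name
    x <- rep_len(unname(x), 2)
    names(x) <- c("low", "high")
    x
  }
  per_group <- c("index_median", "index_log_sigma", "csf_median",
                 "csf_log_sigma", "serum_avail_prob", "cdms_prob",
                 "attack_prob", "ocb_prob", "followup_median", "mri_rate",
                 "lesion_prob_per_mri", "lesion_count_extra", "age_mean",
                 "age_sd", "male_prob", "cis_prob")
  for (nm in per_group) cfg[[nm]] <- pg(cfg[[nm]])

  sizes <- c(cfg$n_low, cfg$n_high, cfg$n_indeterminate)
  if (any(sizes < 0) || any(sizes != round(sizes))) {
    stop("group sizes must be non-negative integers")
  }
  probs <- c(cfg$serum_avail_prob, cfg$cdms_prob, cfg$attack_prob,
             cfg$ocb_prob, cfg$lesion_prob_per_mri, cfg$male_prob,
             cfg$cis_prob, cfg$index_csf_corr)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  spreads <- c(cfg$index_log_sigma, cfg$csf_log_sigma, cfg$qalb_log_sigma,
               cfg$serum_albumin_log_sigma, cfg$tnc_noise_sd, cfg$age_sd)
  if (any(spreads <= 0)) stop("spreads must be > 0")
  if (any(cfg$followup_median <= 5)) {
    stop("followup_median must exceed the 5-year eligibility floor")
  }
  if (any(cfg$index_median <= 0) || any(cfg$csf_median <= 0) ||
      cfg$qalb_median <= 0) {
    stop("medians must be > 0")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop("seed must be a single integer")
  }
  structure(cfg, class = "simulation_config")
}

# Per-group treatment label frequencies (including untreated).
treatment_table <- function(group) {
  if (group == "high") {
    c("None" = 5, "Fingolimod" = 2, "GA+IFN" = 1, "Interferon" = 5,
      "Natalizumab" = 2, "Ocrelizumab" = 2)
  } else {
    c("None" = 7, "Dimethyl fumarate" = 2, "Glatiramer acetate" = 3,
      "Interferon" = 6, "Natalizumab" = 1, "Ozanimod" = 1)
  }
}

# Substream id per patient: group blocks are spaced so enlarging one group
# never shifts another group's streams.
substream_id <- function(group, i) {
  offset <- c(low = 0, high = 1e6, indeterminate = 2e6)[[group]]
  offset + i
}

# Mix (seed, id) through a splitmix-style avalanche hash so per-patient
# substream seeds are decorrelated; structured seeds (consecutive
# integers) fed straight to the generator leave detectable correlation
# between patients' early draws.
patient_seed <- function(seed, id) {
  M <- 2147483647
  x <- (abs(as.numeric(seed)) * 2654435769 + as.numeric(id)) %% M
  for (i in 1:3) {
    x <- (x * 48271) %% M            # Lehmer step
    x <- bitwXor(as.integer(x), bitwShiftR(as.integer(x), 15))
    x <- as.numeric(x) %% M
  }
  as.integer(x)
}

# Midpoint of the two group values, used for the indeterminate arm.
mid <- function(x) mean(x)

#' Generate a synthetic CIS/RIS cohort
#'
#' Draws a cohort under a [simulation_config()]: per-group log-normal
#' biomarkers (correlated latent log index and log CSF CXCL13), serum
#' availability as a Bernoulli (serum CXCL13 is then derived from the
#' latent index, the CSF concentration and the albumin quotient, so the
#' recomputed index reproduces the latent one), Bernoulli clinical
#' outcomes, Poisson MRI surveillance with per-MRI lesion Bernoullis, and
#' a truncated linear TNC model. Fully reproducible from
#' `config$seed`; each patient has an independent substream.
#'
#' @param config A [simulation_config()].
#' @return A list of class `generated_cohort`: `records` (a validated
#'   cohort data frame, see [read_cohort()]) and `truth` (per-patient
#'   generating group, latent index and serum availability).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must come from simulation_config()")
  }
  plan <- rbind(
    if (config$n_low > 0)
      data.frame(group = "low", i = seq_len(config$n_low)),
    if (config$n_high > 0)
      data.frame(group = "high", i = seq_len(config$n_high)),
    if (config$n_indeterminate > 0)
      data.frame(group = "indeterminate", i = seq_len(config$n_indeterminate))
  )
  n <- if (is.null(plan)) 0L else nrow(plan)
  rec <- vector("list", n)
  tru <- vector("list", n)

  for (r in seq_len(n)) {
    g <- plan$group[r]
    id <- substream_id(g, plan$i[r])
    set.seed(patient_seed(config$seed, id))
    gi <- if (g == "indeterminate") NA else g   # index into per-group params
    par <- function(x) if (is.na(gi)) mid(x) else x[[gi]]

    # latent biomarkers
    if (g == "indeterminate") {
      index <- stats::runif(1, 20, 30)
      csf <- stats::runif(1, 5, 14)
    } else {
      z1 <- stats::rnorm(1)
      z2 <- config$index_csf_corr * z1 +
        sqrt(1 - config$index_csf_corr^2) * stats::rnorm(1)
      index <- exp(log(config$index_median[[gi]]) +
                     config$index_log_sigma[[gi]] * z1)
      csf <- exp(log(config$csf_median[[gi]]) +
                   config$csf_log_sigma[[gi]] * z2)
    }
    qalb <- exp(log(config$qalb_median) +
                  config$qalb_log_sigma * stats::rnorm(1))
    serum_albumin <- exp(log(config$serum_albumin_median) +
                           config$serum_albumin_log_sigma * stats::rnorm(1))
    csf_albumin <- qalb * serum_albumin
    serum_avail <- stats::runif(1) < par(config$serum_avail_prob)
    serum_cxcl13 <- if (serum_avail) csf / (index * qalb) else NA_real_

    # outcomes
    followup <- 5 + stats::rgamma(
      1, shape = 2,
      scale = (par(config$followup_median) - 5) /
        stats::qgamma(0.5, shape = 2))
    n_mris <- stats::rpois(1, par(config$mri_rate) * followup)
    n_lesion_mris <- stats::rbinom(1, n_mris,
                                   par(config$lesion_prob_per_mri))
    n_lesions <- if (n_lesion_mris > 0) {
      n_lesion_mris + sum(stats::rpois(n_lesion_mris,
                                       par(config$lesion_count_extra)))
    } else 0L
    cdms <- stats::runif(1) < par(config$cdms_prob)
    attack_any <- stats::runif(1) < par(config$attack_prob)
    n_attacks <- if (attack_any) {
      1L + stats::rpois(1, config$attack_extra_mean)
    } else 0L
    ocb <- stats::runif(1) < par(config$ocb_prob)
    tnc <- max(0, round(config$tnc_intercept + config$tnc_slope * csf +
                          stats::rnorm(1, 0, config$tnc_noise_sd)))

    # demographics
    age <- max(18, stats::rnorm(1, par(config$age_mean), par(config$age_sd)))
    sex <- if (stats::runif(1) < par(config$male_prob)) "male" else "female"
    diagnosis <- if (stats::runif(1) < par(config$cis_prob)) "CIS" else "RIS"
    tt <- treatment_table(if (g == "high") "high" else "low")
    treatment <- sample(names(tt), 1, prob = tt)

    pid <- sprintf("%s%04d", toupper(substr(g, 1, 1)), plan$i[r])
    rec[[r]] <- data.frame(
      patient_id = pid, diagnosis = diagnosis, age = age, sex = sex,
      treatment = treatment, csf_cxcl13 = csf,
      serum_cxcl13 = serum_cxcl13, csf_albumin = csf_albumin,
      serum_albumin = serum_albumin, albumin_unit = "mg/dL", tnc = tnc,
      converted_cdms = cdms, ocb_positive = ocb, n_attacks = n_attacks,
      n_mris = as.integer(n_mris),
      n_mris_with_new_lesions = as.integer(n_lesion_mris),
      n_new_or_enhancing_lesions = as.integer(n_lesions),
      followup_years = followup, study_eligible = TRUE,
      stringsAsFactors = FALSE)
    tru[[r]] <- data.frame(
      patient_id = pid, group = g, index_true = index,
      serum_available = serum_avail, stringsAsFactors = FALSE)
  }

  records <- if (n > 0) do.call(rbind, rec) else {
    stop("config generates an empty cohort")
  }
  truth <- do.call(rbind, tru)
  records$n_attacks <- as.integer(records$n_attacks)
  validate_cohort(records)
  structure(list(records = records, truth = truth),
            class = "generated_cohort")
}

#' Compare a generated cohort against its configured targets
#'
#' Summarises, per generating group, the empirical outcome rates and
#' biomarker medians against the configured targets, with a Monte-Carlo
#' tolerance at the realised group size: two binomial standard errors for
#' rates, and two asymptotic standard errors of the sample median
#' (1.2533 sigma / sqrt(n), on the log scale) for log-normal medians.
#' `flag` marks parameters whose deviation exceeds the tolerance; at
#' study-sized groups the tolerances are wide, at simulation scale they
#' tighten.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config The [simulation_config()] whose targets to check against.
#' @return A data frame: `parameter`, `group`, `target`, `observed`,
#'   `deviation`, `tolerance`, `scale` (probability or log-ratio), `flag`.
#' @export
calibration_report <- function(cohort, config) {
  stopifnot(inherits(cohort, "generated_cohort"),
            inherits(config, "simulation_config"))
  rows <- list()
  for (g in c("low", "high")) {
    in_g <- cohort$truth$group == g
    ng <- sum(in_g)
    if (ng == 0) next
    recs <- cohort$records[in_g, ]
    rate_row <- function(parameter, target, observed_count) {
      obs <- observed_count / ng
      tol <- 2 * sqrt(target * (1 - target) / ng)
      data.frame(parameter = parameter, group = g, target = target,
                 observed = obs, deviation = abs(obs - target),
                 tolerance = tol, scale = "probability",
                 flag = abs(obs - target) > tol)
    }
    med_row <- function(parameter, target, values, log_sigma) {
      obs <- stats::median(values)
      dev <- abs(log(obs / target))
      tol <- 2 * 1.2533 * log_sigma / sqrt(ng)
      data.frame(parameter = parameter, group = g, target = target,
                 observed = obs, deviation = dev, tolerance = tol,
                 scale = "log-ratio", flag = dev > tol)
    }
    rows <- c(rows, list(
      rate_row("cdms_prob", config$cdms_prob[[g]],
               sum(recs$converted_cdms)),
      rate_row("attack_prob", config$attack_prob[[g]],
               sum(recs$n_attacks >= 1)),
      rate_row("ocb_prob", config$ocb_prob[[g]], sum(recs$ocb_positive)),
      rate_row("serum_avail_prob", config$serum_avail_prob[[g]],
               sum(!is.na(recs$serum_cxcl13))),
      med_row("csf_median", config$csf_median[[g]], recs$csf_cxcl13,
              config$csf_log_sigma[[g]]),
      med_row("index_median", config$index_median[[g]],
              cohort$truth$index_true[in_g],
              config$index_log_sigma[[g]])))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
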