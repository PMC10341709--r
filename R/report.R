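# 32-bit FNV-1a fingerprint (hex) of a deparsed object, for provenance.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261 %% 2147483648
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

#' Reference CIS/RIS cohort built from published group-level counts
#'
#' A deterministic 37-patient cohort reproducing the group-level counts of
#' the motivating five-year CIS/RIS follow-up cohort: 20 index-low
#' patients (2 CDMS converters, 1 with clinical attacks, 13 OCB-positive,
#' 6 with serum available, 14 with lesion-free MRIs, 1 with one
#' lesion-positive MRI, 5 with no MRIs performed, 16 CIS / 4 RIS) and 17
#' index-high patients (14 converters, 9 with attacks, 16 OCB-positive, 7
#' with serum available, 4 lesion-free, 5 with one and 8 with more than
#' one lesion-positive MRI, all CIS). Biomarker values are fixed at the
#' group medians, so the stratification reproduces the intended group
#' sizes exactly. Patient-level joint structure beyond these margins is
#' arbitrary (attributes are assigned to the first k patients of a group),
#' which leaves every marginal count, rate, 2x2 table and exact test
#' identical to the published ones.
#'
#' @return A validated cohort data frame of 37 patients.
#' @export
reference_cohort <- function() {
  first <- function(n, k) seq_len(n) <= k
  build <- function(n, prefix, csf, index, serum_k, cdms_k, attack_k,
                    ocb_k, one_lesion_k, multi_lesion_k, no_mri_k, ris_k,
                    male_k, age, followup) {
    qalb <- 0.005
    serum_alb <- 4000
    serum_avail <- first(n, serum_k)
    # serum CXCL13 back-solved so the computed index equals the group value
    serum_cx <- ifelse(serum_avail, csf / (index * qalb), NA_real_)
    no_mri <- rev(first(n, no_mri_k))          # from the tail: keeps the
    multi <- first(n, multi_lesion_k)          # lesion/no-MRI sets disjoint
    one <- !multi & first(n, multi_lesion_k + one_lesion_k)
    n_mris <- ifelse(no_mri, 0L, ifelse(multi, 5L, 4L))
    lesion_mris <- ifelse(multi, 2L, ifelse(one, 1L, 0L))
    data.frame(
      patient_id = sprintf("%s%02d", prefix, seq_len(n)),
      diagnosis = ifelse(rev(first(n, ris_k)), "RIS", "CIS"),
      age = age, sex = ifelse(first(n, male_k), "male", "female"),
      treatment = "None", csf_cxcl13 = csf, serum_cxcl13 = serum_cx,
      csf_albumin = qalb * serum_alb, serum_albumin = serum_alb,
      albumin_unit = "mg/dL",
      tnc = round(2 + 0.3 * csf) + (seq_len(n) %% 5),
      converted_cdms = first(n, cdms_k), ocb_positive = first(n, ocb_k),
      n_attacks = as.integer(first(n, attack_k)),
      n_mris = n_mris, n_mris_with_new_lesions = lesion_mris,
      n_new_or_enhancing_lesions = lesion_mris,
      followup_years = followup, study_eligible = TRUE,
      stringsAsFactors = FALSE)
  }
  low <- build(20, "L", csf = 2.02, index = 5.99, serum_k = 6,
               cdms_k = 2, attack_k = 1, ocb_k = 13, one_lesion_k = 1,
               multi_lesion_k = 0, no_mri_k = 5, ris_k = 4, male_k = 3,
               age = 41.9, followup = 6.81)
  high <- build(17, "H", csf = 17.83, index = 67.07, serum_k = 7,
                cdms_k = 14, attack_k = 9, ocb_k = 16, one_lesion_k = 5,
                multi_lesion_k = 8, no_mri_k = 0, ris_k = 0, male_k = 3,
                age = 35.5, followup = 6.35)
  cohort <- rbind(low, high)
  validate_cohort(cohort)
  cohort
}

# One summary row not produced by summarize_variable (e.g. the n row).
plain_row <- function(variable, cells, levels_g) {
  row <- data.frame(variable = variable, stringsAsFactors = FALSE)
  for (i in seq_along(levels_g)) row[[paste0("group_", levels_g[i])]] <-
      cells[i]
  row$p_value <- NA_real_
  row$p_label <- ""
  row$stars <- ""
  row$method <- "none"
  row
}

#' Run the full CXCL13-index analysis over a cohort
#'
#' Ties the pipeline together: stratifies the cohort under a threshold
#' policy, builds the group-comparison summary table (Kruskal-Wallis for
#' continuous variables, two-sided Fisher exact for binary ones,
#' categorical variables listed without a test), cross-tabulates the
#' stratification against each MS-activity outcome with exact diagnostic
#' performance intervals, and fits the CSF CXCL13 versus total nucleated
#' cell count regression. Indeterminate patients are counted and reported
#' but excluded from the group comparisons and confusion tables. The
#' result is deterministic given the cohort and options.
#'
#' @param cohort A validated cohort data frame.
#' @param policy A [threshold_policy()].
#' @param conf_level Confidence level for exact intervals. Default 0.95.
#' @return An object of class `cxcl13_report`: `summary_table`,
#'   `group_sizes`, `n_indeterminate`, `confusion` (per-outcome list with
#'   `counts` and `performance`), `regression`, `provenance`.
#' @export
run_analysis <- function(cohort, policy = threshold_policy(),
                         conf_level = 0.95) {
  validate_cohort(cohort)
  strata <- stratify_cohort(cohort, policy)
  group <- strata$group[match(cohort$patient_id, strata$patient_id)]
  keep <- group %in% c("low", "high")
  gg <- factor(as.character(group[keep]), levels = c("low", "high"))
  cc <- cohort[keep, ]
  ss <- strata[keep, ]

  sv <- function(values, kind, variable) {
    summarize_variable(values, gg, kind, variable)
  }
  mri_cat <- ifelse(cc$n_mris == 0, "No MRIs performed",
                    ifelse(cc$n_mris_with_new_lesions == 0, "None",
                           ifelse(cc$n_mris_with_new_lesions == 1, "One",
                                  "More than one")))
  pct_lesions <- 100 * percent_mris_with_new_lesions(
    cc$n_mris_with_new_lesions, cc$n_mris)

  summary_table <- rbind(
    plain_row("n", as.character(table(gg)), levels(gg)),
    sv(ss$index, "continuous_median_iqr", "CXCL13 index (median [IQR])"),
    sv(!is.na(cc$serum_cxcl13), "binary", "Serum available (%)"),
    sv(cc$csf_cxcl13, "continuous_median_iqr",
       "CSF CXCL13 pg/mL (median [IQR])"),
    sv(cc$age, "continuous_mean_sd", "Age (mean (SD))"),
    sv(cc$sex == "male", "binary", "Sex = male (%)"),
    sv(cc$diagnosis, "categorical", "Diagnosis (%)"),
    sv(cc$followup_years, "continuous_median_iqr",
       "Follow-up years (median [IQR])"),
    sv(cc$converted_cdms, "binary", "Converted to CDMS (%)"),
    sv(cc$ocb_positive, "binary", "OCB positive (%)"),
    sv(cc$n_attacks >= 1, "binary", "One or more clinical attacks (%)"),
    sv(as.numeric(cc$n_mris), "continuous_median_iqr",
       "Number of MRIs during follow-up (median [IQR])"),
    sv(mri_cat, "categorical", "Number of MRIs with new lesions (%)"),
    sv(as.numeric(cc$n_new_or_enhancing_lesions), "continuous_mean_sd",
       "Number of new or enhancing lesions (mean (SD))"),
    sv(pct_lesions, "continuous_median_iqr",
       "Percent of MRIs with new lesions (median [IQR])"),
    sv(cc$treatment, "categorical", "Treatment (%)"))
  rownames(summary_table) <- NULL

  confusion <- lapply(c(cdms = "cdms", attacks = "attacks",
                        new_lesions = "new_lesions"), function(oc) {
    tab <- build_confusion(cohort, strata, oc)
    list(counts = tab,
         performance = diagnostic_performance(tab, conf_level))
  })

  regression <- if (sum(!is.na(cohort$tnc)) >= 3 &&
                    stats::var(cohort$csf_cxcl13[!is.na(cohort$tnc)]) > 0) {
    linear_fit_r2(cohort$csf_cxcl13, cohort$tnc)
  } else NULL

  structure(list(
    summary_table = summary_table,
    group_sizes = c(low = sum(gg == "low"), high = sum(gg == "high")),
    n_indeterminate = sum(!keep),
    confusion = confusion,
    regression = regression,
    provenance = list(
      package_version = as.character(utils::packageVersion("cxcl13index")),
      n_records = nrow(cohort),
      policy = unclass(policy),
      conf_level = conf_level,
      config_hash = config_hash(list(unclass(policy), conf_level)))
  ), class = "cxcl13_report")
}

# Markdown pipe table from a data frame of character/numeric cells.
md_table <- function(df) {
  cells <- vapply(df, function(col) as.character(col), character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) {
    paste0("| ", paste(ifelse(is.na(r), "", r), collapse = " | "), " |")
  })
  paste(c(header, sep, body), collapse = "\n")
}

# Diagnostic-performance section as one data frame (outcome rows,
# sensitivity/specificity and count columns, optionally with CIs).
performance_frame <- function(report, with_ci = TRUE) {
  rows <- lapply(names(report$confusion), function(oc) {
    entry <- report$confusion[[oc]]
    perf <- entry$performance
    pick <- function(m, f) perf[[f]][perf$measure == m]
    base <- data.frame(
      outcome = oc,
      sensitivity = pick("sensitivity", "estimate"),
      specificity = pick("specificity", "estimate"),
      tp = entry$counts$tp, fp = entry$counts$fp,
      tn = entry$counts$tn, fn = entry$counts$fn)
    if (with_ci) {
      base$sensitivity_lower <- pick("sensitivity", "lower")
      base$sensitivity_upper <- pick("sensitivity", "upper")
      base$specificity_lower <- pick("specificity", "lower")
      base$specificity_upper <- pick("specificity", "upper")
      base$ppv <- pick("ppv", "estimate")
      base$npv <- pick("npv", "estimate")
    }
    base
  })
  do.call(rbind, rows)
}

#' Render an analysis report
#'
#' Renders a [run_analysis()] report as Markdown (summary table,
#' diagnostic-performance table with seven columns per row, regression
#' and provenance), as TSV (the diagnostic-performance table with exact
#' confidence-interval columns, numerically typed), or as JSON (lossless
#' for round-tripping). p-values below 0.001 print as "<0.001";
#' significance marks follow * p<0.05, ** p<0.01, *** p<0.001.
#'
#' @param report A `cxcl13_report` from [run_analysis()].
#' @param format One of `"markdown"`, `"tsv"`, `"json"`.
#' @param path Optional output file; when given the rendering is written
#'   there.
#' @return The rendered text, invisibly a single string.
#' @export
render_report <- function(report, format = c("markdown", "tsv", "json"),
                          path = NULL) {
  stopifnot(inherits(report, "cxcl13_report"))
  format <- match.arg(format)
  text <- switch(format,
    markdown = {
      st <- report$summary_table
      disp <- data.frame(
        Variable = st$variable, check.names = FALSE,
        stringsAsFactors = FALSE)
      for (col in grep("^group_", names(st), value = TRUE)) {
        disp[[sub("^group_", "", col)]] <- st[[col]]
      }
      disp[["p-value"]] <- st$p_label
      disp[["sig"]] <- st$stars
      perf <- performance_frame(report, with_ci = TRUE)
      perf_disp <- data.frame(
        Outcome = perf$outcome,
        Sensitivity = sprintf("%.2f (%.2f-%.2f)", perf$sensitivity,
                              perf$sensitivity_lower,
                              perf$sensitivity_upper),
        Specificity = sprintf("%.2f (%.2f-%.2f)", perf$specificity,
                              perf$specificity_lower,
                              perf$specificity_upper),
        TP = perf$tp, FP = perf$fp, TN = perf$tn, FN = perf$fn)
      reg <- if (!is.null(report$regression)) {
        sprintf(
          "OLS of TNC on CSF CXCL13: slope %.4g, R^2 = %.3f, p = %s (n = %d)",
          report$regression$slope, report$regression$r_squared,
          format_p(report$regression$p_value_slope), report$regression$n)
      } else "not computed (insufficient TNC data)"
      paste0(
        "# CXCL13 index analysis\n\n",
        sprintf("Groups: %d low, %d high; %d indeterminate excluded.\n\n",
                report$group_sizes[["low"]], report$group_sizes[["high"]],
                report$n_indeterminate),
        "## Group comparison\n\n", md_table(disp), "\n\n",
        "## Diagnostic performance\n\n", md_table(perf_disp), "\n\n",
        "## CSF CXCL13 vs total nucleated cells\n\n", reg, "\n\n",
        sprintf("Provenance: cxcl13index %s, config %s\n",
                report$provenance$package_version,
                report$provenance$config_hash))
    },
    tsv = {
      perf <- performance_frame(report, with_ci = TRUE)
      con <- textConnection("tsv_out", "w", local = TRUE)
      utils::write.table(perf, con, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      close(con)
      paste0(paste(tsv_out, collapse = "\n"), "\n")
    },
    json = {
      payload <- list(
        summary_table = report$summary_table,
        group_sizes = as.list(report$group_sizes),
        n_indeterminate = report$n_indeterminate,
        confusion = lapply(report$confusion, function(e) {
          list(counts = unclass(e$counts)[c("tp", "fp", "tn", "fn",
                                            "outcome", "n_excluded")],
               performance = e$performance)
        }),
        regression = if (is.null(report$regression)) NULL else
          unclass(report$regression),
        provenance = report$provenance)
      as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                    digits = NA, null = "null"))
    })
  if (!is.null(path)) writeLines(text, path)
  invisible(text)
}

#' @export
print.cxcl13_report <- function(x, ...) {
  cat(render_report(x, "markdown"))
  invisible(x)
}
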