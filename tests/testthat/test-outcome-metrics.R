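test_that("outcome predicates derive the binary endpoints", {
  cohort <- small_cohort()
  expect_equal(outcome_predicate(cohort, "cdms"), c(TRUE, FALSE, TRUE))
  expect_equal(outcome_predicate(cohort, "attacks"), c(TRUE, FALSE, TRUE))
  # patient 2 had no MRIs performed: counts as outcome-negative
  expect_equal(outcome_predicate(cohort, "new_lesions"),
               c(TRUE, FALSE, TRUE))
  expect_error(outcome_predicate(cohort, "edss"))
})

test_that("confusion tables reproduce the reference cohort counts", {
  cohort <- reference_cohort()
  strata <- stratify_cohort(cohort)

  cdms <- build_confusion(cohort, strata, "cdms")
  expect_equal(c(cdms$tp, cdms$fp, cdms$tn, cdms$fn), c(14, 3, 18, 2))

  lesions <- build_confusion(cohort, strata, "new_lesions")
  expect_equal(c(lesions$tp, lesions$fp, lesions$tn, lesions$fn),
               c(13, 4, 19, 1))

  attacks <- build_confusion(cohort, strata, "attacks")
  expect_equal(c(attacks$tp, attacks$fp, attacks$tn, attacks$fn),
               c(9, 8, 19, 1))
})

test_that("confusion cells conserve the non-indeterminate patient count", {
  cfg <- simulation_config(n_low = 30L, n_high = 25L, n_indeterminate = 9L,
                           seed = 7)
  cohort <- generate_cohort(cfg)$records
  strata <- stratify_cohort(cohort)
  n_kept <- sum(strata$group %in% c("low", "high"))
  for (oc in c("cdms", "attacks", "new_lesions")) {
    tab <- build_confusion(cohort, strata, oc)
    expect_equal(tab$tp + tab$fp + tab$tn + tab$fn, n_kept)
    expect_equal(tab$n_excluded, nrow(cohort) - n_kept)
  }
  expect_error(build_confusion(cohort, strata[-1, ], "cdms"),
               "no stratum")
})

test_that("empty cohorts give all-zero confusion tables", {
  empty <- small_cohort()[0, ]
  tab <- build_confusion(empty, stratify_cohort(empty), "cdms")
  expect_equal(c(tab$tp, tab$fp, tab$tn, tab$fn), c(0, 0, 0, 0))
})

test_that("diagnostic performance uses the standard formulas", {
  tab <- structure(list(tp = 14, fp = 3, tn = 18, fn = 2, outcome = "cdms",
                        n_excluded = 0), class = "confusion_table")
  perf <- diagnostic_performance(tab)
  est <- function(m) perf$estimate[perf$measure == m]
  expect_equal(est("sensitivity"), 14 / 16)
  expect_equal(est("specificity"), 18 / 21)
  expect_equal(est("ppv"), 14 / 17)
  expect_equal(est("npv"), 18 / 20)
  expect_true(all(perf$defined))
  expect_true(all(perf$lower <= perf$estimate & perf$estimate <= perf$upper))
})

test_that("exact intervals match the Clopper-Pearson oracle", {
  # closed form for x = n: lower bound (alpha/2)^(1/n)
  tab <- structure(list(tp = 5, fp = 0, tn = 0, fn = 0, outcome = "cdms",
                        n_excluded = 0), class = "confusion_table")
  perf <- diagnostic_performance(tab)
  sens <- perf[perf$measure == "sensitivity", ]
  expect_equal(sens$estimate, 1)
  expect_equal(sens$lower, 0.025^(1 / 5), tolerance = 1e-10)
  # against binom.test on assorted cells
  for (cell in list(c(14, 2), c(3, 18), c(1, 0), c(0, 7))) {
    x <- cell[1]; n <- sum(cell)
    ci <- binom.test(x, n)$conf.int
    got <- cxcl13index:::clopper_pearson(x, n)
    expect_equal(unname(got), as.numeric(ci), tolerance = 1e-10)
  }
})

test_that("zero denominators are flagged undefined, not NaN", {
  tab <- structure(list(tp = 0, fp = 4, tn = 6, fn = 0, outcome = "cdms",
                        n_excluded = 0), class = "confusion_table")
  perf <- diagnostic_performance(tab)
  sens <- perf[perf$measure == "sensitivity", ]
  expect_false(sens$defined)
  expect_true(is.na(sens$estimate))
  expect_false(any(is.nan(unlist(perf[sapply(perf, is.numeric)]))))
})

test_that("transposing the table swaps sensitivity and specificity", {
  set.seed(4)
  for (i in 1:20) {
    cells <- rpois(4, 8)
    tab <- structure(list(tp = cells[1], fp = cells[2], tn = cells[3],
                          fn = cells[4], outcome = "cdms", n_excluded = 0),
                     class = "confusion_table")
    swapped <- structure(list(tp = cells[3], fp = cells[4], tn = cells[1],
                              fn = cells[2], outcome = "cdms",
                              n_excluded = 0), class = "confusion_table")
    p1 <- diagnostic_performance(tab)
    p2 <- diagnostic_performance(swapped)
    expect_equal(p1$estimate[p1$measure == "sensitivity"],
                 p2$estimate[p2$measure == "specificity"])
    expect_equal(p1$lower[p1$measure == "sensitivity"],
                 p2$lower[p2$measure == "specificity"])
  }
})

test_that("screening-adjusted MRI metric guards the zero-MRI case", {
  expect_equal(percent_mris_with_new_lesions(2, 6), 1 / 3)
  expect_equal(percent_mris_with_new_lesions(0, 4), 0)
  expect_true(is.na(percent_mris_with_new_lesions(0, 0)))
  expect_error(percent_mris_with_new_lesions(3, 2), "exceeds")
})

test_that("sensitivity converges to the mixture limit at large n", {
  cfg <- simulation_config(n_low = 5000L, n_high = 5000L, seed = 11)
  gc <- generate_cohort(cfg)
  # truth-based strata isolate the confusion arithmetic from classifier noise
  strata <- data.frame(
    patient_id = gc$truth$patient_id,
    group = factor(gc$truth$group, levels = c("low", "high", "indeterminate")))
  tab <- build_confusion(gc$records, strata, "cdms")
  perf <- diagnostic_performance(tab)
  p_h <- 0.824; p_l <- 0.100
  n_pos <- 5000 * p_h + 5000 * p_l
  limit <- (5000 * p_h) / n_pos
  se <- sqrt(limit * (1 - limit) / n_pos)
  got <- perf$estimate[perf$measure == "sensitivity"]
  expect_lt(abs(got - limit), 2 * se)
})
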