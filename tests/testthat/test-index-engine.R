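test_that("compute_index reproduces the quotient arithmetic", {
  one <- compute_index(10, 100, 20, 4000)  # q_alb = 0.005
  expect_equal(one$q_cxcl13, 0.1)
  expect_equal(one$q_albumin, 0.005)
  expect_equal(one$index, 20)

  # randomized positive inputs against the direct (a/b)/(c/d) oracle
  set.seed(1)
  a <- rlnorm(200); b <- rlnorm(200); c <- rlnorm(200); d <- rlnorm(200)
  got <- compute_index(a, b, c, d)
  expect_equal(got$index, (a / b) / (c / d), tolerance = 1e-12)
})

test_that("missing inputs propagate as absent, not zero", {
  res <- compute_index(10, NA, 20, 4000)
  expect_true(is.na(res$q_cxcl13))
  expect_true(is.na(res$index))
  expect_equal(res$q_albumin, 0.005)
  expect_error(compute_index(c(10, NA)), "csf_cxcl13")
  expect_error(compute_index(10, -5, 20, 4000), "serum_cxcl13")
})

test_that("classification follows the dual threshold system", {
  pol <- threshold_policy()
  cls <- classify_index(c(67.07, 5.99, 25), csf_cxcl13 = 1, policy = pol)
  expect_equal(as.character(cls$group), c("high", "low", "indeterminate"))
  expect_true(all(cls$basis == "index"))

  # CSF-only fallback when the index is absent
  csf <- classify_index(rep(NA_real_, 3), c(17.83, 2.02, 8), pol)
  expect_equal(as.character(csf$group), c("high", "low", "indeterminate"))
  expect_true(all(csf$basis == "csf_only"))

  # values exactly on a cut are indeterminate (strict above/below reading)
  ties <- classify_index(c(30, 20, NA, NA), c(1, 1, 14, 5), pol)
  expect_true(all(ties$group == "indeterminate"))
})

test_that("classification is monotone in the index", {
  set.seed(2)
  idx <- sort(rlnorm(500, log(25), 1.5))
  ord <- c(low = 1L, indeterminate = 2L, high = 3L)
  g <- ord[as.character(classify_index(idx, 1)$group)]
  expect_true(all(diff(g) >= 0))
})

test_that("the index is invariant under common rescaling of each pair", {
  set.seed(3)
  a <- rlnorm(50); b <- rlnorm(50); c <- rlnorm(50); d <- rlnorm(50)
  base <- compute_index(a, b, c, d)$index
  # mg/dL -> g/L on the albumin pair; assay recalibration on CXCL13 pair
  rescaled <- compute_index(3.7 * a, 3.7 * b, 0.01 * c, 0.01 * d)$index
  expect_equal(rescaled, base, tolerance = 1e-12)
})

test_that("stratify_cohort classifies every record and keeps indeterminates", {
  cohort <- small_cohort()
  # indices: (10/100)/0.005 = 20 -> indeterminate tie; make it high
  cohort$serum_cxcl13[1] <- 29.85  # (10/29.85)/0.005 = 67.0
  strata <- stratify_cohort(cohort)
  expect_equal(nrow(strata), 3L)
  expect_equal(as.character(strata$group[1]), "high")
  expect_equal(as.character(strata$basis[2]), "csf_only")
  expect_equal(as.character(strata$group[2]), "low")     # csf 2.02 < 5
  expect_equal(as.character(strata$group[3]), "high")    # index 59.4

  all_csf <- small_cohort()
  all_csf$serum_cxcl13 <- NA_real_
  expect_true(all(stratify_cohort(all_csf)$basis == "csf_only"))

  empty <- stratify_cohort(small_cohort()[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("index rule wins over the CSF-only rule when both apply", {
  cohort <- small_cohort()
  # csf 17.83 (> 14, CSF rule says high) but index (17.83/60)/(18/3900)
  # = 64.4 -> still index basis; now force a low index with high CSF
  cohort$serum_cxcl13[3] <- 20000
  strata <- stratify_cohort(cohort)
  expect_equal(as.character(strata$basis[3]), "index")
  expect_equal(as.character(strata$group[3]), "low")
})

test_that("CSF-only rule agrees with the index rule outside the CSF band", {
  cfg <- simulation_config(n_low = 2000L, n_high = 2000L,
                           serum_avail_prob = c(low = 1, high = 1),
                           seed = 1)
  cohort <- generate_cohort(cfg)$records
  ha <- harmonization_agreement(cohort)
  expect_gt(ha$n_eligible, 1000)
  expect_gte(ha$agreement, 0.90)
  # the disagreement rate is the reported complement
  expect_equal(ha$agreement + ha$disagreement, 1)
})
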