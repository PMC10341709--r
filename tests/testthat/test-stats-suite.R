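test_that("Fisher exact reproduces known two-sided p-values", {
  expect_equal(round(fisher_exact_two_sided(9, 8, 1, 19)$p_value, 3), 0.002)
  expect_equal(round(fisher_exact_two_sided(16, 1, 13, 7)$p_value, 3), 0.048)
  expect_lt(fisher_exact_two_sided(14, 3, 2, 18)$p_value, 0.001)
  # two tables share these margins, each with probability 1/2
  expect_equal(fisher_exact_two_sided(1, 0, 0, 1)$p_value, 1)
  expect_equal(fisher_exact_two_sided(matrix(c(9, 8, 1, 19), 2,
                                             byrow = TRUE))$p_value,
               fisher_exact_two_sided(9, 8, 1, 19)$p_value)
})

test_that("Fisher exact matches stats::fisher.test on random tables", {
  set.seed(5)
  for (i in 1:100) {
    cells <- rpois(4, sample(1:15, 1))
    if (sum(cells) == 0) next
    mine <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10,
                 info = paste(cells, collapse = ","))
  }
})

test_that("zero margins give the degenerate p = 1", {
  res <- fisher_exact_two_sided(0, 0, 3, 4)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "total")
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p is invariant under simultaneous row and column swaps", {
  set.seed(6)
  for (i in 1:50) {
    cells <- rpois(4, 6)
    if (sum(cells) == 0) next
    p1 <- fisher_exact_two_sided(cells[1], cells[2], cells[3],
                                 cells[4])$p_value
    p2 <- fisher_exact_two_sided(cells[4], cells[3], cells[2],
                                 cells[1])$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("hypergeometric support probabilities are normalized", {
  set.seed(7)
  for (i in 1:50) {
    m1 <- sample(1:30, 1); m2 <- sample(1:30, 1)
    k <- sample(1:(m1 + m2 - 1), 1)
    support <- max(0, k - m2):min(k, m1)
    total <- sum(exp(cxcl13index:::hypergeom_log_pmf(support, m1, m2, k)))
    expect_lt(abs(total - 1), 1e-12)
  }
})

test_that("Kruskal-Wallis reproduces the hand-ranked H statistic", {
  # ranks 1..6: R1 = 6, R2 = 15 -> H = 12/(6*7) * (36/3 + 225/3) - 3*7
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(round(res$statistic, 3), 3.857)
  expect_equal(res$p_value,
               stats::pchisq(res$statistic, df = 1, lower.tail = FALSE))
  # identical pooled constant data: no rank variation
  flat <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(kruskal_wallis(list(numeric(0), 1:3)), "empty")
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
})

test_that("two-group Kruskal-Wallis matches the rank-sum approximation", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(15, mean = runif(1, -1, 1))
    p_kw <- kruskal_wallis(list(x, y))$p_value
    p_ws <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    expect_equal(p_kw, p_ws, tolerance = 1e-10)
  }
})

test_that("the linear fit recovers exact and hand-computed R-squared", {
  x <- c(1, 2, 3, 4, 5)
  exact <- linear_fit_r2(x, 2 * x + 1)
  expect_equal(exact$r_squared, 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)

  y <- c(2.1, 3.9, 6.2, 7.8, 10.5)
  fit <- linear_fit_r2(x, y)
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  ss_res <- sum((y - alpha - beta * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(fit$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_equal(fit$slope, beta, tolerance = 1e-12)

  expect_error(linear_fit_r2(rep(1, 5), 1:5), "variance")
  expect_error(linear_fit_r2(1:2, 1:2), "n >= 3")
})

test_that("independent x and y give near-zero R-squared at large n", {
  set.seed(9)
  fit <- linear_fit_r2(rnorm(1000), rnorm(1000))
  expect_lt(fit$r_squared, 0.02)
  expect_true(fit$p_value_slope >= 0 && fit$p_value_slope <= 1)
})

test_that("summary rows format counts, medians and means as published", {
  group <- factor(rep(c("low", "high"), c(20, 17)), levels = c("low", "high"))
  ocb <- c(rep(TRUE, 13), rep(FALSE, 7), rep(TRUE, 16), FALSE)
  row <- summarize_variable(ocb, group, "binary", "OCB positive (%)")
  expect_equal(row$group_low, "13 (65.0)")
  expect_equal(row$group_high, "16 (94.1)")
  expect_equal(round(row$p_value, 3), 0.048)
  expect_equal(row$stars, "*")

  const <- summarize_variable(rep(4.2, 37), group, "continuous_median_iqr",
                              "flat")
  expect_equal(const$group_low, const$group_high)
  expect_equal(const$p_value, 1)

  set.seed(10)
  age <- c(rnorm(20, 41.89, 12.27), rnorm(17, 35.51, 10.51))
  mean_row <- summarize_variable(age, group, "continuous_mean_sd", "Age")
  expect_match(mean_row$group_low, "^-?[0-9]+\\.[0-9]{2} \\([0-9]+\\.[0-9]{2}\\)$")

  cat_rows <- summarize_variable(rep(c("CIS", "RIS"), c(30, 7)), group,
                                 "categorical", "Diagnosis (%)")
  expect_equal(nrow(cat_rows), 2L)
  expect_true(all(is.na(cat_rows$p_value)))

  expect_error(summarize_variable(letters[1:37], group, "binary", "x"),
               "logical")
})
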