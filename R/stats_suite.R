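# Log PMF of the hypergeometric distribution over a 2x2 table's support:
# x successes in the first column out of row margins m1, m2, with column-1
# margin k. Computed via lgamma so large margins stay finite.
hypergeom_log_pmf <- function(x, m1, m2, k) {
  n <- m1 + m2
  lgamma(m1 + 1) - lgamma(x + 1) - lgamma(m1 - x + 1) +
    lgamma(m2 + 1) - lgamma(k - x + 1) - lgamma(m2 - k + x + 1) -
    (lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact test of association in a 2x2 contingency table with both margins
#' fixed. The p-value is the sum, over the full hypergeometric support, of
#' the probabilities of all tables at least as extreme as the one observed
#' — i.e. whose point probability does not exceed that of the observed
#' table (the standard two-sided rule). Point probabilities are computed
#' on the log scale via `lgamma` and accumulated with Kahan compensated
#' summation; a relative slack of 1e-7 guards ties against floating-point
#' noise.
#'
#' @param x A 2x2 matrix of non-negative counts, or the count `a` (row 1,
#'   column 1) when `b`, `c`, `d` are given separately.
#' @param b,c,d Remaining cells, row-wise, when `x` is scalar.
#' @return A list of class `cx_test`: `p_value`, `method`, `n` (table
#'   total) and `degenerate` (`TRUE` when a zero margin forces p = 1).
#' @examples
#' fisher_exact_two_sided(matrix(c(9, 8, 1, 19), 2, byrow = TRUE))$p_value
#' @export
fisher_exact_two_sided <- function(x, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("x must be a 2x2 matrix")
    a <- x[1, 1]; b <- x[1, 2]; c <- x[2, 1]; d <- x[2, 2]
  } else {
    a <- x
    if (is.null(b) || is.null(c) || is.null(d)) {
      stop("supply a 2x2 matrix or all four cells")
    }
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  n <- sum(cells)
  if (n < 1) stop("table total must be >= 1")

  m1 <- a + b   # row-1 margin
  m2 <- c + d   # row-2 margin
  k  <- a + c   # column-1 margin
  out <- list(statistic = NA_real_, p_value = 1,
              method = "two-sided Fisher exact (hypergeometric enumeration)",
              n = n, degenerate = FALSE)
  class(out) <- "cx_test"
  if (m1 == 0 || m2 == 0 || k == 0 || k == n) {
    out$degenerate <- TRUE
    return(out)
  }

  support <- max(0, k - m2):min(k, m1)
  log_p <- hypergeom_log_pmf(support, m1, m2, k)
  log_obs <- log_p[support == a]
  include <- log_p <= log_obs + 1e-7   # relative slack on the log scale

  # Kahan compensated summation of the included probabilities
  s <- 0; comp <- 0
  for (lp in log_p[include]) {
    y <- exp(lp) - comp
    t <- s + y
    comp <- (t - s) - y
    s <- t
  }
  out$p_value <- min(1, s)
  out
}

#' @export
print.cx_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic)) cat(sprintf("  statistic = %.4g\n", x$statistic))
  cat(sprintf("  p = %s, n = %d%s\n", format_p(x$p_value), x$n,
              if (isTRUE(x$degenerate)) " (degenerate margin)" else ""))
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' Compares two or more groups of a continuous or ordinal variable by the
#' Kruskal-Wallis H statistic with tie correction, with the p-value from
#' the chi-square approximation on k - 1 degrees of freedom (delegates to
#' [stats::kruskal.test()]).
#'
#' @param groups A list of two or more numeric vectors, each non-empty.
#' @return A list of class `cx_test` with `statistic` (H), `p_value`,
#'   `method`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("groups must be a list of >= 2 numeric vectors")
  }
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  n <- sum(lengths(groups))
  if (n < 3L) stop("total n must be >= 3")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    # all observations tied: no rank variation, H = 0
    res <- list(statistic = 0, p_value = 1)
  } else {
    kt <- stats::kruskal.test(groups)
    res <- list(statistic = unname(kt$statistic), p_value = kt$p.value)
  }
  structure(list(statistic = res$statistic, p_value = res$p_value,
                 method = "Kruskal-Wallis rank-sum (tie-corrected)", n = n),
            class = "cx_test")
}

#' Ordinary least-squares fit with R-squared
#'
#' Fits `y ~ x` by ordinary least squares and reports the slope,
#' intercept, coefficient of determination `R^2 = 1 - SS_res/SS_tot` and
#' the two-sided t-test p-value for the slope. Used for the CSF CXCL13
#' versus total nucleated cell count relationship.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; `x` must vary.
#' @return A list of class `fit_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value_slope`, `n`.
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need n >= 3 complete pairs")
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exact fit; R^2 = 1 is a legitimate result here
  sm <- suppressWarnings(summary(fit))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value_slope = sm$coefficients[2, 4],
    n = length(x)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope = %.4g, intercept = %.4g\n", x$n,
              x$slope, x$intercept))
  cat(sprintf("  R^2 = %.3f, slope p = %s\n", x$r_squared,
              format_p(x$p_value_slope)))
  invisible(x)
}

# p-value rendering used across reports: 3 d.p. with a "<0.001" floor.
format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

# Cohort-table significance marks.
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

fmt_num <- function(x, digits = 2) {
  formatC(x, format = "f", digits = digits)
}

# "k (pct)" cell; an empty group prints "0 (-)" instead of a NaN percent.
count_pct_cell <- function(counts, totals) {
  ifelse(totals > 0,
         sprintf("%d (%s)", as.integer(counts),
                 fmt_num(100 * counts / totals, 1)),
         "0 (-)")
}

#' Summarise one variable across stratification groups
#'
#' Produces one row of a cohort summary table: a formatted cell per group
#' plus the group-comparison test appropriate to the variable kind.
#' Continuous kinds are compared by Kruskal-Wallis; binary variables by
#' the two-sided Fisher exact test; categorical variables with more than
#' two levels are listed without a p-value.
#'
#' @param values The variable: numeric for continuous kinds, logical for
#'   binary, character/factor for categorical. `NA` values are dropped
#'   from summaries (and from binary denominators).
#' @param group Group label per observation; levels define column order.
#' @param kind One of `"continuous_median_iqr"`, `"continuous_mean_sd"`,
#'   `"binary"`, `"categorical"`.
#' @param variable Row label for the output.
#' @return A data frame with columns `variable`, one formatted column per
#'   group level, `p_value`, `p_label`, `stars`, `method`. Categorical
#'   variables yield one row per level.
#' @export
summarize_variable <- function(values, group,
                               kind = c("continuous_median_iqr",
                                        "continuous_mean_sd",
                                        "binary", "categorical"),
                               variable = "") {
  kind <- match.arg(kind)
  if (length(values) != length(group)) {
    stop("values and group must have equal length")
  }
  # supplied factor levels are kept even when empty, so a degenerate
  # cohort (one group unpopulated) still yields a full-width table
  group <- if (is.factor(group)) group else factor(group)
  levels_g <- levels(group)
  split_v <- split(values, group)

  cell_names <- paste0("group_", levels_g)
  make_row <- function(variable, cells, p, method) {
    row <- data.frame(variable = variable, stringsAsFactors = FALSE)
    for (i in seq_along(cells)) row[[cell_names[i]]] <- cells[i]
    row$p_value <- p
    row$p_label <- if (is.na(p)) "" else format_p(p)
    row$stars <- p_stars(p)
    row$method <- method
    row
  }

  if (kind %in% c("continuous_median_iqr", "continuous_mean_sd")) {
    if (!is.numeric(values)) stop("continuous kinds require numeric values")
    cells <- vapply(split_v, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) return("NA")
      if (kind == "continuous_median_iqr") {
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%s [%s, %s]", fmt_num(q[2]), fmt_num(q[1]), fmt_num(q[3]))
      } else {
        sprintf("%s (%s)", fmt_num(mean(v)), fmt_num(stats::sd(v)))
      }
    }, "")
    complete <- lapply(split_v, function(v) v[!is.na(v)])
    p <- if (length(complete) >= 2 && all(lengths(complete) > 0) &&
             sum(lengths(complete)) >= 3) {
      kruskal_wallis(complete)$p_value
    } else NA_real_
    return(make_row(variable, cells, p,
                    "Kruskal-Wallis"))
  }

  if (kind == "binary") {
    if (!is.logical(values)) stop("binary kind requires logical values")
    counts <- vapply(split_v, function(v) sum(v, na.rm = TRUE), 1)
    totals <- vapply(split_v, function(v) sum(!is.na(v)), 1)
    cells <- count_pct_cell(counts, totals)
    p <- if (length(levels_g) == 2L && all(totals > 0)) {
      fisher_exact_two_sided(counts[2], totals[2] - counts[2],
                             counts[1], totals[1] - counts[1])$p_value
    } else NA_real_
    return(make_row(variable, cells, p, "Fisher exact (two-sided)"))
  }

  # categorical: one row per level, no test (as for diagnosis/treatment)
  values <- as.character(values)
  lev <- sort(unique(values[!is.na(values)]))
  rows <- lapply(lev, function(l) {
    counts <- vapply(split_v, function(v) sum(v == l, na.rm = TRUE), 1)
    totals <- vapply(split_v, function(v) sum(!is.na(v)), 1)
    make_row(paste0(variable, ": ", l), count_pct_cell(counts, totals),
             NA_real_, "none")
  })
  do.call(rbind, rows)
}
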