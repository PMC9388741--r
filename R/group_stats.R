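#' Group summary triplets
#'
#' Construct a table of per-group summary statistics (mean, SD, n), the input
#' to every summary-statistic test in the package. Cohort tables in clinical
#' papers print exactly these triplets, so the tests below can reproduce a
#' published comparison with no access to subject-level data.
#'
#' @param label character vector of group labels.
#' @param mean,sd,n numeric vectors, recycled to the length of `label`.
#' @return A `data.frame` of class `group_summary` with columns
#'   `label`, `mean`, `sd`, `n`.
#' @examples
#' group_summary(c("acute", "chronic"), mean = c(3.45, 7.80),
#'               sd = c(1.77, 4.08), n = c(12, 18))
#' @export
group_summary <- function(label, mean, sd, n) {
  out <- data.frame(label = as.character(label), mean = as.numeric(mean),
                    sd = as.numeric(sd), n = as.integer(n),
                    stringsAsFactors = FALSE)
  if (any(out$sd < 0)) stop("`sd` must be non-negative", call. = FALSE)
  if (any(out$n < 2L)) stop("`n` must be >= 2 for variance-based tests", call. = FALSE)
  class(out) <- c("group_summary", "data.frame")
  out
}

new_test_result <- function(method, statistic, df, p, variance_rule = NA_character_,
                            extra = list()) {
  stopifnot(p >= 0, p <= 1 + 1e-12)
  structure(c(list(method = method, statistic = statistic, df = df,
                   p.value = min(p, 1), variance_rule = variance_rule), extra),
            class = "mm_test")
}

#' @export
print.mm_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.5g, df = %s, p = %.4g\n", x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p.value))
  if (!is.na(x$variance_rule)) cat("  variance rule:", x$variance_rule, "\n")
  invisible(x)
}

#' Folded-F variance-equality pretest
#'
#' Ratio of the larger to the smaller sample variance, referred to an
#' F distribution with the corresponding degrees of freedom and doubled for a
#' two-sided test. Used to route a two-sample comparison to the pooled or
#' Satterthwaite t-test, the convention of classic stats packages.
#'
#' @param sd1,sd2 sample standard deviations (> 0).
#' @param n1,n2 sample sizes (>= 2).
#' @return An object of class `mm_test` with `statistic` (F), `df`
#'   (numerator, denominator) and `p.value`.
#' @examples
#' folded_f(1.77, 12, 4.08, 18)  # unequal variances at alpha = 0.05
#' @export
folded_f <- function(sd1, n1, sd2, n2) {
  stopifnot_scalar_num(sd1, "sd1"); stopifnot_scalar_num(sd2, "sd2")
  if (sd1 == 0 && sd2 == 0) {
    return(new_test_result("Folded F test for equality of variances",
                           statistic = NaN, df = c(NA, NA), p = 1,
                           extra = list(degenerate = TRUE)))
  }
  if (sd1 == 0 || sd2 == 0) {
    return(new_test_result("Folded F test for equality of variances",
                           statistic = Inf, df = c(NA, NA), p = 0,
                           extra = list(degenerate = TRUE)))
  }
  hi <- if (sd1 >= sd2) list(sd = sd1, n = n1) else list(sd = sd2, n = n2)
  lo <- if (sd1 >= sd2) list(sd = sd2, n = n2) else list(sd = sd1, n = n1)
  f <- (hi$sd / lo$sd)^2
  p <- min(1, 2 * stats::pf(f, hi$n - 1, lo$n - 1, lower.tail = FALSE))
  new_test_result("Folded F test for equality of variances", statistic = f,
                  df = c(hi$n - 1, lo$n - 1), p = p,
                  extra = list(degenerate = FALSE))
}

#' Two-sample t-test from summary statistics
#'
#' Student's two-sample t-test computed from (mean, SD, n) triplets. With
#' `rule = "auto"` a folded-F pretest at `alpha_var` chooses between the
#' pooled-variance test (df = n1 + n2 - 2) and the Satterthwaite
#' unequal-variance approximation with fractional df. The result is identical
#' to [stats::t.test()] run on any raw vectors having exactly these summaries.
#'
#' @param g1,g2 single-row [group_summary()] tables (or lists with
#'   `mean`, `sd`, `n`).
#' @param rule `"auto"`, `"pooled"` or `"satterthwaite"`.
#' @param alpha_var significance level of the variance pretest used by
#'   `"auto"` (default 0.05).
#' @return `mm_test` with the t statistic, df, two-sided p, and the
#'   `variance_rule` actually used.
#' @examples
#' a <- group_summary("acute", 13241.08, 2927.81, 12)
#' c_ <- group_summary("chronic", 9407.89, 2463.35, 18)
#' ttest_summary(a, c_)      # pooled branch, p ~ 0.0006
#' @export
ttest_summary <- function(g1, g2, rule = c("auto", "pooled", "satterthwaite"),
                          alpha_var = 0.05) {
  rule <- match.arg(rule)
  m1 <- g1$mean; s1 <- g1$sd; n1 <- g1$n
  m2 <- g2$mean; s2 <- g2$sd; n2 <- g2$n
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) {
      return(new_test_result("Two-sample t-test (summary statistics)", 0,
                             n1 + n2 - 2, 1, variance_rule = "degenerate"))
    }
    return(new_test_result("Two-sample t-test (summary statistics)", Inf,
                           n1 + n2 - 2, 0, variance_rule = "degenerate"))
  }
  if (rule == "auto") {
    rule <- if (folded_f(s1, n1, s2, n2)$p.value < alpha_var) "satterthwaite" else "pooled"
  }
  if (rule == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    tval <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs(tval), df)
  new_test_result("Two-sample t-test (summary statistics)", tval, df, p,
                  variance_rule = rule)
}

#' One-way ANOVA from summary statistics
#'
#' Reconstructs between- and within-group sums of squares from per-group
#' (mean, SD, n) and refers F = MSB/MSW to F(k - 1, N - k). Equivalent to a
#' raw-data one-way ANOVA on any data matching the summaries; for two groups
#' F equals the square of the pooled t statistic.
#'
#' @param groups a [group_summary()] table with one row per group (k >= 2).
#' @return `mm_test`; `extra` carries `mse` (the pooled within-group mean
#'   square) needed by [tukey_pairwise_summary()].
#' @export
anova_summary <- function(groups) {
  k <- nrow(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n <- groups$n; m <- groups$mean; s <- groups$sd
  N <- sum(n)
  if (N - k < 1L) stop("no residual degrees of freedom", call. = FALSE)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  mse <- ssw / (N - k)
  if (mse == 0) {
    p <- if (ssb == 0) 1 else 0
    return(new_test_result("One-way ANOVA (summary statistics)",
                           if (ssb == 0) 0 else Inf, c(k - 1, N - k), p,
                           extra = list(mse = 0, degenerate = TRUE)))
  }
  f <- (ssb / (k - 1)) / mse
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  new_test_result("One-way ANOVA (summary statistics)", f, c(k - 1, N - k), p,
                  extra = list(mse = mse))
}

#' Tukey-Kramer pairwise comparison from summary statistics
#'
#' Studentized-range adjusted pairwise comparison after a one-way ANOVA,
#' using the Tukey-Kramer statistic
#' q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j)) referred to the
#' studentized-range distribution with k groups and N - k error df. The
#' Kramer form handles unequal group sizes.
#'
#' @param groups a [group_summary()] table (k >= 2 rows).
#' @param pair integer or character vector of length 2 selecting the two
#'   groups to compare (row indices or labels).
#' @return `mm_test` with the q statistic and adjusted p.
#' @examples
#' g <- group_summary(c("none", "acute", "chronic"),
#'                    mean = c(9731.65, 13241.08, 9407.89),
#'                    sd = c(4406.23, 2927.81, 2463.35), n = c(23, 12, 18))
#' tukey_pairwise_summary(g, c("none", "chronic"))  # adjusted p ~ 0.95
#' @export
tukey_pairwise_summary <- function(groups, pair) {
  if (is.character(pair)) pair <- match(pair, groups$label)
  if (length(pair) != 2L || anyNA(pair)) stop("`pair` must select two groups", call. = FALSE)
  k <- nrow(groups); N <- sum(groups$n)
  mse <- anova_summary(groups)$mse
  i <- pair[1]; j <- pair[2]
  if (mse == 0) {
    same <- groups$mean[i] == groups$mean[j]
    return(new_test_result("Tukey-Kramer pairwise comparison",
                           if (same) 0 else Inf, c(k, N - k), as.numeric(same),
                           extra = list(degenerate = TRUE)))
  }
  q <- abs(groups$mean[i] - groups$mean[j]) /
    sqrt(mse / 2 * (1 / groups$n[i] + 1 / groups$n[j]))
  p <- stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
  new_test_result("Tukey-Kramer pairwise comparison", q, c(k, N - k), p)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test with the probability-mass definition: the p-value is
#' the sum of hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return `mm_test` with the observed-table hypergeometric probability as
#'   the statistic and the two-sided p.
#' @examples
#' fisher_exact(matrix(c(7, 5, 2, 16), 2, byrow = TRUE))  # p ~ 0.0125
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  ht <- stats::fisher.test(table)
  m <- sum(table[1, ]); nn <- sum(table[2, ]); kk <- sum(table[, 1])
  obs <- stats::dhyper(table[1, 1], m, nn, kk)
  new_test_result("Fisher exact test (two-sided, probability mass)",
                  statistic = obs, df = NA_real_, p = ht$p.value,
                  extra = list(odds_ratio = unname(ht$estimate)))
}

#' Pearson chi-squared test for an r x c table
#'
#' X^2 = sum (O - E)^2 / E with df = (r-1)(c-1) and no continuity correction
#' by default, so that the 2x2 statistic equals the squared two-proportion z.
#'
#' @param table r x c matrix of non-negative counts.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return `mm_test`.
#' @export
chisq_table <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (sum(table) <= 0) stop("table total must be positive", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  new_test_result("Pearson chi-squared test", unname(ht$statistic),
                  unname(ht$parameter), ht$p.value,
                  extra = list(expected = ht$expected))
}

#' Choose the appropriate cohort-comparison test
#'
#' Routing rule for cohort characteristic tables: a continuous variable with
#' two groups gets the summary t-test ([ttest_summary()], auto variance
#' rule); with three or more groups, one-way ANOVA plus Tukey-Kramer
#' pairwise comparisons; a categorical variable gets Fisher's exact test when
#' any expected cell count falls below `fisher_threshold`, otherwise the
#' Pearson chi-squared test.
#'
#' @param type `"continuous"` or `"categorical"`.
#' @param groups for continuous variables a [group_summary()] table; for
#'   categorical variables a contingency matrix.
#' @param fisher_threshold minimum expected cell count for chi-squared
#'   (default 5).
#' @return list with `method` (name of the chosen test) and `result`
#'   (`mm_test`; for ANOVA also `pairwise`, a named list of Tukey results).
#' @export
select_test <- function(type = c("continuous", "categorical"), groups,
                        fisher_threshold = 5) {
  type <- match.arg(type)
  if (type == "continuous") {
    if (nrow(groups) == 2L) {
      res <- ttest_summary(groups[1, ], groups[2, ])
      return(list(method = "ttest", result = res))
    }
    res <- anova_summary(groups)
    prs <- utils::combn(nrow(groups), 2, simplify = FALSE)
    pw <- lapply(prs, function(p) tukey_pairwise_summary(groups, p))
    names(pw) <- vapply(prs, function(p) {
      paste(groups$label[p], collapse = " vs ")
    }, character(1))
    return(list(method = "anova", result = res, pairwise = pw))
  }
  tab <- as.matrix(groups)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < fisher_threshold) && all(dim(tab) == c(2L, 2L))) {
    list(method = "fisher", result = fisher_exact(tab))
  } else {
    list(method = "chisq", result = chisq_table(tab))
  }
}
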