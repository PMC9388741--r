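test_that("folded F routes equal and unequal variance pairs correctly", {
  eq <- folded_f(2, 10, 2, 10)
  expect_equal(eq$statistic, 1)
  expect_equal(eq$p.value, 1)

  # marrow adiposity SDs: clearly unequal spread
  un <- folded_f(4.08, 18, 1.77, 12)
  expect_equal(un$statistic, (4.08 / 1.77)^2, tolerance = 1e-12)
  expect_equal(un$p.value, 2 * pf((4.08 / 1.77)^2, 17, 11, lower.tail = FALSE))
  expect_lt(un$p.value, 0.05)

  # miR-148a-3p SDs: compatible spread, pooled branch
  pl <- folded_f(2927.81, 12, 2463.35, 18)
  expect_equal(pl$statistic, (2927.81 / 2463.35)^2, tolerance = 1e-12)
  expect_gt(pl$p.value, 0.05)
})

test_that("summary t-test equals a raw-data t-test with matching summaries", {
  cases <- list(
    list(m1 = 13241.08, s1 = 2927.81, n1 = 12, m2 = 9407.89, s2 = 2463.35, n2 = 18),
    list(m1 = 3.45, s1 = 1.77, n1 = 12, m2 = 7.80, s2 = 4.08, n2 = 18),
    list(m1 = 0.5, s1 = 1.2, n1 = 5, m2 = -0.3, s2 = 0.8, n2 = 9))
  for (cs in cases) {
    x <- raw_with_summary(cs$m1, cs$s1, cs$n1)
    y <- raw_with_summary(cs$m2, cs$s2, cs$n2)
    g1 <- list(mean = cs$m1, sd = cs$s1, n = cs$n1)
    g2 <- list(mean = cs$m2, sd = cs$s2, n = cs$n2)
    pooled <- ttest_summary(g1, g2, rule = "pooled")
    expect_equal(pooled$p.value, t.test(x, y, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
    satt <- ttest_summary(g1, g2, rule = "satterthwaite")
    expect_equal(satt$p.value, t.test(x, y)$p.value, tolerance = 1e-10)
    expect_equal(satt$df, unname(t.test(x, y)$parameter), tolerance = 1e-8)
  }
})

test_that("t-test degenerate and symmetry behaviour", {
  same <- list(mean = 5, sd = 1, n = 8)
  expect_equal(ttest_summary(same, same)$statistic, 0)
  expect_equal(ttest_summary(same, same)$p.value, 1)
  flat <- list(mean = 2, sd = 0, n = 6)
  expect_equal(ttest_summary(flat, flat)$p.value, 1)

  a <- list(mean = 1, sd = 2, n = 7); b <- list(mean = 3, sd = 2.4, n = 11)
  ab <- ttest_summary(a, b); ba <- ttest_summary(b, a)
  expect_equal(ab$p.value, ba$p.value)
  expect_equal(ab$statistic, -ba$statistic)
})

test_that("summary ANOVA matches raw aov and collapses to t^2 for 2 groups", {
  g <- group_summary(c("a", "b", "c"), mean = c(1, 2, 1.4),
                     sd = c(0.9, 1.1, 1.0), n = c(8, 12, 10))
  raw <- data.frame(
    y = c(raw_with_summary(1, 0.9, 8), raw_with_summary(2, 1.1, 12),
          raw_with_summary(1.4, 1.0, 10)),
    g = rep(c("a", "b", "c"), c(8, 12, 10)))
  res <- anova_summary(g)
  ref <- summary(aov(y ~ g, data = raw))[[1]]
  expect_equal(res$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p.value, ref$`Pr(>F)`[1], tolerance = 1e-10)

  g2 <- g[1:2, ]
  tt <- ttest_summary(g2[1, ], g2[2, ], rule = "pooled")
  a2 <- anova_summary(g2)
  expect_equal(a2$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(a2$p.value, tt$p.value, tolerance = 1e-10)

  flat <- group_summary(c("a", "b"), c(3, 3), c(1, 1), c(5, 5))
  expect_equal(anova_summary(flat)$statistic, 0)
  expect_equal(anova_summary(flat)$p.value, 1)
})

test_that("Tukey-Kramer from summaries matches raw-data TukeyHSD", {
  g <- group_summary(c("none", "acute", "chronic"),
                     mean = c(9731.65, 13241.08, 9407.89),
                     sd = c(4406.23, 2927.81, 2463.35), n = c(23, 12, 18))
  raw <- data.frame(
    y = c(raw_with_summary(9731.65, 4406.23, 23),
          raw_with_summary(13241.08, 2927.81, 12),
          raw_with_summary(9407.89, 2463.35, 18)),
    g = factor(rep(c("none", "acute", "chronic"), c(23, 12, 18)),
               levels = c("none", "acute", "chronic")))
  hsd <- TukeyHSD(aov(y ~ g, data = raw))$g
  expect_equal(tukey_pairwise_summary(g, c("none", "acute"))$p.value,
               hsd["acute-none", "p adj"], tolerance = 1e-8)
  expect_equal(tukey_pairwise_summary(g, c("acute", "chronic"))$p.value,
               hsd["chronic-acute", "p adj"], tolerance = 1e-8)
  expect_equal(tukey_pairwise_summary(g, c("none", "chronic"))$p.value,
               hsd["chronic-none", "p adj"], tolerance = 1e-8)

  gg <- group_summary(c("a", "b", "c"), c(1, 1, 2), c(1, 1, 1), c(6, 6, 6))
  expect_equal(tukey_pairwise_summary(gg, c("a", "b"))$statistic, 0)
  expect_gt(tukey_pairwise_summary(gg, c("a", "b"))$p.value, 0.999)
})

test_that("Fisher exact matches brute-force enumeration on assorted tables", {
  tabs <- list(matrix(c(7, 5, 2, 16), 2, byrow = TRUE),
               matrix(c(10, 2, 14, 4), 2, byrow = TRUE),
               matrix(c(1, 9, 11, 3), 2, byrow = TRUE),
               matrix(c(0, 5, 8, 2), 2, byrow = TRUE),
               matrix(c(3, 3, 3, 3), 2, byrow = TRUE))
  for (tb in tabs) {
    expect_equal(fisher_exact(tb)$p.value, fisher_bruteforce(tb),
                 tolerance = 1e-9)
  }
})

test_that("chi-squared equals the squared two-proportion z-test on 2x2", {
  tb <- matrix(c(30, 20, 18, 32), 2, byrow = TRUE)
  res <- chisq_table(tb)
  p1 <- tb[1, 1] / sum(tb[1, ]); p2 <- tb[2, 1] / sum(tb[2, ])
  pp <- sum(tb[, 1]) / sum(tb)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / sum(tb[1, ]) + 1 / sum(tb[2, ])))
  expect_equal(res$statistic, z^2, tolerance = 1e-10)
  even <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chisq_table(even)$statistic, 0)
  expect_equal(chisq_table(even)$p.value, 1)
  expect_error(chisq_table(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("test selection routes by variable type and expected counts", {
  # tetraplegia: an expected cell of 3.6 forces the exact test
  tetra <- matrix(c(7, 5, 2, 16), 2, byrow = TRUE)
  expect_lt(min(outer(rowSums(tetra), colSums(tetra)) / sum(tetra)), 5)
  expect_equal(select_test("categorical", tetra)$method, "fisher")

  big <- matrix(c(30, 25, 28, 31), 2, byrow = TRUE)
  expect_equal(select_test("categorical", big)$method, "chisq")

  g3 <- group_summary(c("a", "b", "c"), c(37.08, 36.88, 34.43),
                      c(11.07, 9.45, 9.51), c(23, 12, 18))
  plan <- select_test("continuous", g3)
  expect_equal(plan$method, "anova")
  expect_length(plan$pairwise, 3L)
  plan2 <- select_test("continuous", g3[2:3, ])
  expect_equal(plan2$method, "ttest")
})

test_that("all reported p-values lie in [0, 1]", {
  set.seed(99)
  for (i in 1:25) {
    g <- group_summary(letters[1:3], rnorm(3), runif(3, 0.1, 4),
                       sample(3:20, 3, replace = TRUE))
    expect_true(anova_summary(g)$p.value >= 0 && anova_summary(g)$p.value <= 1)
    tt <- ttest_summary(g[1, ], g[2, ])
    expect_true(tt$p.value >= 0 && tt$p.value <= 1)
    tk <- tukey_pairwise_summary(g, c(1, 3))
    expect_true(tk$p.value >= 0 && tk$p.value <= 1)
  }
})
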