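test_that("paired t statistic equals its closed form", {
  set.seed(41)
  g1 <- rnorm(15, 50, 8); g2 <- g1 + rnorm(15, 2, 3)
  r <- paired_compare(g1, g2)
  d <- g1 - g2
  expect_equal(r$test_used, "t")
  expect_equal(r$statistic, mean(d) / (sd(d) / sqrt(15)), tolerance = 1e-9)
  expect_equal(r$mean_diff, r$mean_g1 - r$mean_g2, tolerance = 1e-9)
  expect_equal(r$p_value, t.test(g1, g2, paired = TRUE)$p.value)
})

test_that("the normality gate routes heavy-tailed differences to Wilcoxon", {
  set.seed(42)
  g2 <- rnorm(24, 50, 5)
  # two-point contamination: most differences tiny, a few huge
  d <- c(rnorm(20, 0, 0.2), c(40, -35, 38, -42))
  g1 <- g2 + d
  r <- paired_compare(g1, g2)
  expect_lt(r$normality_p, 0.01)
  expect_equal(r$test_used, "wilcoxon")

  gn <- g2 + rnorm(24, 1, 2)   # normal differences stay parametric
  rn <- paired_compare(gn, g2)
  expect_gt(rn$normality_p, 0.01)
  expect_equal(rn$test_used, "t")
})

test_that("identical groups give a flagged degenerate result", {
  g <- c(1, 2, 3, 4, 5)
  r <- paired_compare(g, g)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_true(is.na(r$statistic))
  expect_equal(r$mean_diff, 0)
})

test_that("Shapiro-Wilk wrapper matches the standard test and guards input", {
  set.seed(43)
  d <- rnorm(24)
  sw <- shapiro_wilk(d)
  ref <- shapiro.test(d)
  expect_equal(sw$W, unname(ref$statistic))
  expect_equal(sw$p, ref$p.value)
  expect_gt(sw$p, 0.05)
  heavy <- c(rnorm(20, 0, 0.1), 30, -25, 28, -33)
  expect_lt(shapiro_wilk(heavy)$p, 0.05)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("signed-rank test agrees with the standard routine when zero-free", {
  set.seed(44)
  # exact path: n <= 25, no zeros, no ties
  g1 <- round(rnorm(18, 50, 6), 3); g2 <- round(rnorm(18, 48, 6), 3)
  r <- wilcoxon_paired(g1, g2)
  ref <- wilcox.test(g1, g2, paired = TRUE, exact = TRUE)
  expect_true(r$exact)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  # approximation path: n > 25, continuity-corrected normal
  G1 <- round(rnorm(40, 50, 6), 3); G2 <- round(rnorm(40, 48, 6), 3)
  R <- wilcoxon_paired(G1, G2)
  REF <- wilcox.test(G1, G2, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_false(R$exact)
  expect_equal(R$statistic, unname(REF$statistic))
  expect_equal(R$p, REF$p.value, tolerance = 1e-9)
})

test_that("zeros are handled by Pratt's method (hand-computed case)", {
  # d = (0, 1, -2, 3, 4): ranks of |d| are 1..5 with the zero ranked first;
  # V = 2 + 4 + 5 = 11; E = (5*6 - 1*2)/4 = 7; Var = (330 - 6)/24 = 13.5;
  # z = (11 - 7 - 0.5)/sqrt(13.5); p = 2*pnorm(-z) = 0.34083
  g2 <- c(10, 10, 10, 10, 10)
  g1 <- g2 + c(0, 1, -2, 3, 4)
  r <- wilcoxon_paired(g1, g2)
  expect_false(r$exact)
  expect_equal(r$statistic, 11)
  expect_equal(r$n, 4)
  expect_equal(r$p, 0.34083, tolerance = 1e-4)
})

test_that("swapping the arguments mirrors the effect but not the p-value", {
  set.seed(45)
  g1 <- rnorm(20, 52, 5); g2 <- rnorm(20, 50, 5)
  a <- wilcoxon_paired(g1, g2); b <- wilcoxon_paired(g2, g1)
  expect_equal(a$p, b$p)
  expect_equal(a$statistic + b$statistic, 20 * 21 / 2)
  expect_error(wilcoxon_paired(g1, g1), "zero")
})

test_that("all-positive differences reach the smallest attainable p", {
  g2 <- seq(10, 19)
  g1 <- g2 + runif(10, 0.5, 1.5)
  r <- wilcoxon_paired(g1, g2)
  expect_equal(r$statistic, 10 * 11 / 2)     # maximal rank sum
  expect_equal(r$p, 2 * psignrank(0, 10))    # most extreme two-sided p
})

test_that("group summaries report mean and sd/sqrt(n)", {
  v <- c(1, 3, 5, 10, 10, 10)
  g <- c("a", "a", "a", "b", "b", "b")
  s <- group_summary(v, g)
  expect_equal(s$mean, c(3, 10))
  expect_equal(s$se, c(sd(c(1, 3, 5)) / sqrt(3), 0))
  expect_error(group_summary(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("ANOVA-Duncan handles degenerate and clear-cut groups", {
  v <- rep(5, 12); g <- rep(1:4, each = 3)
  r <- anova_duncan(v, g)
  expect_equal(r$F, 0)
  expect_equal(r$p_value, 1)
  expect_true(all(r$letters == r$letters[1]))

  set.seed(46)
  v2 <- c(rnorm(5, 0, 1e-4), rnorm(5, 100, 1e-4))
  r2 <- anova_duncan(v2, rep(c("lo", "hi"), each = 5))
  expect_lt(r2$p_value, 1e-6)
  expect_false(r2$letters[["lo"]] == r2$letters[["hi"]])
})

test_that("two-group Duncan reduces to the protected pairwise comparison", {
  set.seed(47)
  for (rep in 1:20) {
    v <- rnorm(12, 50, 5) + rep(c(0, runif(1, 0, 8)), each = 6)
    g <- rep(c("a", "b"), each = 6)
    r <- anova_duncan(v, g)
    tp <- t.test(v ~ g, var.equal = TRUE)$p.value
    expect_equal(r$letters[["a"]] != r$letters[["b"]], tp < 0.05)
  }
})

test_that("square transform drives the ranges but reporting stays raw", {
  set.seed(48)
  v <- c(rnorm(6, 20, 5), rnorm(6, 50, 5))
  g <- rep(1:2, each = 6)
  r <- anova_duncan(v, g, transform = "square")
  expect_equal(r$transform, "square")
  expect_equal(r$group_means, group_summary(v, g)$mean)     # raw scale
  expect_equal(r$p_value,
               summary(aov(v^2 ~ factor(g)))[[1]][["Pr(>F)"]][1])
})

test_that("unbalanced designs fall back to the harmonic mean n with a flag", {
  set.seed(49)
  v <- c(rnorm(6, 10), rnorm(4, 30))
  g <- rep(c("a", "b"), c(6, 4))
  expect_warning(r <- anova_duncan(v, g), "harmonic")
  expect_false(r$balanced)
  expect_equal(r$n_harmonic, 2 / (1 / 6 + 1 / 4))
})
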