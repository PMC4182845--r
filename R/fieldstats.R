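#' Paired comparison of two area series with a normality gate
#'
#' Computes the differences `d = g1 - g2`, tests them for normality with
#' Shapiro-Wilk, and applies either the paired two-tailed Student t-test
#' (normality not rejected) or the paired two-tailed Wilcoxon signed-rank
#' test ([wilcoxon_paired()]).
#'
#' The gate rejects normality when the Shapiro-Wilk p-value falls below
#' `normality_alpha`, which defaults to 0.01: switching to the
#' nonparametric test only on strong evidence of non-normality avoids
#' abandoning the t-test over borderline deviations, a known weakness of
#' pretest-at-alpha strategies. Set `normality_alpha = alpha` for the
#' naive gate.
#'
#' @param g1,g2 numeric vectors of equal length (percent areas), `n >= 3`
#' @param alpha significance level for the comparison itself (default
#'   0.05)
#' @param normality_alpha level of the Shapiro-Wilk gate (default 0.01)
#' @return list of class `paired_test_result`: `n`, `mean_g1`, `mean_g2`,
#'   `mean_diff`, `sd_diff`, `statistic` (t or signed-rank V),
#'   `p_value`, `test_used` (`"t"`, `"wilcoxon"`, or `"degenerate"`),
#'   `normality_p`, `significant`, `degenerate`
#' @export
paired_compare <- function(g1, g2, alpha = 0.05, normality_alpha = 0.01) {
  if (length(g1) != length(g2)) stop("unequal lengths", call. = FALSE)
  n <- length(g1)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- g1 - g2
  base <- list(n = n, mean_g1 = mean(g1), mean_g2 = mean(g2),
               mean_diff = mean(d), sd_diff = sd(d))
  if (sd(d) == 0) {
    res <- c(base, list(
      statistic = NA_real_,
      p_value = if (all(d == 0)) 1 else 0,
      test_used = "degenerate", normality_p = NA_real_,
      significant = !all(d == 0), degenerate = TRUE))
    return(structure(res, class = "paired_test_result"))
  }
  sw <- shapiro_wilk(d)
  if (sw$p >= normality_alpha) {
    tt <- t.test(g1, g2, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value; used <- "t"
  } else {
    wt <- wilcoxon_paired(g1, g2)
    stat <- wt$statistic; p <- wt$p; used <- "wilcoxon"
  }
  structure(c(base, list(statistic = stat, p_value = p, test_used = used,
                         normality_p = sw$p, significant = p < alpha,
                         degenerate = FALSE)),
            class = "paired_test_result")
}

#' Shapiro-Wilk normality test
#'
#' Standard Shapiro-Wilk W and p-value (backed by [stats::shapiro.test()]).
#'
#' @param d numeric vector, `3 <= n <= 5000`
#' @return list with `W` and `p`
#' @export
shapiro_wilk <- function(d) {
  if (length(d) < 3 || length(d) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (sd(d) == 0)
    stop("Shapiro-Wilk is undefined for a constant vector", call. = FALSE)
  sw <- stats::shapiro.test(d)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Paired two-tailed Wilcoxon signed-rank test
#'
#' Signed-rank test on `d = g1 - g2` with a fixed, documented convention:
#' zero differences are handled by Pratt's method (zeros are ranked with
#' the rest but their ranks are dropped from both rank sums), ties receive
#' mid-ranks, and the p-value uses the exact signed-rank distribution when
#' `n <= exact_max_n` and there are no zeros or ties, otherwise the normal
#' approximation with a 0.5 continuity correction (variance corrected for
#' zeros and ties).
#'
#' @param g1,g2 numeric vectors of equal length
#' @param exact_max_n largest n for which the exact distribution is used
#'   (default 25)
#' @return list with `statistic` (V, the positive-rank sum), `p`, `n`
#'   (non-zero pairs), `exact`
#' @export
wilcoxon_paired <- function(g1, g2, exact_max_n = 25L) {
  if (length(g1) != length(g2)) stop("unequal lengths", call. = FALSE)
  d <- g1 - g2
  if (all(d == 0)) stop("all differences are zero", call. = FALSE)
  N <- length(d)
  r <- rank(abs(d))                       # mid-ranks, zeros included (Pratt)
  V <- sum(r[d > 0])
  nz <- sum(d == 0)
  n_eff <- N - nz
  if (n_eff < 3) stop("need at least 3 non-zero differences", call. = FALSE)
  ties <- any(duplicated(abs(d[d != 0])))
  if (N <= exact_max_n && nz == 0 && !ties) {
    mid <- N * (N + 1) / 4
    p <- if (V > mid) 2 * psignrank(V - 1, N, lower.tail = FALSE)
         else 2 * psignrank(V, N)
    p <- min(1, p)
    return(list(statistic = V, p = p, n = n_eff, exact = TRUE))
  }
  # normal approximation, Pratt zero correction and tie correction
  mu <- (N * (N + 1) - nz * (nz + 1)) / 4
  sig2 <- (N * (N + 1) * (2 * N + 1) - nz * (nz + 1) * (2 * nz + 1)) / 24
  tab <- table(r[d != 0])
  sig2 <- sig2 - sum(tab^3 - tab) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = V, p = p, n = n_eff, exact = FALSE)
}

#' Per-group mean and standard error
#'
#' @param values numeric vector (percent areas)
#' @param groups group labels (e.g. mulch 1..4)
#' @return data.frame with `group`, `n`, `mean`, `se` (`sd / sqrt(n)`)
#' @export
group_summary <- function(values, groups) {
  groups <- as.factor(groups)
  sp <- split(values, groups)
  if (any(lengths(sp) < 2)) stop("each group needs n >= 2", call. = FALSE)
  data.frame(group = names(sp),
             n = lengths(sp),
             mean = vapply(sp, mean, 0),
             se = vapply(sp, function(x) sd(x) / sqrt(length(x)), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way ANOVA with Duncan's multiple range test
#'
#' Fits a one-way fixed-effects ANOVA of `values` on `groups`
#' (optionally after squaring the values, the transform used for the
#' heavy-tailed local-entropy areas) and ranks the group means with
#' Duncan's multiple range test: for a span of `p` ordered means the
#' critical range is `R_p = q(1 - alpha_p, p, df_error) * sqrt(MSE / n)`
#' with the Duncan protection level `alpha_p = 1 - (1 - alpha)^(p - 1)`,
#' `q` the studentized-range quantile. Two means differ significantly iff
#' their difference exceeds the critical range for their span and they are
#' not contained in a wider non-significant range. Groups are assigned
#' display letters: groups sharing a letter are not significantly
#' different at `alpha`.
#'
#' Reported per-group means and standard errors are always on the raw
#' (untransformed) percent scale; the ANOVA and ranges operate on the
#' transformed scale when `transform = "square"`.
#'
#' @param values numeric vector (percent areas)
#' @param groups group labels, `>= 2` groups with `n >= 2` each
#' @param alpha significance level (default 0.05)
#' @param transform `"none"` or `"square"`
#' @return list of class `anova_duncan_result`: `group_ids`,
#'   `group_means`, `group_se` (raw scale), `F`, `p_value`, `letters`,
#'   `transform`, `df_error`, `mse`, `n_harmonic`, `balanced`
#' @export
anova_duncan <- function(values, groups, alpha = 0.05,
                         transform = c("none", "square")) {
  transform <- match.arg(transform)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  raw <- group_summary(values, groups)
  v <- if (transform == "square") values^2 else values
  ns <- table(groups)
  balanced <- length(unique(ns)) == 1L
  if (!balanced)
    warning("unbalanced groups: harmonic mean n used for Duncan ranges",
            call. = FALSE)
  n_h <- length(ns) / sum(1 / as.numeric(ns))

  fit <- aov(v ~ groups)
  an <- suppressWarnings(anova(fit))
  ssb <- an[["Sum Sq"]][1]
  mse <- an[["Mean Sq"]][2]
  df_err <- an[["Df"]][2]
  tol <- 1e-10 * (sum(v^2) / length(v) + 1)
  if (mse <= tol) {                   # degenerate: no within-group variation
    mse <- 0
    Fv <- if (ssb <= tol) 0 else Inf
    pv <- if (ssb <= tol) 1 else 0
  } else {
    Fv <- an[["F value"]][1]
    pv <- an[["Pr(>F)"]][1]
  }

  means_t <- vapply(split(v, groups), mean, 0)
  letters <- duncan_letters(means_t, mse, df_err, n_h, alpha)

  structure(list(group_ids = raw$group, group_means = raw$mean,
                 group_se = raw$se, F = Fv, p_value = pv,
                 letters = letters[raw$group], transform = transform,
                 df_error = df_err, mse = mse, n_harmonic = n_h,
                 balanced = balanced),
            class = "anova_duncan_result")
}

# Duncan letter display. means_t: named vector of (transformed-scale) group
# means; returns named character vector of letters.
duncan_letters <- function(means_t, mse, df_err, n_h, alpha) {
  k <- length(means_t)
  ord <- order(means_t, decreasing = TRUE)
  m <- means_t[ord]
  se_m <- sqrt(mse / n_h)
  crit <- vapply(2:max(2, k), function(p) {
    ap <- 1 - (1 - alpha)^(p - 1)
    qtukey(1 - ap, p, df_err) * se_m
  }, 0)
  # nonsig[i, j] (i < j in rank order): range i..j not significant
  nonsig <- matrix(FALSE, k, k)
  diag(nonsig) <- TRUE
  for (i in seq_len(k)) for (j in seq_len(k)) if (j > i) {
    span <- j - i + 1
    R <- if (is.finite(se_m) && se_m > 0) crit[span - 1] else 0
    nonsig[i, j] <- (m[i] - m[j]) <= R + 1e-12 * max(abs(m[i]), 1)
  }
  # protection: a range inside a non-significant range is non-significant
  for (span in rev(2:max(2, k))) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (j <= k && nonsig[i, j])
        for (a in i:j) for (b in a:j) nonsig[a, b] <- TRUE
    }
  }
  # maximal non-significant runs -> letters
  runs <- list()
  for (i in seq_len(k)) {
    j <- max(which(nonsig[i, i:k])) + i - 1
    runs[[i]] <- c(i, j)
  }
  runs <- unique(runs)
  keep <- vapply(seq_along(runs), function(a) {
    !any(vapply(seq_along(runs), function(b) {
      b != a && runs[[b]][1] <= runs[[a]][1] && runs[[b]][2] >= runs[[a]][2]
    }, TRUE))
  }, TRUE)
  runs <- runs[keep]
  runs <- runs[order(vapply(runs, `[`, 0, 1))]
  lab <- rep("", k)
  for (a in seq_along(runs)) {
    rng <- runs[[a]][1]:runs[[a]][2]
    lab[rng] <- paste0(lab[rng], letters[a])
  }
  out <- lab[order(ord)]
  names(out) <- names(means_t)
  out
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "Paired comparison (n = %d): mean diff = %.4f (G1 %.4f, G2 %.4f)\n",
    x$n, x$mean_diff, x$mean_g1, x$mean_g2))
  cat(sprintf("  test: %s, statistic = %s, p = %.4f%s\n", x$test_used,
              format(x$statistic, digits = 4), x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  if (!is.na(x$normality_p))
    cat(sprintf("  Shapiro-Wilk on differences: p = %.4f\n", x$normality_p))
  invisible(x)
}

#' @export
print.anova_duncan_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F = %.4g, p = %.4g\n",
              if (x$transform == "square") " (squared values)" else "",
              x$F, x$p_value))
  df <- data.frame(group = x$group_ids,
                   mean = round(x$group_means, 2),
                   se = round(x$group_se, 2),
                   duncan = unname(x$letters))
  print(df, row.names = FALSE)
  invisible(x)
}
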