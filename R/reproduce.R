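#' Threshold agreement summaries
#'
#' Pairwise agreement between the automatic and manual thresholds across
#' the images of a per-image table: mean and maximum absolute difference
#' for OT vs RC, OT vs MT, RC vs MT, plus the maximum signed `t_ot -
#' t_rc`. On the field data the two global methods nearly coincide
#' (mean |t_OT - t_RC| well below one gray level apart at 8 bits) while
#' the manual threshold sits farther away.
#'
#' @param table1 data.frame as returned by [load_table1()]
#' @return data.frame with columns `pair`, `mean_abs_diff`,
#'   `max_abs_diff`, `max_signed_diff`
#' @export
threshold_summaries <- function(table1 = load_table1()) {
  pairs <- list(c("t_ot", "t_rc"), c("t_ot", "t_mt"), c("t_rc", "t_mt"))
  do.call(rbind, lapply(pairs, function(p) {
    d <- table1[[p[1]]] - table1[[p[2]]]
    data.frame(pair = paste(p, collapse = " - "),
               mean_abs_diff = mean(abs(d)),
               max_abs_diff = max(abs(d)),
               max_signed_diff = max(d),
               stringsAsFactors = FALSE)
  }))
}

#' Area discrepancy summaries against the reference
#'
#' Mean and maximum absolute discrepancy between each method's percent
#' bare-soil area and the expert reference area across the images.
#'
#' @param table1 data.frame as returned by [load_table1()]
#' @return data.frame with columns `method`, `mean_abs_diff`,
#'   `max_abs_diff`
#' @export
area_discrepancy_summaries <- function(table1 = load_table1()) {
  methods <- c(OT = "a_ot", RC = "a_rc", MT = "a_mt", LE = "a_le")
  do.call(rbind, lapply(names(methods), function(m) {
    d <- table1$a_r - table1[[methods[[m]]]]
    data.frame(method = m, mean_abs_diff = mean(abs(d)),
               max_abs_diff = max(abs(d)), stringsAsFactors = FALSE)
  }))
}

#' Paired method-vs-reference comparisons
#'
#' Runs [paired_compare()] of the reference area against each
#' thresholding method's area, one row per method, reproducing the
#' published comparison table: mean difference, group means, SD of the
#' differences, the statistic of the test the normality gate selected,
#' and its two-tailed p-value.
#'
#' @param table1 data.frame as returned by [load_table1()]
#' @param alpha significance level (default 0.05)
#' @param normality_alpha Shapiro-Wilk gate level, see [paired_compare()]
#' @return data.frame with one row per method (OT, RC, MT, LE)
#' @export
reproduce_table3 <- function(table1 = load_table1(), alpha = 0.05,
                             normality_alpha = 0.01) {
  methods <- c(OT = "a_ot", RC = "a_rc", MT = "a_mt", LE = "a_le")
  do.call(rbind, lapply(names(methods), function(m) {
    r <- paired_compare(table1$a_r, table1[[methods[[m]]]], alpha = alpha,
                        normality_alpha = normality_alpha)
    data.frame(g1 = "A_R", g2 = paste0("A_", m),
               mean_diff = r$mean_diff, mean_g1 = r$mean_g1,
               mean_g2 = r$mean_g2, sd_diff = r$sd_diff,
               statistic = r$statistic, p_value = r$p_value,
               test_used = r$test_used, normality_p = r$normality_p,
               significant = r$significant, stringsAsFactors = FALSE)
  }))
}

#' Per-mulch deterioration comparison
#'
#' Runs [anova_duncan()] on the reference and each method's area column
#' grouped by mulch material. The local-entropy column is analyzed on
#' squared values (its distribution is heavy-tailed); all reported means
#' and SEs stay on the raw percent scale.
#'
#' @param table1 data.frame as returned by [load_table1()]
#' @param alpha significance level (default 0.05)
#' @return named list of `anova_duncan_result` objects for `A_R`, `A_OT`,
#'   `A_RC`, `A_LE`, plus a `summary` data.frame in display form
#'   (`mean +/- se` with Duncan letters, ANOVA p per column)
#' @export
reproduce_table4 <- function(table1 = load_table1(), alpha = 0.05) {
  cols <- c(A_R = "a_r", A_OT = "a_ot", A_RC = "a_rc", A_LE = "a_le")
  res <- lapply(names(cols), function(nm) {
    anova_duncan(table1[[cols[[nm]]]], table1$mulch, alpha = alpha,
                 transform = if (nm == "A_LE") "square" else "none")
  })
  names(res) <- names(cols)
  disp <- data.frame(mulch = res$A_R$group_ids, stringsAsFactors = FALSE)
  for (nm in names(cols)) {
    r <- res[[nm]]
    disp[[nm]] <- sprintf("%.2f ± %.2f %s", r$group_means, r$group_se,
                          r$letters)
  }
  pv <- vapply(res, function(r) r$p_value, 0)
  res$summary <- disp
  res$p_values <- pv
  res
}
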