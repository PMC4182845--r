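#' Threshold selection on the saturation histogram
#'
#' Four methods are compared on mulched-soil photographs: Otsu (OT),
#' Ridler-Calvard isodata (RC), co-occurrence local entropy (LE), and a
#' user-supplied manual threshold (MT). All return a `threshold_result`.
#'
#' @name thresholding
NULL

threshold_result <- function(method, t, t_bin = NA_integer_,
                             iterations = NA_integer_, objective = NA_real_) {
  structure(list(method = method, t = t, t_bin = t_bin,
                 iterations = iterations, objective = objective),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold %s> t = %.6f", x$method, x$t))
  if (!is.na(x$t_bin)) cat(sprintf(" (bin %d)", x$t_bin))
  if (!is.na(x$iterations)) cat(sprintf(", %d iterations", x$iterations))
  if (!is.na(x$objective)) cat(sprintf(", objective = %.6g", x$objective))
  cat("\n")
  invisible(x)
}

#' Class statistics at a candidate histogram split
#'
#' Splits the histogram at bin `t_bin`: background is bins `<= t_bin`,
#' foreground bins `> t_bin`. Returns the class probabilities
#' `omega0`, `omega1`, the class mean gray levels `m1`, `m2` (on the bin
#' index scale 0..255), the between-class variance
#' `sigma_b2 = omega0 * omega1 * (m1 - m2)^2` and the within-class
#' variance `sigma_w2`. If either class has zero mass its mean is `NA`
#' and `sigma_b2 = 0`.
#'
#' @param hist a [gray_histogram()]
#' @param t_bin split bin in `0..255`
#' @return list with fields `omega0`, `omega1`, `m1`, `m2`, `sigma_b2`,
#'   `sigma_w2`
#' @export
class_statistics <- function(hist, t_bin) {
  check_histogram(hist)
  if (t_bin < 0 || t_bin > 255) stop("t_bin must be in 0..255", call. = FALSE)
  p <- hist$probabilities
  i <- 0:255
  bg <- i <= t_bin
  w0 <- sum(p[bg]); w1 <- 1 - w0
  m1 <- if (w0 > 0) sum(i[bg] * p[bg]) / w0 else NA_real_
  m2 <- if (w1 > 0) sum(i[!bg] * p[!bg]) / w1 else NA_real_
  if (w0 > 0 && w1 > 0) {
    sb2 <- w0 * w1 * (m1 - m2)^2
    v1 <- sum((i[bg] - m1)^2 * p[bg]) / w0
    v2 <- sum((i[!bg] - m2)^2 * p[!bg]) / w1
    sw2 <- w0 * v1 + w1 * v2
  } else {
    sb2 <- 0
    mu <- sum(i * p)
    sw2 <- sum((i - mu)^2 * p)
  }
  list(omega0 = w0, omega1 = w1, m1 = m1, m2 = m2,
       sigma_b2 = sb2, sigma_w2 = sw2)
}

#' Otsu's threshold
#'
#' Finds the split bin maximizing the between-class variance over all 256
#' candidate splits (equivalently, minimizing the within-class variance).
#' When several bins attain the maximum (a plateau), the floor of the mean
#' of the maximizing bin indices is returned.
#'
#' @param hist a [gray_histogram()]
#' @return a `threshold_result` with `method = "OT"`, grid-valued
#'   `t = t_bin / 255`, and `objective` the achieved between-class variance
#'   (bin-index scale)
#' @export
otsu_threshold <- function(hist) {
  check_histogram(hist)
  stop_if_degenerate(hist)
  p <- hist$probabilities
  i <- 0:255
  w0 <- cumsum(p)
  mu_t <- cumsum(i * p)
  mu <- mu_t[256]
  w1 <- 1 - w0
  # sigma_b2(t) = (mu * w0 - mu_t)^2 / (w0 * w1); 0 where a class is empty
  num <- (mu * w0 - mu_t)^2
  den <- w0 * w1
  sb2 <- ifelse(den > 0, num / den, 0)
  best <- max(sb2)
  idx <- which(sb2 >= best - 1e-12 * max(best, 1)) - 1L  # bins, 0-based
  t_bin <- as.integer(floor(mean(idx)))
  threshold_result("OT", t = bin_value(t_bin), t_bin = t_bin,
                   objective = best)
}

#' Ridler-Calvard (isodata) threshold
#'
#' Iterates the fixed point `t <- (m1(t) + m2(t)) / 2`, where `m1`, `m2`
#' are the mean gray values of the two histogram classes separated by the
#' current threshold, starting from the overall histogram mean, until two
#' successive thresholds differ by less than `tol`. The converged
#' threshold is real-valued (not snapped to the 1/255 grid), matching how
#' isodata thresholds are conventionally reported.
#'
#' @param hist a [gray_histogram()]
#' @param tol convergence tolerance on the `[0, 1]` scale (default half a
#'   bin, `1/510`)
#' @param max_iter iteration cap; exceeding it is an error
#' @return a `threshold_result` with `method = "RC"` and the iteration
#'   count
#' @export
ridler_calvard_threshold <- function(hist, tol = 1 / 510, max_iter = 200L) {
  check_histogram(hist)
  stop_if_degenerate(hist)
  p <- hist$probabilities
  v <- bin_value(0:255)
  t <- sum(v * p)  # overall mean
  for (k in seq_len(max_iter)) {
    bg <- v <= t
    w0 <- sum(p[bg]); w1 <- 1 - w0
    m1 <- sum(v[bg] * p[bg]) / w0
    m2 <- sum(v[!bg] * p[!bg]) / w1
    t_new <- (m1 + m2) / 2
    if (abs(t_new - t) < tol)
      return(threshold_result("RC", t = t_new, iterations = k))
    t <- t_new
  }
  stop("Ridler-Calvard iteration did not converge after ", max_iter,
       " iterations", call. = FALSE)
}

#' Local-entropy threshold
#'
#' The default `"cooccurrence"` variant builds the gray-level
#' co-occurrence matrix of the quantized plane over ordered
#' one-step axial neighbor pairs (each pixel with its right neighbor and
#' with the neighbor below, no wraparound). For each candidate split it
#' renormalizes the background-background quadrant (`i <= t`, `j <= t`)
#' and the foreground-foreground quadrant (`i > t`, `j > t`) to
#' probability distributions and sums their Shannon entropies (bits,
#' `0 log 0 = 0`); the split maximizing the sum is returned (first bin on
#' ties). Because the objective uses spatial co-occurrence rather than the
#' first-order histogram alone, it is a local method.
#'
#' The `"first_order"` variant is the classical maximum-sum-entropy
#' (Kapur-style) threshold on the first-order histogram, provided for
#' sensitivity analysis.
#'
#' @param plane numeric matrix on `[0, 1]`
#' @param variant `"cooccurrence"` (default) or `"first_order"`
#' @return a `threshold_result` with `method = "LE"`, grid-valued `t`,
#'   and `objective` the achieved summed entropy in bits
#' @export
local_entropy_threshold <- function(plane,
                                    variant = c("cooccurrence", "first_order")) {
  variant <- match.arg(variant)
  q <- quantize_plane(plane)
  if (length(unique(as.vector(q))) < 2L)
    stop("degenerate plane: fewer than two distinct quantized levels",
         call. = FALSE)
  if (variant == "cooccurrence") {
    C <- cooccurrence_matrix(q)
    obj <- quadrant_entropy_curve(C)
  } else {
    p <- saturation_histogram(q / 255)$probabilities
    obj <- first_order_entropy_curve(p)
  }
  t_bin <- which.max(obj) - 1L
  threshold_result("LE", t = bin_value(t_bin), t_bin = t_bin,
                   objective = obj[t_bin + 1L])
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered neighbor pairs `(i, j)`: each pixel's level `i` with the
#' level `j` of its right neighbor and of the neighbor below (no
#' wraparound).
#'
#' @param q integer matrix of quantized levels in `0..255` (see
#'   [quantize_plane()])
#' @return 256 x 256 matrix of pair counts
#' @export
cooccurrence_matrix <- function(q) {
  m <- nrow(q); n <- ncol(q)
  from <- integer(0); to <- integer(0)
  if (n > 1) { from <- c(from, q[, -n]); to <- c(to, q[, -1]) }
  if (m > 1) { from <- c(from, q[-m, ]); to <- c(to, q[-1, ]) }
  if (!length(from)) stop("plane too small for neighbor pairs", call. = FALSE)
  counts <- tabulate(from * 256L + to + 1L, nbins = 256L * 256L)
  matrix(counts, 256L, 256L, byrow = TRUE)
}

# summed BB + FF quadrant entropy (bits) for every split t = 0..255;
# H(quadrant) = log2(S) - T/S with S = sum(c), T = sum(c log2 c)
quadrant_entropy_curve <- function(C) {
  clog <- ifelse(C > 0, C * log2(pmax(C, 1)), 0)
  cum2d <- function(x) t(apply(apply(x, 2, cumsum), 1, cumsum))
  S_tl <- cum2d(C)      # S_tl[i, j] = sum over rows <= i, cols <= j
  T_tl <- cum2d(clog)
  tot_S <- S_tl[256, 256]; tot_T <- T_tl[256, 256]
  k <- 1:256
  s_bb <- diag(S_tl); t_bb <- diag(T_tl)
  # bottom-right quadrant sums via inclusion-exclusion
  s_ff <- tot_S - S_tl[k, 256] - S_tl[256, k] + s_bb
  t_ff <- tot_T - T_tl[k, 256] - T_tl[256, k] + t_bb
  h <- function(s, tt) ifelse(s > 0, log2(s) - tt / s, 0)
  h(s_bb, t_bb) + h(s_ff, t_ff)
}

# Kapur-style first-order sum entropy for every split t = 0..255
first_order_entropy_curve <- function(p) {
  plog <- ifelse(p > 0, p * log2(p), 0)
  w0 <- cumsum(p); cl <- cumsum(plog)
  w1 <- 1 - w0; cl1 <- cl[256] - cl
  hb <- ifelse(w0 > 0, log2(w0) - cl / w0, 0)
  hf <- ifelse(w1 > 0, log2(w1) - cl1 / w1, 0)
  hb + hf
}

#' Manual threshold
#'
#' Wraps a user-chosen threshold, as set interactively on the histogram
#' display of common imaging software.
#'
#' @param t threshold in `[0, 1]`
#' @return a `threshold_result` with `method = "MT"`
#' @export
manual_threshold <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0 || t > 1)
    stop("manual threshold must be a single value in [0, 1]", call. = FALSE)
  threshold_result("MT", t = t)
}

#' Shannon entropy of a histogram
#'
#' `H = -sum(p_i log2 p_i)` in bits over the non-zero bin probabilities.
#'
#' @param hist a [gray_histogram()]
#' @return list with `H` (bits) and `L` (number of gray levels, 256)
#' @export
shannon_entropy <- function(hist) {
  check_histogram(hist)
  p <- hist$probabilities
  p <- p[p > 0]
  list(H = -sum(p * log2(p)), L = hist$levels)
}

stop_if_degenerate <- function(hist) {
  if (sum(hist$counts > 0) < 2L)
    stop("degenerate histogram: fewer than two occupied bins; ",
         "no two-class split exists", call. = FALSE)
  invisible(TRUE)
}
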