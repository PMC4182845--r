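# Independent brute-force oracles for the thresholding objectives.
# Deliberately written as plain per-bin summations so they share no code
# path with the package's vectorized implementations.

oracle_class_stats <- function(counts, t_bin) {
  p <- counts / sum(counts)
  w0 <- 0; w1 <- 0; s0 <- 0; s1 <- 0
  for (i in 0:255) {
    if (i <= t_bin) { w0 <- w0 + p[i + 1]; s0 <- s0 + i * p[i + 1] }
    else            { w1 <- w1 + p[i + 1]; s1 <- s1 + i * p[i + 1] }
  }
  m1 <- if (w0 > 0) s0 / w0 else NA_real_
  m2 <- if (w1 > 0) s1 / w1 else NA_real_
  sb2 <- if (w0 > 0 && w1 > 0) w0 * w1 * (m1 - m2)^2 else 0
  list(omega0 = w0, omega1 = w1, m1 = m1, m2 = m2, sigma_b2 = sb2)
}

# all bins attaining the maximal between-class variance
oracle_otsu_argmax <- function(counts) {
  sb2 <- vapply(0:255, function(t) oracle_class_stats(counts, t)$sigma_b2, 0)
  best <- max(sb2)
  which(sb2 >= best - 1e-12 * max(best, 1)) - 1L
}

# summed BB + FF quadrant entropy at split t, by direct renormalization
oracle_quadrant_entropy <- function(C, t_bin) {
  ent <- function(block) {
    s <- sum(block)
    if (s == 0) return(0)
    q <- block[block > 0] / s
    -sum(q * log2(q))
  }
  k <- t_bin + 1
  ent(C[seq_len(k), seq_len(k), drop = FALSE]) +
    ent(C[-seq_len(k), -seq_len(k), drop = FALSE])
}

random_histogram <- function(occupied = sample(3:20, 1)) {
  counts <- integer(256)
  bins <- sample(0:255, occupied)
  counts[bins + 1] <- sample(1:500, occupied, replace = TRUE)
  counts
}

spike_histogram <- function(bins, weights) {
  counts <- integer(256)
  counts[bins + 1] <- weights
  counts
}

# blobby random mask for cleanup property tests
random_mask <- function(m = 60, n = 60, p = 0.5) {
  noise <- matrix(rnorm(m * n), m, n)
  sm <- noise
  for (i in 1:2) {
    sm <- (sm +
      rbind(sm[1, ], sm[-m, ]) + rbind(sm[-1, ], sm[m, ]) +
      cbind(sm[, 1], sm[, -n]) + cbind(sm[, -1], sm[, n])) / 5
  }
  sm > quantile(sm, 1 - p)
}
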