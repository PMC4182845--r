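test_that("class statistics match the brute-force summation oracle", {
  # single-class split: all mass above the candidate threshold
  h <- gray_histogram(spike_histogram(100, 50))
  cs <- class_statistics(h, 50)
  expect_equal(cs$omega0, 0)
  expect_equal(cs$sigma_b2, 0)
  expect_true(is.na(cs$m1))

  # equal spikes split in the middle
  h2 <- gray_histogram(spike_histogram(c(64, 192), c(10, 10)))
  cs2 <- class_statistics(h2, 128)
  expect_equal(cs2$omega0, 0.5)
  expect_equal(cs2$omega1, 0.5)
  expect_equal(cs2$m1, 64)
  expect_equal(cs2$m2, 192)

  set.seed(21)
  for (rep in 1:10) {
    counts <- random_histogram(occupied = 5)
    t_bin <- sample(0:255, 1)
    got <- class_statistics(gray_histogram(counts), t_bin)
    want <- oracle_class_stats(counts, t_bin)
    expect_equal(got[c("omega0", "omega1", "m1", "m2", "sigma_b2")], want)
  }
})

test_that("between- and within-class variance sum to the total at every split", {
  set.seed(22)
  for (rep in 1:5) {
    counts <- random_histogram()
    h <- gray_histogram(counts)
    p <- h$probabilities
    mu <- sum((0:255) * p)
    total_var <- sum(((0:255) - mu)^2 * p)
    for (t_bin in seq(0, 255, by = 17)) {
      cs <- class_statistics(h, t_bin)
      expect_equal(cs$sigma_b2 + cs$sigma_w2, total_var, tolerance = 1e-9)
    }
  }
})

test_that("Otsu maximizes between-class variance (exhaustive oracle)", {
  # plateau between equal spikes: floor of the plateau mean
  h <- gray_histogram(spike_histogram(c(64, 192), c(10, 10)))
  r <- otsu_threshold(h)
  expect_equal(r$t_bin, 127L)
  expect_equal(r$t, 127 / 255)

  set.seed(23)
  for (rep in 1:40) {
    counts <- random_histogram()
    r <- otsu_threshold(gray_histogram(counts))
    argmax <- oracle_otsu_argmax(counts)
    expect_equal(r$t_bin, as.integer(floor(mean(argmax))))
    expect_equal(r$objective, oracle_class_stats(counts, argmax[1])$sigma_b2,
                 tolerance = 1e-9)
  }
})

test_that("Otsu threshold sits within one bin of the class-mean average", {
  # holds for histograms with dense support (as real saturation
  # histograms have); wide empty gaps would let the maximizing plateau
  # drift from the class-mean average
  set.seed(24)
  for (rep in 1:20) {
    counts <- pmax(1, round(
      1000 * dnorm(0:255, runif(1, 40, 100), runif(1, 10, 30)) +
      1000 * dnorm(0:255, runif(1, 140, 220), runif(1, 10, 30)) +
      runif(256, 0, 2)))
    r <- otsu_threshold(gray_histogram(counts))
    cs <- class_statistics(gray_histogram(counts), r$t_bin)
    expect_lte(abs(r$t_bin - (cs$m1 + cs$m2) / 2), 1)
  }
})

test_that("Ridler-Calvard converges to its fixed point", {
  # constant class means: limit is their midpoint
  h <- gray_histogram(spike_histogram(c(64, 192), c(10, 10)))
  r <- ridler_calvard_threshold(h)
  expect_equal(r$t, 128 / 255, tolerance = 1 / 510)
  expect_equal(r$method, "RC")
  expect_gte(r$iterations, 1)

  set.seed(25)
  for (rep in 1:20) {
    counts <- random_histogram()
    h <- gray_histogram(counts)
    r <- ridler_calvard_threshold(h)
    v <- bin_value(0:255)
    p <- h$probabilities
    bg <- v <= r$t
    m1 <- sum(v[bg] * p[bg]) / sum(p[bg])
    m2 <- sum(v[!bg] * p[!bg]) / sum(p[!bg])
    expect_lt(abs(r$t - (m1 + m2) / 2), 1 / 510)
  }
})

test_that("RC lands at the symmetry center of a symmetric bimodal mixture", {
  counts <- integer(256)
  for (k in 0:12) {
    w <- round(1000 * exp(-k^2 / 18))
    counts[81 + k] <- counts[81 - k] <- w   # mode at bin 80
    counts[181 + k] <- counts[181 - k] <- w # mode at bin 180
  }
  counts[81] <- counts[181] <- 1000
  r <- ridler_calvard_threshold(gray_histogram(counts))
  expect_equal(r$t, 130 / 255, tolerance = 1 / 255)
  # equal class shapes: Otsu and RC agree within one bin
  ot <- otsu_threshold(gray_histogram(counts))
  expect_lte(abs(ot$t - r$t), 1 / 255 + 1e-12)
})

test_that("degenerate single-level inputs raise typed errors", {
  single <- gray_histogram(spike_histogram(40, 100))
  expect_error(otsu_threshold(single), "degenerate")
  expect_error(ridler_calvard_threshold(single), "degenerate")
  expect_error(local_entropy_threshold(matrix(0.3, 10, 10)), "degenerate")
})

test_that("local entropy equals the exhaustive quadrant-entropy scan", {
  plane <- cbind(matrix(50 / 255, 20, 10), matrix(200 / 255, 20, 10))
  r <- local_entropy_threshold(plane)
  C <- cooccurrence_matrix(quantize_plane(plane))
  obj <- vapply(0:255, function(t) oracle_quadrant_entropy(C, t), 0)
  expect_equal(r$t_bin, which.max(obj) - 1L)
  expect_equal(r$objective, max(obj), tolerance = 1e-9)

  set.seed(26)
  noisy <- matrix(runif(30 * 30, 0.1, 0.4), 30, 30)
  noisy[, 16:30] <- runif(30 * 15, 0.6, 0.9)
  rn <- local_entropy_threshold(noisy)
  Cn <- cooccurrence_matrix(quantize_plane(noisy))
  objn <- vapply(0:255, function(t) oracle_quadrant_entropy(Cn, t), 0)
  expect_equal(rn$t_bin, which.max(objn) - 1L)
})

test_that("local entropy is invariant to swapping the two regions", {
  plane <- cbind(matrix(50 / 255, 20, 10), matrix(200 / 255, 20, 10))
  swapped <- cbind(matrix(200 / 255, 20, 10), matrix(50 / 255, 20, 10))
  expect_equal(local_entropy_threshold(plane)$t_bin,
               local_entropy_threshold(swapped)$t_bin)
})

test_that("first-order entropy variant maximizes the Kapur sum entropy", {
  set.seed(27)
  plane <- matrix(c(runif(200, 0.05, 0.3), runif(200, 0.5, 0.95)), 20, 20)
  r <- local_entropy_threshold(plane, variant = "first_order")
  p <- saturation_histogram(plane)$probabilities
  ent <- function(q) { q <- q[q > 0] / sum(q); -sum(q * log2(q)) }
  obj <- vapply(0:255, function(t) {
    lo <- p[seq_len(t + 1)]; hi <- p[-seq_len(t + 1)]
    (if (sum(lo) > 0) ent(lo) else 0) + (if (sum(hi) > 0) ent(hi) else 0)
  }, 0)
  expect_equal(r$t_bin, which.max(obj) - 1L)
})

test_that("manual threshold wraps its input and validates the range", {
  r <- manual_threshold(0.2499)
  expect_equal(r$method, "MT")
  expect_equal(r$t, 0.2499)
  expect_error(manual_threshold(-0.1), "\\[0, 1\\]")
  expect_error(manual_threshold(1.5), "\\[0, 1\\]")
  # extremes are valid and act through the strict > rule downstream
  plane <- matrix(c(0, 0.5, 1, 1), 2, 2)
  expect_equal(sum(binarize(plane, manual_threshold(0))), 3)
  expect_equal(sum(binarize(plane, manual_threshold(1))), 0)
})

test_that("Shannon entropy hits its closed-form landmarks and bounds", {
  uniform <- gray_histogram(rep(4L, 256))
  expect_equal(shannon_entropy(uniform)$H, 8)
  expect_equal(shannon_entropy(gray_histogram(spike_histogram(7, 10)))$H, 0)
  two <- gray_histogram(spike_histogram(c(0, 255), c(5, 5)))
  expect_equal(shannon_entropy(two)$H, 1)
  set.seed(28)
  for (rep in 1:10) {
    H <- shannon_entropy(gray_histogram(random_histogram()))$H
    expect_gte(H, 0)
    expect_lte(H, 8)
  }
})
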