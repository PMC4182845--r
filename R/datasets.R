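#' Load the packaged per-image field dataset
#'
#' Returns the published per-image table for the 24 field photographs
#' (4 mulch materials x 6 blocks, taken 100 days after mulch laying):
#' the threshold selected by each method on the saturation-plane
#' histogram (`t_ot`, `t_rc`, `t_mt`, `t_le`, on `[0, 1]`) and the
#' percent bare-soil area after small-object removal under each method
#' plus the expert-traced reference (`a_ot`, `a_rc`, `a_mt`, `a_le`,
#' `a_r`, in percent).
#'
#' The table is shipped verbatim as printed, including two quirks worth
#' knowing: image 11 is the one frame where `t_rc > t_ot`, and image 17
#' (a nearly intact polyethylene frame) has `a_le = 0`.
#'
#' Mulches 1-2 are biodegradable plastic (BD), mulch 3 polyethylene (PE),
#' mulch 4 paper (PP).
#'
#' @return data.frame with 24 rows and columns `image_id`, `mulch`,
#'   `block`, `t_ot`, `t_rc`, `t_mt`, `t_le`, `a_ot`, `a_rc`, `a_mt`,
#'   `a_le`, `a_r`
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "mulchres",
                      mustWork = TRUE)
  read.csv(path)
}

#' Generate a synthetic two-class field scene
#'
#' Emulates a mulched-plot photograph with known ground truth. A blobby
#' soil/mulch mask is built by smoothing white noise with a Gaussian
#' kernel and thresholding it at the quantile that yields the requested
#' soil fraction (irregular blob boundaries exercise the 8-connected
#' cleanup the way torn mulch does). Per-pixel saturation is drawn from a
#' truncated normal on `[0, 1]`: mean `mu_soil` on soil, `mu_mulch` on
#' mulch, common spread `sigma`. The RGB image is composed so that its
#' HSV saturation equals the drawn plane exactly (hue is a fixed earthy
#' constant; value is moderate on soil and low on mulch).
#'
#' @param soil_fraction target bare-soil fraction in `[0, 1]`
#' @param mu_soil,mu_mulch class mean saturations, `0 <= mu_mulch <
#'   mu_soil <= 1`
#' @param sigma within-class saturation spread (default 0.05)
#' @param dims image size `c(m, n)` (rows, columns); default `c(120,
#'   240)`, a 1/100 linear scale of the 2400 x 1200 field frames
#' @param seed RNG seed; scenes are deterministic given the seed
#' @return list of class `synthetic_scene`: `image` ([rgb_image()]),
#'   `truth_mask` (logical matrix, TRUE = soil), `soil_fraction`,
#'   `mu_soil`, `mu_mulch`, `sigma`, `seed`
#' @export
make_scene <- function(soil_fraction, mu_soil = 0.5, mu_mulch = 0.1,
                       sigma = 0.05, dims = c(120, 240), seed = 1L) {
  if (soil_fraction < 0 || soil_fraction > 1)
    stop("soil_fraction must be in [0, 1]", call. = FALSE)
  if (!(mu_mulch >= 0 && mu_mulch < mu_soil && mu_soil <= 1))
    stop("need 0 <= mu_mulch < mu_soil <= 1", call. = FALSE)
  if (any(dims < 64))
    stop("dims must be at least 64 x 64", call. = FALSE)
  m <- dims[1]; n <- dims[2]
  set.seed(seed)
  truth <- blob_mask(m, n, soil_fraction)
  s <- matrix(0, m, n)
  npx <- sum(truth)
  s[truth]  <- rtruncnorm01(npx, mu_soil, sigma)
  s[!truth] <- rtruncnorm01(m * n - npx, mu_mulch, sigma)
  hue <- matrix(0.08, m, n)                      # earthy orange, constant
  value <- matrix(0.30, m, n); value[truth] <- 0.55
  img <- hsv_to_rgb(structure(list(hue = hue, saturation = s, value = value),
                              class = "hsv_image"))
  structure(list(image = img,
                 truth_mask = structure(truth,
                                        class = c("binary_mask", "matrix")),
                 soil_fraction = soil_fraction, mu_soil = mu_soil,
                 mu_mulch = mu_mulch, sigma = sigma, seed = seed),
            class = "synthetic_scene")
}

# blobby mask with exact pixel-count control via the empirical quantile
blob_mask <- function(m, n, soil_fraction) {
  if (soil_fraction == 0) return(matrix(FALSE, m, n))
  if (soil_fraction == 1) return(matrix(TRUE, m, n))
  noise <- matrix(rnorm(m * n), m, n)
  sm <- gaussian_smooth(noise, sigma = min(m, n) / 12)
  k <- round(soil_fraction * m * n)
  cut <- sort(as.vector(sm), decreasing = TRUE)[k]
  sm >= cut
}

# separable Gaussian smoothing with replicated edges
gaussian_smooth <- function(x, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half):half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  smooth1 <- function(mat) {           # along rows (down columns)
    padded <- rbind(mat[rep(1, half), , drop = FALSE], mat,
                    mat[rep(nrow(mat), half), , drop = FALSE])
    out <- apply(padded, 2, function(col)
      stats::filter(col, kern, sides = 2))
    out[(half + 1):(half + nrow(mat)), , drop = FALSE]
  }
  t(smooth1(t(smooth1(x))))
}

rtruncnorm01 <- function(n, mu, sigma) {
  lo <- pnorm((0 - mu) / sigma)
  hi <- pnorm((1 - mu) / sigma)
  mu + sigma * stats::qnorm(lo + runif(n) * (hi - lo))
}

#' Default synthetic experiment design
#'
#' Four material classes x 6 blocks, mirroring the field layout: two
#' biodegradable-like materials with high deterioration (soil fractions
#' 0.51 and 0.53), a polyethylene-like material with low deterioration
#' (0.18), and a paper-like material in between (0.41). Block-to-block
#' variation is drawn per scene with spread `block_sd` (default 0.05).
#'
#' @param block_sd between-block standard deviation of the soil fraction
#' @return data.frame with columns `mulch`, `label`, `soil_fraction`,
#'   `blocks`
#' @export
default_scene_design <- function(block_sd = 0.05) {
  data.frame(mulch = 1:4,
             label = c("BD1", "BD2", "PE", "PP"),
             soil_fraction = c(0.51, 0.53, 0.18, 0.41),
             block_sd = block_sd,
             blocks = 6L,
             stringsAsFactors = FALSE)
}

#' Generate a batch of synthetic scenes
#'
#' Builds one scene per (material, block) cell of the design with a
#' per-scene seed derived from the master seed, so two calls with the
#' same seed produce identical batches.
#'
#' @param design data.frame as produced by [default_scene_design()]
#' @param seed master seed
#' @param ... passed to [make_scene()] (e.g. `dims`, `mu_soil`)
#' @return list of `synthetic_scene` objects with attributes `mulch` and
#'   `block` set on each element's name (`"m<mulch>_b<block>"`)
#' @export
scene_batch <- function(design = default_scene_design(), seed = 1L, ...) {
  scenes <- list()
  idx <- 0L
  for (r in seq_len(nrow(design))) {
    for (b in seq_len(design$blocks[r])) {
      idx <- idx + 1L
      scene_seed <- (seed + 7919L * idx) %% .Machine$integer.max
      set.seed(scene_seed)
      sf <- design$soil_fraction[r] + rnorm(1, 0, design$block_sd[r])
      sf <- min(max(sf, 0.02), 0.98)
      scenes[[paste0("m", design$mulch[r], "_b", b)]] <-
        make_scene(sf, seed = scene_seed + 1L, ...)
    }
  }
  scenes
}
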