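#' Binarize a saturation plane
#'
#' A pixel is classified as bare soil (TRUE, white) iff its saturation
#' strictly exceeds the threshold; mulch (FALSE, black) otherwise. Soil is
#' the more saturated class because the black mulch films are nearly
#' achromatic.
#'
#' @param plane numeric matrix on `[0, 1]`
#' @param t a `threshold_result` or a single numeric threshold in `[0, 1]`
#' @return logical matrix of class `binary_mask` (TRUE = soil)
#' @export
binarize <- function(plane, t) {
  check_plane(plane)
  if (inherits(t, "threshold_result")) t <- t$t
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0 || t > 1)
    stop("threshold must be a single value in [0, 1]", call. = FALSE)
  mask <- unclass(plane) > t
  structure(mask, class = c("binary_mask", "matrix"))
}

#' Remove small objects from a binary mask
#'
#' Noise cleanup in two passes: (1) connected components of the
#' foreground with area strictly smaller than `floor(m * n / divisor)`
#' pixels are deleted; (2) the same rule is applied to the complement of
#' the result, which fills small holes. Components are labeled with
#' 8-connectivity by default.
#'
#' @param mask logical matrix (TRUE = soil)
#' @param divisor area rule divisor; the minimum surviving component area
#'   is `floor(m * n / divisor)` (default 100, i.e. 1% of the image)
#' @param connectivity 8 (default) or 4
#' @return cleaned `binary_mask`
#' @export
remove_small_objects <- function(mask, divisor = 100, connectivity = 8) {
  mask <- as_mask(mask)
  min_area <- floor(nrow(mask) * ncol(mask) / divisor)
  out <- drop_small_components(mask, min_area, connectivity)
  out <- !drop_small_components(!out, min_area, connectivity)
  structure(out, class = c("binary_mask", "matrix"))
}

drop_small_components <- function(mask, min_area, connectivity) {
  lab <- .label_components(mask, as.integer(connectivity))
  k <- max(lab)
  if (k == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = k)
  keep <- areas >= min_area
  out <- mask
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Percent bare-soil area of a mask
#'
#' 100 times the number of white (soil) pixels divided by the total pixel
#' count.
#'
#' @param mask logical matrix (TRUE = soil)
#' @return percentage in `[0, 100]`
#' @export
soil_area_percent <- function(mask) {
  mask <- as_mask(mask)
  100 * sum(mask) / length(mask)
}

#' Run the full soil-area pipeline on one image
#'
#' Composes the stages: RGB to HSV, saturation plane, histogram, threshold
#' selection, binarization, small-object removal, percent soil area. Both
#' the pre-cleanup and final areas are recorded.
#'
#' @param image an [rgb_image()] (or bare `m x n x 3` array)
#' @param method `"otsu"`, `"rc"`, `"le"` or `"manual"`
#' @param manual_t threshold in `[0, 1]`, required iff `method = "manual"`
#' @param image_id,mulch,block optional metadata copied into the record
#' @param divisor,connectivity cleanup parameters, see
#'   [remove_small_objects()]
#' @param le_variant passed to [local_entropy_threshold()]
#' @return one-row data.frame (an area record) with columns `image_id`,
#'   `mulch`, `block`, `method`, `t`, `area_pct_precleanup`, `area_pct`
#' @export
process_image <- function(image, method = c("otsu", "rc", "le", "manual"),
                          manual_t = NULL, image_id = NA, mulch = NA,
                          block = NA, divisor = 100, connectivity = 8,
                          le_variant = "cooccurrence") {
  method <- match.arg(method)
  if (method == "manual" && is.null(manual_t))
    stop("`manual_t` is required when method = \"manual\"", call. = FALSE)
  if (method != "manual" && !is.null(manual_t))
    stop("`manual_t` is only meaningful with method = \"manual\"",
         call. = FALSE)
  plane <- extract_saturation(rgb_to_hsv(image))
  tr <- switch(method,
    otsu   = otsu_threshold(saturation_histogram(plane)),
    rc     = ridler_calvard_threshold(saturation_histogram(plane)),
    le     = local_entropy_threshold(plane, variant = le_variant),
    manual = manual_threshold(manual_t))
  mask0 <- binarize(plane, tr)
  mask <- remove_small_objects(mask0, divisor = divisor,
                               connectivity = connectivity)
  data.frame(image_id = image_id, mulch = mulch, block = block,
             method = switch(method, otsu = "OT", rc = "RC", le = "LE",
                             manual = "MT"),
             t = tr$t,
             area_pct_precleanup = soil_area_percent(mask0),
             area_pct = soil_area_percent(mask),
             stringsAsFactors = FALSE)
}

#' Process a batch of images
#'
#' Applies [process_image()] to each element. Per-image failures (e.g. a
#' degenerate single-level histogram from an intact mulch frame) are
#' reported as a warning and skipped rather than aborting the batch; rows
#' are ordered lexicographically by `image_id`.
#'
#' @param images named list of `rgb_image` objects (names become
#'   `image_id`) or character vector of file paths
#' @param ... passed to [process_image()]
#' @return data.frame of area records, one row per successfully processed
#'   image
#' @export
process_batch <- function(images, ...) {
  if (is.character(images)) {
    paths <- images
    images <- lapply(paths, read_field_image)
    names(images) <- tools::file_path_sans_ext(basename(paths))
  }
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    tryCatch(process_image(images[[i]], image_id = ids[i], ...),
             error = function(e) {
               warning("image '", ids[i], "' skipped: ", conditionMessage(e),
                       call. = FALSE)
               NULL
             })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_area_records())
  out[order(out$image_id), , drop = FALSE]
}

empty_area_records <- function() {
  data.frame(image_id = character(0), mulch = numeric(0), block = numeric(0),
             method = character(0), t = numeric(0),
             area_pct_precleanup = numeric(0), area_pct = numeric(0),
             stringsAsFactors = FALSE)
}

as_mask <- function(mask) {
  m <- unclass(mask)
  if (!is.matrix(m) || !is.logical(m))
    stop("`mask` must be a logical matrix", call. = FALSE)
  m
}
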