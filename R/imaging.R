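#' Construct an RGB image
#'
#' Wraps an `m x n x 3` numeric array of channel intensities on `[0, 1]`
#' (as decoded from 8-bit sRGB) after validating it. All downstream
#' processing starts from this container.
#'
#' @param pixels numeric array of dimension `m x n x 3`, values in `[0, 1]`
#' @return an object of class `rgb_image` (the validated array)
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an m x n x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("pixel values must be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  structure(pixels, class = "rgb_image")
}

#' Read a color field photograph
#'
#' Reads an 8-bit PNG or JPEG color image and returns it as an
#' [rgb_image()] with channels on `[0, 1]`. PNG is read with the png
#' package; JPEG requires EBImage. Alpha channels are dropped; grayscale
#' input is replicated across the three channels.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file
#' @return an `rgb_image`
#' @export
read_field_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the EBImage package", call. = FALSE)
    img <- EBImage::readImage(path)
    px <- aperm(array(img, dim = dim(img)[c(1, 2, 3)]), c(2, 1, 3))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  rgb_image(pmin(pmax(px, 0), 1))
}

#' Convert an RGB image to HSV
#'
#' Standard per-pixel RGB to HSV conversion: `V = max(R, G, B)`,
#' `S = (max - min) / max` when `max > 0` and 0 otherwise (achromatic
#' pixels have zero saturation), hue on `[0, 1)`. Only the saturation
#' plane is used by the segmentation pipeline; hue and value are kept so
#' that the conversion is invertible.
#'
#' @param image an [rgb_image()] or bare `m x n x 3` array
#' @return object of class `hsv_image`: list with matrices `hue`,
#'   `saturation`, `value`
#' @export
rgb_to_hsv <- function(image) {
  image <- as_rgb_array(image)
  d <- dim(image)[1:2]
  flat <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(flat, maxColorValue = 1)
  structure(list(
    hue        = matrix(hsv[1, ] %% 1, d[1], d[2]),
    saturation = matrix(hsv[2, ], d[1], d[2]),
    value      = matrix(hsv[3, ], d[1], d[2])
  ), class = "hsv_image")
}

#' Convert HSV planes back to an RGB image
#'
#' Inverse of [rgb_to_hsv()]; used by the synthetic scene generator to
#' compose images with a prescribed saturation plane, and to check that
#' the conversion round-trips.
#'
#' @param hsv an `hsv_image`
#' @return an [rgb_image()]
#' @export
hsv_to_rgb <- function(hsv) {
  stopifnot(inherits(hsv, "hsv_image"))
  h <- as.vector(hsv$hue) * 6
  s <- as.vector(hsv$saturation)
  v <- as.vector(hsv$value)
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  d <- dim(hsv$saturation)
  rgb_image(array(c(r, g, b), dim = c(d, 3L)))
}

#' Extract the saturation plane
#'
#' Returns the S channel unchanged as a matrix on `[0, 1]`. In low-contrast
#' soil/mulch photographs this plane is the one whose histogram is bimodal,
#' so it is the image `f(x, y)` that the thresholding methods operate on.
#'
#' @param hsv an `hsv_image` from [rgb_to_hsv()]
#' @return numeric matrix on `[0, 1]` of class `saturation_plane`
#' @export
extract_saturation <- function(hsv) {
  stopifnot(inherits(hsv, "hsv_image"))
  structure(hsv$saturation, class = c("saturation_plane", "matrix"))
}

#' Quantize a saturation plane to 8-bit levels
#'
#' Maps each value `s` to bin `round(s * 255)` (round half to even), the
#' grid on which the published thresholds lie.
#'
#' @param plane numeric matrix on `[0, 1]`
#' @return integer matrix with values in `0..255`
#' @export
quantize_plane <- function(plane) {
  check_plane(plane)
  q <- round(unclass(plane) * 255)
  storage.mode(q) <- "integer"
  q
}

#' Histogram of a saturation plane
#'
#' Builds the 256-bin histogram of the quantized plane. Bin `k`
#' (`k = 0..255`) represents gray value `k / 255`.
#'
#' @param plane numeric matrix on `[0, 1]` (a `saturation_plane` or bare
#'   matrix)
#' @return object of class `gray_histogram`: list with integer `counts`
#'   (length 256, named by bin index 0..255), `probabilities`, and
#'   `levels = 256`
#' @export
saturation_histogram <- function(plane) {
  q <- quantize_plane(plane)
  counts <- tabulate(as.vector(q) + 1L, nbins = 256L)
  gray_histogram(counts)
}

#' Construct a gray-level histogram
#'
#' @param counts non-negative integer vector of length 256 (bins 0..255)
#' @return a `gray_histogram`
#' @export
gray_histogram <- function(counts) {
  if (length(counts) != 256L || any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be 256 non-negative integers", call. = FALSE)
  total <- sum(counts)
  if (total < 1) stop("histogram is empty", call. = FALSE)
  structure(list(
    counts = as.integer(counts),
    probabilities = counts / total,
    levels = 256L
  ), class = "gray_histogram")
}

#' Gray value represented by a histogram bin
#'
#' @param k bin index in `0..255`
#' @return `k / 255` on the `[0, 1]` scale
#' @export
bin_value <- function(k) k / 255

# ---- internal helpers -------------------------------------------------------

as_rgb_array <- function(image) {
  if (inherits(image, "rgb_image")) return(unclass(image))
  unclass(rgb_image(image))
}

check_plane <- function(plane) {
  if (!is.matrix(unclass(plane)))
    stop("`plane` must be a matrix", call. = FALSE)
  v <- unclass(plane)
  if (!all(is.finite(v)) || min(v) < 0 || max(v) > 1)
    stop("plane values must be finite and in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

check_histogram <- function(hist) {
  if (!inherits(hist, "gray_histogram"))
    stop("expected a `gray_histogram`", call. = FALSE)
  invisible(TRUE)
}
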