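#' Mammogram image objects
#'
#' A `mammogram_image` bundles an 8-bit grayscale pixel matrix with a binary
#' breast-region mask of the same shape. All texture features are computed
#' from pixels inside the mask only; everything outside is background.
#'
#' @param pixels Integer matrix of gray values in `[0, 255]`.
#' @param mask Logical matrix of the same shape, `TRUE` inside the breast
#'   region. Must contain at least one `TRUE` pixel.
#'
#' @return An object of class `mammogram_image`: a list with elements
#'   `pixels` (integer matrix) and `mask` (logical matrix).
#' @examples
#' img <- mammogram_image(matrix(0:255, 16, 16), matrix(TRUE, 16, 16))
#' dim(img$pixels)
#' @export
mammogram_image <- function(pixels, mask = NULL) {
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix.")
  px <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  if (anyNA(px) || any(px < 0L) || any(px > 255L)) {
    abort("`pixels` must contain gray values in [0, 255].")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(px), ncol(px))
  if (!is.matrix(mask) || !identical(dim(mask), dim(px))) {
    abort("`mask` must be a logical matrix with the same shape as `pixels`.")
  }
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (anyNA(mask)) abort("`mask` must not contain missing values.")
  if (!any(mask)) abort("`mask` must contain at least one TRUE pixel.")
  structure(list(pixels = px, mask = mask), class = "mammogram_image")
}

#' @export
print.mammogram_image <- function(x, ...) {
  cat(sprintf(
    "<mammogram_image> %d x %d pixels, %d in mask (%.1f%%)\n",
    nrow(x$pixels), ncol(x$pixels), sum(x$mask),
    100 * mean(x$mask)
  ))
  invisible(x)
}

#' Percentage mammographic density by gray-level thresholding
#'
#' The threshold definition of percentage mammographic density (PMD): the
#' percentage of breast-region pixels whose gray value is at or above a
#' threshold, emulating computer-assisted threshold density assessment.
#'
#' @param image A [mammogram_image()].
#' @param threshold Gray value in `[0, 255]`; pixels with `gray >= threshold`
#'   count as dense. Default 128.
#'
#' @return PMD as a percentage in `[0, 100]`.
#' @examples
#' img <- generate_mammogram(64, 64, target_pmd = 40, seed = 1)
#' threshold_pmd(img)
#' @export
threshold_pmd <- function(image, threshold = 128) {
  check_image(image)
  stopifnot_scalar_number(threshold, "threshold")
  if (threshold < 0 || threshold > 255) {
    abort("`threshold` must lie in [0, 255].")
  }
  g <- image$pixels[image$mask]
  if (length(g) == 0) abort("Mask is empty; PMD is undefined.")
  100 * mean(g >= threshold)
}

#' Quantize gray levels for co-occurrence and run-length analysis
#'
#' Reduces the 256 gray values to `G` equal-width levels,
#' `level = floor(gray / (256 / G))`, keeping the mask.
#'
#' @param image A [mammogram_image()].
#' @param G Number of gray levels; must divide 256 (the package uses 64 for
#'   co-occurrence features and 16 for run-length features).
#'
#' @return A `quantized_image`: list with `levels` (integer matrix in
#'   `[0, G - 1]`), `G`, and `mask`.
#' @examples
#' q <- quantize_gray_levels(generate_mammogram(64, 64, 50, seed = 1), G = 16)
#' range(q$levels)
#' @export
quantize_gray_levels <- function(image, G) {
  check_image(image)
  if (length(G) != 1L || G <= 0 || 256 %% G != 0) {
    abort("`G` must be a positive divisor of 256.")
  }
  width <- 256 / G
  lv <- matrix(as.integer(image$pixels %/% width), nrow(image$pixels))
  structure(list(levels = lv, G = as.integer(G), mask = image$mask),
            class = "quantized_image")
}

check_image <- function(image) {
  if (!inherits(image, "mammogram_image")) {
    abort("Expected a `mammogram_image` object; see `mammogram_image()`.")
  }
  invisible(image)
}

#' Read and write mammogram images as PNG
#'
#' Images are stored as 8-bit grayscale PNG; masks as 0/255 PNG.
#'
#' @param path,mask_path Paths to the image and (optionally) mask PNG files.
#' @param image A [mammogram_image()].
#' @return `read_mammogram()` returns a [mammogram_image()];
#'   `write_mammogram()` invisibly returns `path`.
#' @examples
#' img <- generate_mammogram(48, 48, 30, seed = 2)
#' p <- tempfile(fileext = ".png")
#' write_mammogram(img, p)
#' img2 <- read_mammogram(p)
#' identical(img$pixels, img2$pixels)
#' @export
read_mammogram <- function(path, mask_path = NULL) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  px <- round(arr * 255)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    mask <- m > 0.5
  }
  mammogram_image(px, mask)
}

#' @rdname read_mammogram
#' @export
write_mammogram <- function(image, path, mask_path = NULL) {
  check_image(image)
  png::writePNG(image$pixels / 255, path)
  if (!is.null(mask_path)) {
    png::writePNG(image$mask * 1.0, mask_path)
  }
  invisible(path)
}
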