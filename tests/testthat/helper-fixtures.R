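# Small programmatic fixtures shared across test files.

# Full-mask image from a pixel matrix.
mk_img <- function(px) mammogram_image(px, matrix(TRUE, nrow(px), ncol(px)))

# Constant-gray full-mask image.
const_img <- function(gray = 100L, h = 20L, w = 20L) {
  mk_img(matrix(as.integer(gray), h, w))
}

# The classic 2 x 2 quantized toy: rows (0, 0) and (1, 1) at G = 2.
toy_glcm_image <- function() {
  quantize_gray_levels(mk_img(matrix(c(0L, 255L, 0L, 255L), 2, 2)), G = 2)
}

# iid-noise feature table.
noise_features <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    tbl <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * p), n, p)))
    names(tbl) <- sprintf("f%02d", seq_len(p))
    tbl
  })
}

# Linear-signal regression problem with true R^2 = r2 (5 active features,
# unit slopes).
linear_pmd_problem <- function(n, p = 50, r2 = 0.7, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- sprintf("f%02d", seq_len(p))
    k <- min(5L, p)
    signal <- rowSums(x[, seq_len(k), drop = FALSE])
    sigma <- sqrt(k * (1 - r2) / r2)
    y <- signal + rnorm(n, sd = sigma)
    list(X = tibble::as_tibble(as.data.frame(x)), y = y)
  })
}

expect_no_ties <- function(a, b) {
  expect_true(all(a != b))
}
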