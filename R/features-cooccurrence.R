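# Offsets (drow, dcol) for the four standard orientations, with 0 degrees
# pointing east (+x) and 90 degrees pointing north (row index decreasing).
orientation_offset <- function(orientation, distance = 1L) {
  d <- as.integer(distance)
  switch(as.character(orientation),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    abort("`orientation` must be one of 0, 45, 90, 135 degrees.")
  )
}

#' Gray-level co-occurrence matrix
#'
#' Estimates the probability that two in-mask pixels at a given distance
#' and orientation carry a given pair of gray levels. Pairs are counted in
#' both directions, so the matrix is symmetric, and it is normalized to
#' sum to 1. Pairs with either pixel outside the mask are ignored.
#'
#' @param q A [quantize_gray_levels()] result.
#' @param distance Pixel offset between the two pixels (>= 1).
#' @param orientation One of 0, 45, 90, 135 (degrees; 0 = east, 90 = north).
#'
#' @return A `G x G` matrix of pair probabilities.
#' @examples
#' img <- mammogram_image(matrix(c(0, 255, 0, 255), 2, 2))
#' q <- quantize_gray_levels(img, G = 2)
#' cooccurrence_matrix(q, 1, 0)
#' @export
cooccurrence_matrix <- function(q, distance = 1, orientation = 0) {
  if (!inherits(q, "quantized_image")) {
    abort("`q` must be a `quantized_image`; see `quantize_gray_levels()`.")
  }
  if (distance < 1) abort("`distance` must be >= 1.")
  off <- orientation_offset(orientation, distance)
  lv <- q$levels; m <- q$mask; G <- q$G
  h <- nrow(lv); w <- ncol(lv)
  r0 <- max(1L, 1L - off[1]):min(h, h - off[1])
  c0 <- max(1L, 1L - off[2]):min(w, w - off[2])
  if (length(r0) == 0 || length(c0) == 0) {
    abort("No valid pixel pairs at this distance/orientation.")
  }
  a <- lv[r0, c0, drop = FALSE]
  b <- lv[r0 + off[1], c0 + off[2], drop = FALSE]
  ok <- m[r0, c0, drop = FALSE] & m[r0 + off[1], c0 + off[2], drop = FALSE]
  if (!any(ok)) abort("No valid pixel pairs at this distance/orientation.")
  ai <- a[ok]; bi <- b[ok]
  counts <- tabulate(ai * G + bi + 1L, nbins = G * G) +
    tabulate(bi * G + ai + 1L, nbins = G * G)
  matrix(counts / sum(counts), G, G, byrow = TRUE)
}

# Sum (i + j) and difference |i - j| histograms of a co-occurrence matrix.
sum_diff_histograms <- function(P) {
  G <- nrow(P)
  i <- as.vector(row(P)) - 1L
  j <- as.vector(col(P)) - 1L
  p <- as.vector(P)
  ps <- vapply(split(p, i + j), sum, numeric(1))
  ps <- unname(ps[order(as.integer(names(ps)))])
  pd_raw <- vapply(split(p, abs(i - j)), sum, numeric(1))
  pd <- numeric(G)
  pd[as.integer(names(pd_raw)) + 1L] <- pd_raw
  list(ps = ps, ps_k = 0:(2 * G - 2), pd = pd, pd_k = 0:(G - 1))
}

# The 13 classical co-occurrence statistics plus derived pieces for one
# orientation. Correlation with zero marginal variance is defined as 0.
haralick_from_glcm <- function(P) {
  G <- nrow(P)
  i <- 0:(G - 1)
  px <- rowSums(P)
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  hd <- sum_diff_histograms(P)
  asm <- sum(P^2)
  contrast <- sum(hd$pd_k^2 * hd$pd)
  corr <- if (sig2 > 0) {
    (sum(outer(i, i) * P) - mu^2) / sig2
  } else 0
  idm <- sum(hd$pd / (1 + hd$pd_k^2))
  sum_avg <- sum(hd$ps_k * hd$ps)
  sum_var <- sum((hd$ps_k - sum_avg)^2 * hd$ps)
  sum_ent <- shannon_entropy(hd$ps)
  ent <- shannon_entropy(as.vector(P))
  d_mu <- sum(hd$pd_k * hd$pd)
  d_var <- sum((hd$pd_k - d_mu)^2 * hd$pd)
  d_ent <- shannon_entropy(hd$pd)
  hx <- shannon_entropy(px)
  # hxy1 = hxy2 = H(px) + H(py) analytically; the matrix is symmetric.
  hxy1 <- 2 * hx
  imc1 <- if (hx > 0) (ent - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy1 - ent))))
  list(
    stats = c(asm = asm, contrast = contrast, correlation = corr,
              variance = sig2, idm = idm, sum_average = sum_avg,
              sum_variance = sum_var, sum_entropy = sum_ent, entropy = ent,
              diff_variance = d_var, diff_entropy = d_ent,
              imc1 = imc1, imc2 = imc2),
    sumhist = c(sumhist_mean = sum_avg, sumhist_variance = sum_var,
                sumhist_energy = sum(hd$ps^2), sumhist_entropy = sum_ent),
    diffhist = c(diffhist_mean = d_mu, diffhist_variance = d_var,
                 diffhist_energy = sum(hd$pd^2), diffhist_entropy = d_ent,
                 diffhist_invdiff = idm)
  )
}

#' Markovian (co-occurrence) features (93 values)
#'
#' Second-order texture statistics describing the spatial relationship of
#' gray levels, computed from distance-1 co-occurrence matrices and their
#' sum/difference histograms at the four standard orientations. Per
#' orientation: the 13 classical co-occurrence statistics (angular second
#' moment, contrast, correlation, variance, inverse difference moment, sum
#' average/variance/entropy, entropy, difference variance/entropy, and the
#' two information measures of correlation), four sum-histogram statistics
#' (mean, variance, energy, entropy) and five difference-histogram
#' statistics (mean, variance, energy, entropy, inverse difference). Five
#' orientation-averaged statistics (contrast, correlation, energy, entropy,
#' inverse difference moment) complete the family: 4 x 22 + 5 = 93.
#'
#' @param q A [quantize_gray_levels()] result (the pipeline uses `G = 64`).
#' @return Named numeric vector of 93 finite values.
#' @examples
#' img <- generate_mammogram(64, 64, 40, seed = 1)
#' f <- markovian_features(quantize_gray_levels(img, 64))
#' f["markovian.avg.contrast"]
#' @export
markovian_features <- function(q) {
  per <- lapply(c(0, 45, 90, 135), function(o) {
    haralick_from_glcm(cooccurrence_matrix(q, 1, o))
  })
  block <- vapply(per, function(x) c(x$stats, x$sumhist, x$diffhist),
                  numeric(22))
  avg <- c(
    contrast = mean(vapply(per, function(x) x$stats[["contrast"]], 1)),
    correlation = mean(vapply(per, function(x) x$stats[["correlation"]], 1)),
    energy = mean(vapply(per, function(x) x$stats[["asm"]], 1)),
    entropy = mean(vapply(per, function(x) x$stats[["entropy"]], 1)),
    idm = mean(vapply(per, function(x) x$stats[["idm"]], 1))
  )
  setNames(c(as.vector(t(block)), avg), markovian_feature_names())
}
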