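#' Moment-based and histogram features (92 values)
#'
#' First-order statistics of the gray-level distribution inside the breast
#' mask, with no regard to pixel arrangement.
#'
#' The moment family (76 values) consists of the four central moments
#' (mean, variance, skewness, kurtosis), the normalized central moments
#' (NCM) `m_k = mu_k / sigma^k` for orders `k = 2..19`, and three fixed
#' monotone transformations of each NCM that compress their extreme range:
#' `sign(m) * log(1 + |m|)`, `sign(m) * |m|^(1/k)` and `m / (1 + |m|)`.
#' For a constant region (`sigma = 0`) skewness, kurtosis and all NCMs are
#' defined as 0 so feature vectors stay finite.
#'
#' The histogram family (16 values) divides the full gray spectrum
#' `[0, 256)` into 16 equal-width categories and reports the relative
#' frequency of masked pixels in each; the 16 values sum to 1.
#'
#' @param image A [mammogram_image()] with a non-empty mask.
#' @return Named numeric vector of 92 values (76 `moment.*` then 16
#'   `histogram.bin.*`).
#' @examples
#' f <- intensity_features(generate_mammogram(64, 64, 50, seed = 1))
#' f["moment.mean"]
#' @export
intensity_features <- function(image) {
  check_image(image)
  g <- as.numeric(image$pixels[image$mask])
  n <- length(g)
  mu <- mean(g)
  cent <- g - mu
  s2 <- mean(cent^2)
  s <- sqrt(s2)

  moments <- c(mu, s2,
               if (s > 0) mean(cent^3) / s^3 else 0,
               if (s > 0) mean(cent^4) / s^4 else 0)

  ks <- 2:19
  if (s > 0) {
    ncm <- vapply(ks, function(k) mean(cent^k) / s^k, numeric(1))
  } else {
    ncm <- rep(0, length(ks))
  }
  t_log <- sign(ncm) * log1p(abs(ncm))
  t_root <- sign(ncm) * abs(ncm)^(1 / ks)
  t_ratio <- ncm / (1 + abs(ncm))

  bins <- tabulate(pmin(g %/% 16, 15) + 1, nbins = 16) / n

  setNames(c(moments, ncm, t_log, t_root, t_ratio, bins),
           c(moment_feature_names(), histogram_feature_names()))
}
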