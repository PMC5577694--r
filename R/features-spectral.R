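# Crop the image to the mask bounding box, replacing pixels outside the
# mask by the masked mean so that the mask edge does not dominate the
# spectrum ("mean-fill windowing").
mask_crop_mean_fill <- function(image) {
  rr <- range(which(rowSums(image$mask) > 0))
  cc <- range(which(colSums(image$mask) > 0))
  crop <- image$pixels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  m <- image$mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  mu <- mean(image$pixels[image$mask])
  crop[!m] <- mu
  crop
}

fourier_features_impl <- function(crop) {
  h <- nrow(crop); w <- ncol(crop)
  z <- crop - mean(crop)
  pow <- Mod(fft(z))^2
  pow[1, 1] <- 0 # remove any residual DC
  fr <- fft_freq(h); fc <- fft_freq(w)
  r <- sqrt(outer(fr^2, fc^2, `+`))
  total <- sum(pow)
  annulus <- numeric(16); sector <- numeric(16); centroid <- 0
  if (total > 1e-12) {
    in_band <- r > 0 & r <= 0.5
    rv <- r[in_band]; pv <- pow[in_band]
    # 16 equal-width annuli up to the Nyquist radius (right-closed bins)
    a_idx <- pmin(ceiling(rv / (0.5 / 16)), 16L)
    annulus <- as.vector(rowsum(pv, factor(a_idx, levels = 1:16))) / total
    # 16 angular sectors of 11.25 degrees over [0, 180)
    theta <- outer(fr, fc, function(y, x) atan2(y, x))[in_band] %% pi
    s_idx <- pmin(floor(theta / (pi / 16)) + 1L, 16L)
    sector <- as.vector(rowsum(pv, factor(s_idx, levels = 1:16))) / total
    band_total <- sum(pv)
    centroid <- if (band_total > 0) sum(rv * pv) / band_total else 0
  }
  setNames(c(annulus, sector, centroid), fourier_feature_names())
}

# One level of a separable 2-D Daubechies-4 (4-tap) wavelet decomposition
# with periodic boundary handling; odd dimensions are padded by
# replicating the last row/column.
dwt2_level <- function(x) {
  if (nrow(x) %% 2L == 1L) x <- rbind(x, x[nrow(x), ])
  if (ncol(x) %% 2L == 1L) x <- cbind(x, x[, ncol(x)])
  s3 <- sqrt(3)
  lo <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  hi <- c(lo[4], -lo[3], lo[2], -lo[1])
  step1 <- function(v) {
    n <- length(v)
    idx <- function(k) ((seq(0, n - 2, by = 2) + k) %% n) + 1
    list(
      a = lo[1] * v[idx(0)] + lo[2] * v[idx(1)] +
        lo[3] * v[idx(2)] + lo[4] * v[idx(3)],
      d = hi[1] * v[idx(0)] + hi[2] * v[idx(1)] +
        hi[3] * v[idx(2)] + hi[4] * v[idx(3)]
    )
  }
  cols <- apply(x, 2, step1)
  L <- vapply(cols, `[[`, numeric(nrow(x) / 2), "a")
  H <- vapply(cols, `[[`, numeric(nrow(x) / 2), "d")
  rows_of <- function(mat) {
    out <- apply(mat, 1, step1)
    list(
      a = t(vapply(out, `[[`, numeric(ncol(mat) / 2), "a")),
      d = t(vapply(out, `[[`, numeric(ncol(mat) / 2), "d"))
    )
  }
  Lr <- rows_of(L); Hr <- rows_of(H)
  list(ll = Lr$a, lh = Lr$d, hl = Hr$a, hh = Hr$d)
}

wavelet_features_impl <- function(crop) {
  x <- crop - mean(crop)
  energies <- matrix(0, 3, wavelet_levels,
                     dimnames = list(wavelet_bands, NULL))
  entropies <- energies
  approx <- x
  for (l in seq_len(wavelet_levels)) {
    dec <- dwt2_level(approx)
    for (b in wavelet_bands) {
      cc <- as.vector(dec[[b]])
      e <- sum(cc^2)
      energies[b, l] <- e
      entropies[b, l] <- if (e > 0) shannon_entropy(cc^2 / e) else 0
    }
    approx <- dec$ll
  }
  e_approx <- sum(approx^2)
  total <- sum(energies) + e_approx
  efrac <- if (total > 0) energies / total else energies
  setNames(
    c(as.vector(t(energies)), as.vector(t(efrac)), as.vector(t(entropies)),
      e_approx),
    wavelet_feature_names()
  )
}

#' Fourier and wavelet spectral features (70 values)
#'
#' Frequency-domain texture descriptors computed on the mask bounding box
#' with mean-fill windowing (pixels outside the mask are replaced by the
#' masked mean before transforming).
#'
#' Fourier family (33): the power spectrum of the mean-subtracted crop is
#' partitioned into 16 equal-width radial annuli up to the Nyquist
#' frequency and 16 angular sectors of 11.25 degrees over `[0, 180)`;
#' each bin's share of total spectral power is reported, plus the spectral
#' centroid radius (power-weighted mean frequency radius, cycles/pixel).
#' For a constant region (zero spectral power) all values are 0.
#'
#' Wavelet family (37): a 4-level separable Daubechies-4 decomposition;
#' per level, the energies of the LH, HL and HH detail sub-images, their
#' fractions of total decomposition energy, and the Shannon entropy of
#' each detail sub-band's normalized squared coefficients, plus the energy
#' of the final approximation: 4 x 9 + 1 = 37.
#'
#' @param image A [mammogram_image()] whose mask bounding box is at least
#'   16 x 16 pixels.
#' @return Named numeric vector of 70 values (33 `fourier.*` then 37
#'   `wavelet.*`).
#' @examples
#' f <- spectral_features(generate_mammogram(64, 64, 40, seed = 1))
#' sum(f[grep("fourier.annulus", names(f))]) # <= 1
#' @export
spectral_features <- function(image) {
  check_image(image)
  crop <- mask_crop_mean_fill(image)
  if (nrow(crop) < 16 || ncol(crop) < 16) {
    abort("Mask bounding box smaller than 16 x 16: spectral features undefined.")
  }
  c(fourier_features_impl(crop), wavelet_features_impl(crop))
}
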