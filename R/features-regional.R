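#' Regional features (48 values)
#'
#' Pixels are clustered into regions by a gray-level similarity criterion:
#' at each of eight thresholds `t` in `{32, 64, ..., 224, 256}` the masked
#' image is binarized (`gray >= t`) and 4-connected components are found
#' inside the mask. Six statistics summarize the region set at each
#' threshold: `log(1 + number of regions)`, mean region area, standard
#' deviation of region areas, mean compactness `4*pi*A / P^2` (P = region
#' perimeter in pixel edges), the largest region's share of the mask area,
#' and the mean of the regions' mean gray values. At `t = 256` no pixel
#' qualifies and all statistics default to 0, as they do whenever the
#' region set is empty; 8 x 6 = 48.
#'
#' @param image A [mammogram_image()] with a non-empty mask.
#' @return Named numeric vector of 48 finite values.
#' @examples
#' f <- regional_features(generate_mammogram(64, 64, 40, seed = 1))
#' f["regional.log_n_regions.t128"]
#' @export
regional_features <- function(image) {
  check_image(image)
  mask_area <- sum(image$mask)
  px <- image$pixels
  block <- vapply(regional_thresholds, function(t) {
    bin <- (px >= t) & image$mask
    if (!any(bin)) {
      return(setNames(numeric(6), regional_stats))
    }
    lab <- label_components4(bin)
    nreg <- max(lab)
    areas <- tabulate(lab[lab > 0L], nbins = nreg)
    perim <- component_perimeters(lab, nreg)
    mean_grays <- as.vector(
      rowsum(as.numeric(px[lab > 0L]), lab[lab > 0L])
    ) / areas
    compact <- 4 * pi * areas / perim^2
    c(
      log_n_regions = log1p(nreg),
      mean_area = mean(areas),
      sd_area = if (nreg > 1) sd(areas) else 0,
      mean_compactness = mean(compact),
      largest_fraction = max(areas) / mask_area,
      mean_gray = mean(mean_grays)
    )
  }, numeric(6))
  setNames(as.vector(t(block)), regional_feature_names())
}

# 4-connected component labeling of a logical matrix (EBImage's bwlabel
# uses 4-connectivity). Returns an integer matrix, 0 = background.
label_components4 <- function(bin) {
  lab <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  matrix(as.integer(lab), nrow(bin), ncol(bin))
}

# Perimeter of each labeled region, counted in exposed pixel edges
# (4-neighborhood; frame boundaries count as exposed).
component_perimeters <- function(lab, nreg) {
  h <- nrow(lab); w <- ncol(lab)
  padded <- matrix(0L, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- lab
  core <- padded[2:(h + 1L), 2:(w + 1L)]
  perim <- numeric(nreg)
  for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- padded[2:(h + 1L) + sh[1], 2:(w + 1L) + sh[2]]
    exposed <- core > 0L & nb != core
    if (any(exposed)) {
      cnt <- tabulate(core[exposed], nbins = nreg)
      perim <- perim + cnt
    }
  }
  perim
}
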