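# Data-driven feature registry. All extractors derive their output names
# from these generators, so the inventory can be revised in one place
# without touching extractor logic.

orientations4 <- c("d000", "d045", "d090", "d135")

haralick_stats <- c("asm", "contrast", "correlation", "variance", "idm",
                    "sum_average", "sum_variance", "sum_entropy", "entropy",
                    "diff_variance", "diff_entropy", "imc1", "imc2")
sumhist_stats <- c("sumhist_mean", "sumhist_variance", "sumhist_energy",
                   "sumhist_entropy")
diffhist_stats <- c("diffhist_mean", "diffhist_variance", "diffhist_energy",
                    "diffhist_entropy", "diffhist_invdiff")
avg_stats <- c("contrast", "correlation", "energy", "entropy", "idm")

runlength_stats <- c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp",
                     "glv", "rlv", "lgre", "hgre", "srlge", "srhge",
                     "lrlge", "lrhge")

regional_thresholds <- c(32L, 64L, 96L, 128L, 160L, 192L, 224L, 256L)
regional_stats <- c("log_n_regions", "mean_area", "sd_area",
                    "mean_compactness", "largest_fraction", "mean_gray")

wavelet_bands <- c("lh", "hl", "hh")
wavelet_levels <- 4L

moment_feature_names <- function() {
  ks <- sprintf("k%02d", 2:19)
  c(paste0("moment.", c("mean", "variance", "skewness", "kurtosis")),
    paste0("moment.ncm.", ks),
    paste0("moment.ncm_log.", ks),
    paste0("moment.ncm_root.", ks),
    paste0("moment.ncm_ratio.", ks))
}

histogram_feature_names <- function() {
  sprintf("histogram.bin.%02d", 0:15)
}

markovian_feature_names <- function() {
  per_or <- c(haralick_stats, sumhist_stats, diffhist_stats)
  c(as.vector(t(outer(per_or, orientations4, paste, sep = "."))),
    paste0("avg.", avg_stats)) |>
    (\(x) paste0("markovian.", x))()
}

regional_feature_names <- function() {
  paste0("regional.",
         as.vector(t(outer(regional_stats,
                           sprintf("t%03d", regional_thresholds),
                           paste, sep = "."))))
}

runlength_feature_names <- function() {
  paste0("runlength.",
         as.vector(t(outer(runlength_stats, orientations4, paste, sep = "."))))
}

fourier_feature_names <- function() {
  c(sprintf("fourier.annulus.%02d", 1:16),
    sprintf("fourier.sector.%02d", 1:16),
    "fourier.centroid_radius")
}

wavelet_feature_names <- function() {
  lv <- sprintf("l%d", seq_len(wavelet_levels))
  per_level <- function(stat) {
    as.vector(t(outer(paste0(stat, ".", wavelet_bands), lv, paste, sep = ".")))
  }
  c(paste0("wavelet.", c(per_level("energy"), per_level("efrac"),
                         per_level("entropy"))),
    "wavelet.approx_energy")
}

#' Registry of the 363 texture features
#'
#' The fixed inventory of texture-feature names and families computed by
#' [extract_features()], in extraction order. Family sizes are 76
#' (moment-based), 16 (histogram), 93 (Markovian), 48 (regional), 60
#' (run-length), 33 (Fourier) and 37 (wavelet). Names follow the scheme
#' `<family>.<statistic>[.<orientation|level|threshold|bin>]`.
#'
#' @return A tibble with columns `name` and `family` (363 rows).
#' @examples
#' dplyr::count(feature_registry(), family)
#' @export
feature_registry <- function() {
  tibble::tibble(
    name = c(moment_feature_names(), histogram_feature_names(),
             markovian_feature_names(), regional_feature_names(),
             runlength_feature_names(), fourier_feature_names(),
             wavelet_feature_names()),
    family = rep(
      c("moment", "histogram", "markovian", "regional", "runlength",
        "fourier", "wavelet"),
      times = c(76L, 16L, 93L, 48L, 60L, 33L, 37L)
    )
  )
}
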