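#' Extract the full 363-feature texture vector from a mammogram
#'
#' Runs all seven feature families on one masked image and concatenates
#' them in the fixed order of [feature_registry()]: 76 moment-based, 16
#' histogram, 93 Markovian (co-occurrence at 64 gray levels), 48 regional,
#' 60 run-length (16 gray levels), 33 Fourier and 37 wavelet features.
#' Extraction is deterministic: the same image always yields bit-identical
#' values.
#'
#' @param image A [mammogram_image()].
#' @return A one-row tibble with 363 named numeric columns, suitable for
#'   row-binding into a cohort feature table.
#' @examples
#' feats <- extract_features(generate_mammogram(64, 64, 40, seed = 1))
#' ncol(feats)
#' @export
extract_features <- function(image) {
  check_image(image)
  vals <- c(
    intensity_features(image),
    markovian_features(quantize_gray_levels(image, 64L)),
    regional_features(image),
    run_length_features(quantize_gray_levels(image, 16L)),
    spectral_features(image)
  )
  reg <- feature_registry()
  if (!identical(names(vals), reg$name)) {
    abort("Internal error: extracted names do not match the registry.")
  }
  if (any(!is.finite(vals))) {
    abort(paste0("Non-finite feature value(s): ",
                 paste(head(names(vals)[!is.finite(vals)], 5), collapse = ", ")))
  }
  tibble::as_tibble(as.list(vals))
}

#' Extract a feature table for a list of images
#'
#' @param images List of [mammogram_image()] objects.
#' @param patient_id Optional identifier vector (defaults to `1..n`).
#' @return A tibble with `patient_id` plus the 363 feature columns, one
#'   row per image.
#' @examples
#' imgs <- lapply(1:2, function(s) generate_mammogram(48, 48, 30, seed = s))
#' extract_feature_table(imgs)[, 1:3]
#' @export
extract_feature_table <- function(images, patient_id = NULL) {
  if (is.null(patient_id)) patient_id <- seq_along(images)
  rows <- purrr::map(images, extract_features)
  dplyr::bind_cols(tibble::tibble(patient_id = patient_id),
                   dplyr::bind_rows(rows))
}
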