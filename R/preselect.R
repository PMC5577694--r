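#' Configuration for texture-feature preselection
#'
#' @param skew_threshold Features with absolute sample skewness above this
#'   value are dropped before correlation pruning (an automated stand-in
#'   for visual box-plot screening of extremely skewed features). Default
#'   10; use `Inf` to disable.
#' @param corr_cutoff Spearman correlation cutoff in `(0, 1]`: a feature is
#'   dropped when its absolute correlation with a higher-ranked retained
#'   feature exceeds this value. Default 0.98.
#' @param forced_keep Feature names accepted unconditionally, bypassing
#'   both rules. Defaults to the basic intensity features: the four
#'   central moments and the 16 histogram features.
#' @param seed Integer seed for the random feature ordering.
#'
#' @return A list of class `preselection_config`.
#' @examples
#' preselection_config(corr_cutoff = 0.95)$corr_cutoff
#' @export
preselection_config <- function(skew_threshold = 10, corr_cutoff = 0.98,
                                forced_keep = default_forced_keep(),
                                seed = 1) {
  if (!(corr_cutoff > 0 && corr_cutoff <= 1)) {
    abort("`corr_cutoff` must lie in (0, 1].")
  }
  if (skew_threshold < 0) abort("`skew_threshold` must be non-negative.")
  structure(list(skew_threshold = skew_threshold, corr_cutoff = corr_cutoff,
                 forced_keep = forced_keep, seed = as.integer(seed)),
            class = "preselection_config")
}

#' @rdname preselection_config
#' @export
default_forced_keep <- function() {
  c(paste0("moment.", c("mean", "variance", "skewness", "kurtosis")),
    histogram_feature_names())
}

#' Reduce a feature table to an analysis set
#'
#' Two-stage redundancy pruning of a cohort feature table, performed once
#' on the complete table before any cross-validation (it uses no outcome
#' information, so it does not bias later model assessment):
#' (1) features with absolute sample skewness above `skew_threshold` are
#' dropped; (2) the remaining features are put in random order and walked
#' top to bottom, dropping any feature whose absolute Spearman correlation
#' with an already-retained, higher-ranked feature exceeds `corr_cutoff`.
#' The absolute correlation is used deliberately: a sign-flipped duplicate
#' is just as redundant as an identical one. `forced_keep` features are
#' re-added unconditionally. Constant features have an undefined Spearman
#' correlation; they are treated as uncorrelated (kept, subject to the
#' skewness rule).
#'
#' @param table Feature table: a data frame whose numeric columns are
#'   features (an id column named `patient_id` is ignored); at least 2
#'   rows.
#' @param config A [preselection_config()].
#'
#' @return Character vector of retained feature names, in the column order
#'   of the input table.
#' @examples
#' tbl <- tibble::tibble(a = rnorm(20), b = rnorm(20))
#' tbl$c <- tbl$a # duplicate
#' preselect_features(tbl, preselection_config(forced_keep = character()))
#' @export
preselect_features <- function(table, config = preselection_config()) {
  if (!inherits(config, "preselection_config")) {
    abort("`config` must be a `preselection_config` object.")
  }
  tbl <- as.data.frame(table)
  tbl <- tbl[, setdiff(names(tbl), "patient_id"), drop = FALSE]
  if (nrow(tbl) < 2) abort("At least 2 rows are required for preselection.")
  if (!all(vapply(tbl, is.numeric, logical(1)))) {
    abort("All feature columns must be numeric.")
  }
  feats <- names(tbl)
  unknown <- setdiff(config$forced_keep, feats)
  if (length(unknown) > 0) {
    abort(paste0("`forced_keep` names not in table: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }

  skew <- vapply(tbl, sample_skewness, numeric(1))
  candidates <- feats[abs(skew) <= config$skew_threshold]

  ord <- withr::with_seed(config$seed, sample(candidates))
  x <- as.matrix(tbl[, ord, drop = FALSE])
  rho <- suppressWarnings(cor(x, method = "spearman"))
  rho[!is.finite(rho)] <- 0 # constant features: treated as uncorrelated

  retained <- character(0)
  for (f in ord) {
    if (length(retained) == 0 ||
        all(abs(rho[f, retained]) <= config$corr_cutoff)) {
      retained <- c(retained, f)
    }
  }
  keep <- union(retained, config$forced_keep)
  feats[feats %in% keep]
}
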