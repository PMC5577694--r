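# Collect maximal runs of equal gray level along the lines of one
# orientation, truncating runs at mask boundaries. Returns run gray levels
# (1-based, 1..G) and run lengths.
collect_runs <- function(q, orientation) {
  lv <- q$levels; m <- q$mask
  h <- nrow(lv); w <- ncol(lv)
  rr <- row(lv); cc <- col(lv)
  line_id <- switch(as.character(orientation),
    "0"   = rr,             # rows
    "90"  = cc,             # columns
    "45"  = rr + cc,        # anti-diagonals
    "135" = cc - rr,        # diagonals
    abort("`orientation` must be one of 0, 45, 90, 135 degrees.")
  )
  # Order pixels within each line consistently along the direction.
  ord <- switch(as.character(orientation),
    "0"   = order(line_id, cc),
    "90"  = order(line_id, rr),
    "45"  = order(line_id, cc),
    "135" = order(line_id, cc)
  )
  v <- as.vector(lv)[ord]
  mk <- as.vector(m)[ord]
  lid <- as.vector(line_id)[ord]
  # Out-of-mask pixels (sentinel level G) and line changes break runs:
  # both are encoded into the run key so rle() splits there.
  key <- ifelse(mk, v, q$G) + (lid - min(lid)) * (q$G + 1L)
  r <- rle(key)
  gray <- r$values %% (q$G + 1L)
  keep <- gray < q$G
  list(gray = gray[keep] + 1L, length = r$lengths[keep])
}

#' Run-length features (60 values)
#'
#' Statistics of maximal runs of equal (quantized) gray level along the
#' four standard directions, truncated at the breast-mask boundary. Long
#' runs indicate coarse texture, short runs fine texture. Per direction,
#' 15 statistics of the run-length distribution `n(g, l)` (gray level `g`
#' in `1..G`, run length `l`): short/long run emphasis (SRE, LRE),
#' gray-level and run-length non-uniformity (GLN, RLN) and their
#' normalized versions (GLNN, RLNN), run percentage (RP), gray-level and
#' run-length variance (GLV, RLV), low/high gray-level run emphasis
#' (LGRE, HGRE) and the four joint emphases (SRLGE, SRHGE, LRLGE, LRHGE);
#' 15 x 4 directions = 60.
#'
#' @param q A [quantize_gray_levels()] result (the pipeline uses `G = 16`).
#' @return Named numeric vector of 60 finite values.
#' @examples
#' img <- mammogram_image(matrix(100L, 4, 4))
#' q <- quantize_gray_levels(img, 16)
#' run_length_features(q)[c("runlength.rp.d000", "runlength.sre.d000")]
#' @export
run_length_features <- function(q) {
  if (!inherits(q, "quantized_image")) {
    abort("`q` must be a `quantized_image`; see `quantize_gray_levels()`.")
  }
  np <- sum(q$mask)
  if (np == 0) abort("Empty mask: run-length features are undefined.")
  block <- vapply(c(0, 45, 90, 135), function(o) {
    runs <- collect_runs(q, o)
    g <- as.numeric(runs$gray)
    l <- as.numeric(runs$length)
    nr <- length(g)
    n_g <- tabulate(runs$gray, nbins = q$G)
    n_l <- tabulate(runs$length)
    c(
      sre = mean(1 / l^2),
      lre = mean(l^2),
      gln = sum(n_g^2) / nr,
      glnn = sum(n_g^2) / nr^2,
      rln = sum(n_l^2) / nr,
      rlnn = sum(n_l^2) / nr^2,
      rp = nr / np,
      glv = mean((g - mean(g))^2),
      rlv = mean((l - mean(l))^2),
      lgre = mean(1 / g^2),
      hgre = mean(g^2),
      srlge = mean(1 / (g^2 * l^2)),
      srhge = mean(g^2 / l^2),
      lrlge = mean(l^2 / g^2),
      lrhge = mean(g^2 * l^2)
    )
  }, numeric(15))
  setNames(as.vector(t(block)), runlength_feature_names())
}
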