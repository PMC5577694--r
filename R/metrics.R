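# ---- Performance measures for masking-risk models ------------------------

check_status_risk <- function(status, risk, both_classes = FALSE) {
  if (length(status) == 0) abort("Empty input.")
  if (length(status) != length(risk)) {
    abort("`status` and `risk` must have the same length.")
  }
  if (!all(status %in% c(0, 1))) abort("`status` must be binary 0/1.")
  if (any(risk < 0 | risk > 1)) abort("`risk` must lie in [0, 1].")
  if (both_classes && length(unique(status)) < 2) {
    abort("Both outcome classes must be present.")
  }
  invisible(NULL)
}

#' Brier-type mean squared error of risk predictions
#'
#' Mean squared difference between the observed binary masking status and
#' the predicted masking probability.
#'
#' @param status Binary 0/1 outcome vector.
#' @param risk Predicted probabilities in `[0, 1]`.
#' @return A single number, `mean((status - risk)^2)`.
#' @examples
#' brier_mse(c(1, 0, 0), c(0.8, 0.1, 0.3))
#' @export
brier_mse <- function(status, risk) {
  check_status_risk(status, risk)
  mean((status - risk)^2)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen event carries a higher predicted
#' risk than a randomly chosen nonevent, with ties counted as 1/2:
#' `AUC = (#(risk_1 > risk_0) + 0.5 * #ties) / (n_1 * n_0)`. A constant
#' predictor (all risks tied) therefore scores exactly 0.5.
#'
#' @inheritParams brier_mse
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
auc <- function(status, risk) {
  check_status_risk(status, risk, both_classes = TRUE)
  n1 <- sum(status == 1)
  n0 <- sum(status == 0)
  r <- rank(risk) # midranks handle ties as 1/2
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' False-positive and true-positive rates swept over every distinct risk
#' threshold, from (0, 0) to (1, 1); tied risks move along a single
#' segment, so the trapezoidal area under the curve equals the
#' Mann-Whitney [auc()].
#'
#' @inheritParams brier_mse
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, rows in
#'   monotone non-decreasing order of both rates.
#' @export
roc_points <- function(status, risk) {
  check_status_risk(status, risk, both_classes = TRUE)
  ord <- order(risk, decreasing = TRUE)
  s <- status[ord]; r <- risk[ord]
  keep <- !duplicated(r, fromLast = TRUE) # last index of each tie group
  tp <- cumsum(s)[keep]
  fp <- cumsum(1 - s)[keep]
  tibble::tibble(
    threshold = c(Inf, r[keep]),
    fpr = c(0, fp / sum(status == 0)),
    tpr = c(0, tp / sum(status == 1))
  )
}

#' Continuous net reclassification improvement
#'
#' Compares a new risk model against an old one: events should move up
#' (higher risk), nonevents down. The continuous NRI is
#' `[P(up | event) - P(down | event)] + [P(down | nonevent) - P(up | nonevent)]`,
#' ranging over `[-2, 2]`. Ties (`risk_new == risk_old`) count toward
#' neither direction. Without ties the identity
#' `NRI = (2 * P(up | event) - 1) + (2 * P(down | nonevent) - 1)` holds.
#'
#' @param status Binary 0/1 outcome vector (both classes required).
#' @param risk_new,risk_old Predicted probabilities from the new and old
#'   models.
#' @return One-row tibble: `nri`, `up_events` (`P(up | event)`) and
#'   `down_nonevents` (`P(down | nonevent)`).
#' @examples
#' continuous_nri(c(1, 1, 0), c(0.9, 0.6, 0.1), c(0.5, 0.5, 0.5))
#' @export
continuous_nri <- function(status, risk_new, risk_old) {
  check_status_risk(status, risk_new, both_classes = TRUE)
  if (length(risk_old) != length(risk_new)) {
    abort("`risk_new` and `risk_old` must have the same length.")
  }
  up <- risk_new > risk_old
  down <- risk_new < risk_old
  ev <- status == 1
  p_up_e <- mean(up[ev]); p_down_e <- mean(down[ev])
  p_up_n <- mean(up[!ev]); p_down_n <- mean(down[!ev])
  tibble::tibble(
    nri = (p_up_e - p_down_e) + (p_down_n - p_up_n),
    up_events = p_up_e,
    down_nonevents = p_down_n
  )
}

#' Discovery rates at masking-risk cut-off points
#'
#' For each cut-off `c` (in percent): the proportion of all subjects whose
#' predicted risk exceeds `c` ("high risk"; the frequency above the
#' cut-off) and the discovery rate, i.e. the proportion of truly masked
#' tumors among which the model assigns "high risk".
#'
#' @inheritParams brier_mse
#' @param cutoffs Cut-off points in percent (e.g. `c(5, 10, 12, 15, 20)`).
#' @return Tibble with columns `cutoff`, `frequency_above` and
#'   `discovery_rate` (proportions in `[0, 1]`).
#' @examples
#' discovery_rates(c(1, 1, 0, 0), c(0.30, 0.05, 0.20, 0.01), cutoffs = 10)
#' @export
discovery_rates <- function(status, risk, cutoffs = c(5, 10, 12, 15, 20)) {
  check_status_risk(status, risk)
  if (sum(status == 1) == 0) {
    abort("No events: discovery rates are undefined.")
  }
  purrr::map_dfr(cutoffs, function(co) {
    high <- risk > co / 100
    tibble::tibble(
      cutoff = co,
      frequency_above = mean(high),
      discovery_rate = mean(high[status == 1])
    )
  })
}
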