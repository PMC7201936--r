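#' Define a weighted genetic score
#'
#' @param ids Variant ids.
#' @param weights Per-variant weights; conventionally the discovery-scan
#'   betas (unit weights are also accepted).
#' @param source Label, e.g. `"early"` or `"adult"`.
#' @return Object of class `score_definition`.
#' @export
score_definition <- function(ids, weights, source = "score") {
  if (length(ids) != length(weights))
    input_error("ids and weights must have equal length")
  if (anyDuplicated(ids)) input_error("variant ids must be unique")
  if (any(!is.finite(weights))) input_error("weights must be finite")
  structure(list(ids = as.character(ids), weights = as.numeric(weights),
                 source = source),
            class = "score_definition")
}

#' Derive a score definition from scanned instruments
#'
#' @param stats Clumped `sumstats` of the instruments.
#' @param source Label.
#' @param unit_weights Use weight 1 per variant instead of the scan betas.
#' @return A [score_definition()].
#' @export
score_from_sumstats <- function(stats, source = "score", unit_weights = FALSE) {
  validate_sumstats(stats)
  score_definition(stats$SNP,
                   if (unit_weights) rep(1, nrow(stats)) else stats$beta,
                   source = source)
}

#' Per-individual genetic score values
#'
#' `value_i = sum_j weight_j * dosage_ij`.
#'
#' @param cohort A cohort whose genotypes cover all score variants.
#' @param score A [score_definition()].
#' @return Numeric vector, one value per individual.
#' @export
build_score <- function(cohort, score) {
  if (!inherits(score, "score_definition"))
    input_error("'score' must be a score_definition")
  missing_v <- setdiff(score$ids, colnames(cohort$genotypes))
  if (length(missing_v))
    input_error("score variant(s) missing from cohort: %s",
                paste(missing_v, collapse = ", "))
  drop(cohort$genotypes[, score$ids, drop = FALSE] %*% score$weights)
}

#' Dichotomise a trait at an empirical centile
#'
#' Labels individuals strictly above the empirical centile (default the
#' 85th, the conventional overweight cut-point) as cases, so about 15% of
#' individuals are labelled 1. Heavy ties spanning the centile shift the
#' achieved case fraction; a warning reports it when it deviates from the
#' target by more than 2 percentage points.
#'
#' @param values Numeric trait values (>= 20 of them).
#' @param centile Centile in `[0, 1)` (default 0.85).
#' @return Integer 0/1 labels.
#' @examples
#' table(dichotomize_at_centile(rnorm(100)))
#' @export
dichotomize_at_centile <- function(values, centile = 0.85) {
  if (length(values) < 20L)
    input_error("need >= 20 values to dichotomise (got %d)", length(values))
  centile <- check_number(centile, "centile", 0, 1, open_upper = TRUE)
  cut <- stats::quantile(values, centile, names = FALSE)
  labels <- as.integer(values > cut)
  achieved <- mean(labels)
  if (abs(achieved - (1 - centile)) > 0.02)
    warning(sprintf(
      "ties at the %.0fth centile: achieved case fraction %.3f (target %.3f)",
      100 * centile, achieved, 1 - centile))
  labels
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) statistic with midrank tie correction;
#' the curve is a threshold sweep over the observed score values. For
#' tie-free scores the rank AUC equals the trapezoidal area under the
#' curve exactly.
#'
#' @param scores Numeric predictor values.
#' @param labels 0/1 (or logical) class labels; both classes must occur.
#' @return Object of class `roc_result`: `auc`, `curve` (data frame of
#'   `fpr`, `tpr`, monotone non-decreasing), `n_cases`, `n_controls`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    input_error("scores and labels must have equal length")
  if (!all(labels %in% 0:1)) input_error("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    input_error("both classes must be present (cases %d, controls %d)", n1, n0)
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # threshold sweep: cumulative counts at each distinct score value
  ord <- order(scores, decreasing = TRUE)
  cases <- cumsum(labels[ord] == 1L)
  ctrls <- cumsum(labels[ord] == 0L)
  last <- cumsum(rle(scores[ord])$lengths)
  curve <- data.frame(fpr = c(0, ctrls[last] / n0),
                      tpr = c(0, cases[last] / n1))
  structure(list(auc = auc, curve = curve, n_cases = n1, n_controls = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, digits = 3, ...) {
  cat(sprintf("ROC: AUC = %.*f (%d cases, %d controls, %d curve points)\n",
              digits, x$auc, x$n_cases, x$n_controls, nrow(x$curve)))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc A [roc_auc()] result.
#' @return The trapezoidal area of `roc$curve`.
#' @export
roc_trapezoid_area <- function(roc) {
  cv <- roc$curve
  sum(diff(cv$fpr) * (utils::head(cv$tpr, -1) + utils::tail(cv$tpr, -1)) / 2)
}
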