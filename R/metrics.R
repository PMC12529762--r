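#' Binary classification metrics for imbalanced data
#'
#' Computes F1 (positive class = active), Recall, AUROC (rank-based
#' Mann-Whitney statistic with average ranks for ties, identical to the
#' pairwise-comparison definition) and the Matthews correlation coefficient.
#' Any MCC with a zero denominator term is defined as 0 (the standard
#' convention; an all-positive predictor on imbalanced data scores MCC 0
#' despite Recall 1). AUROC is undefined for single-class truth and is
#' reported as `NA` with the `auroc_defined` flag set to `FALSE`.
#'
#' @param y integer 0/1 truth vector.
#' @param scores numeric predicted scores/probabilities.
#' @param threshold score cutoff for the hard prediction (default 0.5).
#' @return named list: `f1`, `auroc`, `recall`, `mcc`, `auroc_defined`.
#' @export
classification_metrics <- function(y, scores, threshold = 0.5) {
  stopifnot(length(y) == length(scores), length(y) > 0)
  y <- as.integer(y)
  pred <- as.integer(scores >= threshold)
  tp <- as.numeric(sum(pred == 1L & y == 1L))
  fp <- as.numeric(sum(pred == 1L & y == 0L))
  fn <- as.numeric(sum(pred == 0L & y == 1L))
  tn <- as.numeric(sum(pred == 0L & y == 0L))
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (tp * tn - fp * fn) / sqrt(denom)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    auroc <- NA_real_; defined <- FALSE
  } else {
    r <- rank(scores)
    auroc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    defined <- TRUE
  }
  list(f1 = f1, auroc = auroc, recall = recall, mcc = mcc,
       auroc_defined = defined)
}

#' Regression metrics
#'
#' Mean absolute error and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`. A constant truth vector leaves R^2
#' undefined; it is reported as 0 with `r2_defined = FALSE` and a warning.
#'
#' @param y numeric truth (pX values).
#' @param pred numeric predictions.
#' @return named list: `mae`, `r2`, `r2_defined`.
#' @export
regression_metrics <- function(y, pred) {
  stopifnot(length(y) == length(pred), length(y) > 0)
  mae <- mean(abs(y - pred))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant response: R^2 undefined, reported as 0")
    return(list(mae = mae, r2 = 0, r2_defined = FALSE))
  }
  list(mae = mae, r2 = 1 - sum((y - pred)^2) / ss_tot, r2_defined = TRUE)
}
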