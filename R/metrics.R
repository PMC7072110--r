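# Evaluation statistics: pixel-overlap metrics for segmentation masks and
# error/agreement metrics for predicted ages.

#' Pixel confusion counts between two binary masks
#'
#' Foreground (1) is the positive class.
#'
#' @param truth,pred 0/1 matrices of equal shape.
#' @return named vector `(tp, fp, tn, fn)`; the counts sum to the pixel count.
#' @export
confusion_counts <- function(truth, pred) {
  assert_binary_mask(truth, "truth")
  assert_binary_mask(pred, "pred")
  if (!all(dim(truth) == dim(pred))) contract_error("mask shapes differ")
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  tn <- sum(truth == 0 & pred == 0)
  fn <- sum(truth == 1 & pred == 0)
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Dice, sensitivity and specificity of a predicted mask
#'
#' `dice = 2 tp / (2 tp + fp + fn)`; `sensitivity = tp / (tp + fn)`;
#' `specificity = tn / (tn + fp)`. Each raises a degenerate-input error when
#' its denominator is zero (e.g. Dice of two empty masks).
#'
#' @inheritParams confusion_counts
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(truth, pred) {
  cc <- confusion_counts(truth, pred)
  den <- 2 * cc["tp"] + cc["fp"] + cc["fn"]
  if (den == 0) degenerate_error("Dice undefined: both masks are empty")
  unname(2 * cc["tp"] / den)
}

#' @rdname dice
#' @export
sensitivity <- function(truth, pred) {
  cc <- confusion_counts(truth, pred)
  if (cc["tp"] + cc["fn"] == 0) {
    degenerate_error("sensitivity undefined: truth has no foreground pixel")
  }
  unname(cc["tp"] / (cc["tp"] + cc["fn"]))
}

#' @rdname dice
#' @export
specificity <- function(truth, pred) {
  cc <- confusion_counts(truth, pred)
  if (cc["tn"] + cc["fp"] == 0) {
    degenerate_error("specificity undefined: truth has no background pixel")
  }
  unname(cc["tn"] / (cc["tn"] + cc["fp"]))
}

check_age_pair <- function(truth, pred) {
  if (length(truth) != length(pred)) contract_error("age vectors differ in length")
  if (length(truth) == 0L) contract_error("age vectors are empty")
  invisible(NULL)
}

#' Mean absolute error and root mean square error (months)
#'
#' @param truth,pred numeric age vectors of equal nonzero length.
#' @return scalar error in the input units.
#' @export
mae <- function(truth, pred) {
  check_age_pair(truth, pred)
  mean(abs(truth - pred))
}

#' @rdname mae
#' @export
rmse <- function(truth, pred) {
  check_age_pair(truth, pred)
  sqrt(mean((truth - pred)^2))
}

#' Lin's concordance correlation coefficient
#'
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with population
#' (divide by n) moments. Lies in `[-1, 1]` and equals 1 only for exact
#' agreement; unlike Pearson correlation it penalizes location and scale
#' shifts.
#'
#' @param truth,pred numeric vectors of equal length >= 2, each non-constant.
#' @return scalar in `[-1, 1]`.
#' @export
ccc <- function(truth, pred) {
  check_age_pair(truth, pred)
  if (length(truth) < 2L) contract_error("ccc needs at least 2 observations")
  mx <- mean(truth); my <- mean(pred)
  vx <- mean((truth - mx)^2); vy <- mean((pred - my)^2)
  if (vx == 0 || vy == 0) degenerate_error("ccc undefined for a constant sequence")
  cxy <- mean((truth - mx) * (pred - my))
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Regression evaluation report for one cohort
#'
#' @param truth,pred age vectors in months.
#' @param cohort label (`"all"`, `"male"`, `"female"`, ...).
#' @return one-row data.frame with `cohort`, `n`, `mae`, `rmse`, `ccc`.
#' @export
regression_report <- function(truth, pred, cohort = "all") {
  data.frame(cohort = cohort, n = length(truth),
             mae = mae(truth, pred), rmse = rmse(truth, pred),
             ccc = ccc(truth, pred), stringsAsFactors = FALSE)
}

#' Segmentation evaluation report over mask pairs
#'
#' @param truths,preds lists of 0/1 masks, aligned.
#' @param strategy label for the table row.
#' @return one-row data.frame with mean `sensitivity`, `specificity`, `dice`.
#' @export
segmentation_report <- function(truths, preds, strategy = "AL") {
  stopifnot(length(truths) == length(preds))
  s <- mapply(sensitivity, truths, preds)
  p <- mapply(specificity, truths, preds)
  d <- mapply(dice, truths, preds)
  data.frame(strategy = strategy, n = length(truths),
             sensitivity = mean(s), specificity = mean(p), dice = mean(d),
             stringsAsFactors = FALSE)
}
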