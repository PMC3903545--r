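# Screening performance metrics: F-beta, the all-include baseline,
# confusion counts and the derived screening-burden statistics.

#' F-beta summary measure
#'
#' The weighted harmonic mean of precision and recall,
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`. With `beta = 3` (the
#' screening default) recall is weighted nine times as heavily as
#' precision, matching reviewer behavior during the first screening
#' pass.
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @param beta Recall weighting (default 3).
#' @return The F-beta fraction (0, with a warning, when both inputs are
#'   0).
#' @export
#' @examples
#' f_beta(precision = 0.125, recall = 1)  # 0.5882
f_beta <- function(precision, recall, beta = 3) {
  stopifnot(all(precision >= 0 & precision <= 1),
            all(recall >= 0 & recall <= 1))
  out <- numeric(length(precision))
  zero <- precision == 0 & recall == 0
  if (any(zero)) warn("F-beta undefined when precision and recall are both 0; returning 0")
  b2 <- beta^2
  out[!zero] <- ((1 + b2) * precision[!zero] * recall[!zero] /
                   (b2 * precision[!zero] + recall[!zero]))
  out
}

#' Baseline F3 of an all-include classifier
#'
#' Labeling every citation `include` gives perfect recall and precision
#' equal to the eligible fraction; this is the floor any useful
#' screening classifier must beat.
#'
#' @param eligible_fraction Fraction of citations provisionally
#'   eligible, strictly between 0 and 1.
#' @param beta Recall weighting (default 3).
#' @return Baseline F-beta as a percentage.
#' @export
#' @examples
#' baseline_f3(0.125)  # 58.82
baseline_f3 <- function(eligible_fraction, beta = 3) {
  if (any(eligible_fraction <= 0 | eligible_fraction >= 1)) {
    abort("eligible fraction must be strictly between 0 and 1")
  }
  100 * f_beta(precision = eligible_fraction,
               recall = rep(1, length(eligible_fraction)), beta = beta)
}

#' Evaluate predictions for one independent test
#'
#' Confusion counts (include is the positive class) and the derived
#' percentages: recall, precision, F3, classification error
#' (`100 - accuracy`) and second-pass reduction in screening burden
#' (`RSB = 100 - classification error`).
#'
#' @param predictions,labels Character vectors over
#'   `include`/`exclude`, aligned.
#' @param beta Recall weighting in the F measure (default 3).
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `n`, `recall`,
#'   `precision`, `f3`, `classification_error`, `rsb_second_pass` (all
#'   rates as percentages).
#' @export
evaluate_predictions <- function(predictions, labels, beta = 3) {
  if (length(predictions) != length(labels)) {
    abort("predictions and labels must have the same length")
  }
  pred_pos <- predictions == "include"
  true_pos <- labels == "include"
  tp <- sum(pred_pos & true_pos)
  fp <- sum(pred_pos & !true_pos)
  fn <- sum(!pred_pos & true_pos)
  tn <- sum(!pred_pos & !true_pos)
  n <- length(labels)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f3 <- if (precision == 0 && recall == 0) 0 else
    f_beta(precision, recall, beta = beta)
  err <- 100 * (fp + fn) / n
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    recall = 100 * recall,
    precision = 100 * precision,
    f3 = 100 * f3,
    classification_error = err,
    rsb_second_pass = 100 - err
  )
}

#' One-tailed Z-test of mean F3 against the baseline
#'
#' `Z = (mean - baseline) / (sd / sqrt(n))`, with the upper-tail normal
#' p-value. The variance source (across independent tests or across CV
#' folds) is the caller's choice, passed explicitly.
#'
#' @param mean_f3,sd_f3 Mean and standard deviation of F3 (percent).
#' @param n_tests Number of tests contributing to the mean (at least 2).
#' @param baseline Baseline F3 (percent).
#' @return A one-row tibble with `z` and `p_value`.
#' @export
z_vs_baseline <- function(mean_f3, sd_f3, n_tests, baseline) {
  if (sd_f3 <= 0) abort("sd_f3 must be positive")
  if (n_tests < 2) abort("n_tests must be at least 2")
  z <- (mean_f3 - baseline) / (sd_f3 / sqrt(n_tests))
  tibble::tibble(z = z, p_value = pnorm(z, lower.tail = FALSE))
}
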