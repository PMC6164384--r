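# Evaluation statistics: confusion-matrix summaries (SE, SP, Q, G-mean),
# regression summaries (squared Pearson R2, RMSE, MAE, large-error share)
# and the 3xMAE outlier rule.

#' Confusion counts
#'
#' Either pass the four counts directly, or factors of observed and
#' predicted labels plus the positive class.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @param observed,predicted Factors/vectors of class labels.
#' @param positive The positive-class label (defaults to the first level
#'   of `observed`).
#' @return A `confusion_counts` object (list with tp, tn, fp, fn).
#' @examples
#' confusion_counts(tp = 18, tn = 36, fp = 13, fn = 7)
#' @export
confusion_counts <- function(tp = NULL, tn = NULL, fp = NULL, fn = NULL,
                             observed = NULL, predicted = NULL,
                             positive = NULL) {
  if (is.null(tp)) {
    stopifnot(!is.null(observed), !is.null(predicted),
              length(observed) == length(predicted))
    if (is.null(positive)) {
      positive <- if (is.factor(observed)) levels(observed)[1] else
        sort(unique(as.character(observed)))[1]
    }
    obs_pos <- as.character(observed) == positive
    pred_pos <- as.character(predicted) == positive
    tp <- sum(obs_pos & pred_pos); fn <- sum(obs_pos & !pred_pos)
    fp <- sum(!obs_pos & pred_pos); tn <- sum(!obs_pos & !pred_pos)
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) < 1) stop("confusion matrix is empty", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  TN %d  FP %d  FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

.undef <- function(what) {
  warning(what, " undefined (zero denominator); returning NA", call. = FALSE)
  NA_real_
}

#' Sensitivity (true-positive rate)
#'
#' `SE = TP / (TP + FN)`.  A zero denominator yields `NA` with a warning,
#' never 0.
#'
#' @param cm A [confusion_counts()] object.
#' @return Numeric in `[0, 1]` or `NA`.
#' @export
sensitivity <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  d <- cm$tp + cm$fn
  if (d == 0) return(.undef("sensitivity"))
  cm$tp / d
}

#' Specificity (true-negative rate)
#'
#' `SP = TN / (TN + FP)`.
#'
#' @inheritParams sensitivity
#' @return Numeric in `[0, 1]` or `NA`.
#' @export
specificity <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  d <- cm$tn + cm$fp
  if (d == 0) return(.undef("specificity"))
  cm$tn / d
}

#' Overall predictive accuracy Q
#'
#' `Q = (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @inheritParams sensitivity
#' @return Numeric in `[0, 1]`.
#' @export
accuracy_q <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  (cm$tp + cm$tn) / (cm$tp + cm$tn + cm$fp + cm$fn)
}

#' Geometric mean of sensitivity and specificity
#'
#' `G = sqrt(SE * SP)`; balance-robust summary for imbalanced classes.
#'
#' @inheritParams sensitivity
#' @return Numeric in `[0, 1]` or `NA`.
#' @export
g_mean <- function(cm) {
  se <- sensitivity(cm); sp <- specificity(cm)
  sqrt(se * sp)
}

#' All classification metrics at once
#'
#' @inheritParams sensitivity
#' @param digits Rounding (half-up) for the `rounded` component; default 2
#'   to match tabulated reporting.
#' @return List with `counts`, `raw` (se, sp, q, g_mean) and `rounded`.
#' @export
classification_report <- function(cm, digits = 2) {
  raw <- c(se = sensitivity(cm), sp = specificity(cm),
           q = accuracy_q(cm), g_mean = g_mean(cm))
  list(counts = cm, raw = raw, rounded = round_half_up(raw, digits))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (2.345 -> 2.35 at 2 dp), matching
#' how tabulated values are conventionally printed, unlike base R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon so decimal ties survive binary representation (0.725 is
  # stored fractionally below 72.5/100)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Regression evaluation report
#'
#' `r2` is the **squared Pearson correlation** between observed and
#' predicted (the convention of QSAR tables), not the coefficient of
#' determination; the latter is also returned as `r2_cod`.
#' `pct_abs_err_ge_1` is the percentage of samples with absolute error
#' >= 1 (one log unit on the pIC50 scale).
#'
#' @param y Observed values (length >= 2).
#' @param y_hat Predicted values.
#' @return List with `r2`, `r2_cod`, `rmse`, `mae`, `pct_abs_err_ge_1`, `n`.
#' @examples
#' regression_report(c(0, 1, 2), c(0, 1, 5))
#' @export
regression_report <- function(y, y_hat) {
  stopifnot(is.numeric(y), is.numeric(y_hat), length(y) == length(y_hat))
  n <- length(y)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  err <- y - y_hat
  r2 <- if (stats::sd(y) == 0 || stats::sd(y_hat) == 0) {
    .undef("squared Pearson r")
  } else {
    stats::cor(y, y_hat)^2
  }
  ss_tot <- sum((y - mean(y))^2)
  r2_cod <- if (ss_tot == 0) NA_real_ else 1 - sum(err^2) / ss_tot
  list(r2 = r2,
       r2_cod = r2_cod,
       rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)),
       pct_abs_err_ge_1 = 100 * mean(abs(err) >= 1),
       n = n)
}

#' Flag prediction outliers by the 3 x MAE rule
#'
#' A sample is an outlier when its absolute error is strictly greater
#' than `factor * mae`.
#'
#' @param abs_errors Non-negative absolute errors.
#' @param mae Reference mean absolute error; defaults to
#'   `mean(abs_errors)`.
#' @param factor Multiplier; default 3.
#' @return List with logical `flags`, `n_outliers` and `percentage`.
#' @export
outlier_flags <- function(abs_errors, mae = NULL, factor = 3) {
  stopifnot(is.numeric(abs_errors), all(abs_errors >= 0))
  if (is.null(mae)) mae <- mean(abs_errors)
  flags <- abs_errors > factor * mae
  list(flags = flags, n_outliers = sum(flags),
       percentage = 100 * mean(flags))
}
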