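#' Balanced accuracy
#'
#' (TPR + TNR) / 2, mitigating class imbalance.  When one class is absent
#' from `y_true` the undefined rate is skipped and the defined rate is
#' returned alone, with a warning (balanced left/right designs never hit
#' this).
#'
#' @param y_true,y_pred equal-length vectors coded in {0, 1}.
#' @return a value in [0, 1].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop_shape("y_true and y_pred must have the same length")
  }
  y_true <- as_binary(y_true, "y_true")
  y_pred <- as_binary(y_pred, "y_pred")
  rates <- c(
    if (any(y_true == 1)) mean(y_pred[y_true == 1] == 1),
    if (any(y_true == 0)) mean(y_pred[y_true == 0] == 0)
  )
  if (length(rates) < 2) {
    warning("one class absent from y_true; returning the defined rate only",
            call. = FALSE)
  }
  mean(rates)
}

#' Group specificity index (GSI)
#'
#' \deqn{\mathrm{GSI} = 2\,\mathrm{BAT}\,(\mathrm{BAT} - 0.5 -
#'   |\mathrm{BANT} - 0.5|),}
#' where BAT and BANT are the balanced accuracies on target- and
#' nontarget-group test samples.  GSI is 0 when the two accuracies are
#' identical and 1 in the maximal-specificity case BAT = 1, BANT = 0.5.
#' The raw value is returned even when negative; models with BAT < 0.5
#' (worse than chance on their own group) are flagged via the `"valid"`
#' attribute rather than dropped.
#'
#' @param bat balanced accuracy on the target group, in [0, 1].
#' @param bant balanced accuracy on the nontarget group, in [0, 1].
#' @return a scalar with attribute `valid` (`FALSE` when `bat < 0.5`).
#' @export
gsi <- function(bat, bant) {
  if (any(bat < 0 | bat > 1) || any(bant < 0 | bant > 1)) {
    stop("bat and bant must lie in [0, 1]", call. = FALSE)
  }
  val <- 2 * bat * (bat - 0.5 - abs(bant - 0.5))
  attr(val, "valid") <- bat >= 0.5
  val
}

#' Absolute accuracy gap
#'
#' Absolute difference of two accuracies on the caller's scale (percent or
#' fraction -- the two arguments must share a scale; mixed scales are not
#' detectable).
#'
#' @param acc_target,acc_nontarget accuracies on a consistent scale.
#' @return nonnegative difference on the input scale.
#' @export
accuracy_gap <- function(acc_target, acc_nontarget) {
  abs(acc_target - acc_nontarget)
}

#' Pairwise Pearson correlation between model weight vectors
#'
#' Compares lateralization patterns across fitted models.  The bias is a
#' location term, not a connection weight, so it is excluded by default.
#'
#' @param models a list of numeric weight vectors of equal length, or a
#'   matrix with one model per row.
#' @param drop_first drop the first element of each vector (the bias).
#' @return a symmetric correlation matrix with unit diagonal; entries
#'   involving a zero-variance vector are `NA` (with a warning).
#' @export
weight_correlation_matrix <- function(models, drop_first = TRUE) {
  W <- if (is.matrix(models)) models else do.call(rbind, models)
  if (nrow(W) < 2) stop("need at least 2 models", call. = FALSE)
  if (drop_first) W <- W[, -1, drop = FALSE]
  sds <- apply(W, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance weight vector; correlations set to NA",
            call. = FALSE)
  }
  R <- suppressWarnings(stats::cor(t(W)))
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- 1
  R
}
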