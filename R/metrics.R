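check_pairs <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) abort_validation("empty prediction/ground-truth set")
  nm <- names(pairs)
  if (!all(c("pred", "gt") %in% nm)) {
    stopifnot(ncol(pairs) >= 2L)
    names(pairs)[1:2] <- c("pred", "gt")
  }
  pairs
}

#' Mean absolute counting error
#'
#' \eqn{MAE = \frac{1}{N}\sum_{i=1}^N |C^{pre}_i - C^{gt}_i|} over per-image
#' predicted and true counts.
#'
#' @param pairs Data frame with columns `pred`, `gt` (or first two columns).
#' @return Scalar MAE.
#' @examples
#' count_mae(data.frame(pred = c(3, 10), gt = c(5, 6)))  # 3
#' @export
count_mae <- function(pairs) {
  pairs <- check_pairs(pairs)
  mean(abs(pairs$pred - pairs$gt))
}

#' Root mean squared counting error
#'
#' \eqn{RMSE = \sqrt{\frac{1}{N}\sum_{i=1}^N (C^{pre}_i - C^{gt}_i)^2}};
#' always at least as large as the MAE.
#'
#' @inheritParams count_mae
#' @return Scalar RMSE.
#' @export
count_rmse <- function(pairs) {
  pairs <- check_pairs(pairs)
  sqrt(mean((pairs$pred - pairs$gt)^2))
}

#' Relative counting accuracy
#'
#' `100 * (1 - MAE / mean(gt))`, in percent. The formula is
#' reverse-engineered from the reported headline accuracy and its MAE and
#' test-set mean count, which it reproduces; it is not stated in closed form
#' in the source literature.
#'
#' @inheritParams count_mae
#' @return Percentage; errors when the mean true count is zero.
#' @export
relative_accuracy <- function(pairs) {
  pairs <- check_pairs(pairs)
  m <- mean(pairs$gt)
  if (m <= 0) abort_validation("relative accuracy undefined: mean true count is 0")
  100 * (1 - count_mae(pairs) / m)
}

#' Evaluate predicted against true per-image counts
#'
#' @inheritParams count_mae
#' @return A `count_evaluation`: pairs, `n`, `mae`, `rmse`,
#'   `relative_accuracy` (NA when the mean true count is zero).
#' @export
evaluate_counts <- function(pairs) {
  pairs <- check_pairs(pairs)
  ra <- if (mean(pairs$gt) > 0) relative_accuracy(pairs) else NA_real_
  structure(list(pairs = pairs, n = nrow(pairs), mae = count_mae(pairs),
                 rmse = count_rmse(pairs), relative_accuracy = ra),
            class = "count_evaluation")
}

#' @export
print.count_evaluation <- function(x, ...) {
  cat(sprintf("count_evaluation over %d images: MAE %.3f, RMSE %.3f", x$n,
              x$mae, x$rmse))
  if (!is.na(x$relative_accuracy))
    cat(sprintf(", accuracy %.2f%%", x$relative_accuracy))
  cat("\n")
  invisible(x)
}
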