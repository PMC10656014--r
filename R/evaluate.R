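# Evaluation: accuracy with split-based error bars, precision-recall sweep,
# and posterior calibration.

#' Classification accuracy with split-based standard error
#'
#' Overall accuracy (correct predictions / reads) plus the standard error of
#' the accuracy estimator from `n_splits` contiguous equal-size splits of the
#' read set.
#'
#' @param predicted Predicted peptide ids (`NA` counts as incorrect).
#' @param truth True peptide ids, same length.
#' @param n_splits Number of contiguous splits (default 10).
#' @return List with `accuracy`, `se` (standard error of the mean) and
#'   `split_accuracy`.
#' @export
accuracy_splits <- function(predicted, truth, n_splits = 10L) {
  if (length(predicted) != length(truth))
    stop("predicted and truth lengths differ")
  n <- length(predicted)
  if (n == 0L) stop("empty input")
  if (n_splits > n) stop("more splits than reads")
  correct <- !is.na(predicted) & predicted == truth
  grp <- rep(seq_len(n_splits), each = ceiling(n / n_splits),
             length.out = n)
  split_acc <- tapply(correct, grp, mean)
  se <- if (n_splits > 1L) stats::sd(split_acc) / sqrt(n_splits) else NA_real_
  list(accuracy = mean(correct), se = as.numeric(se),
       split_accuracy = as.numeric(split_acc))
}

#' Precision-recall curve over the posterior confidence
#'
#' Sweeps a confidence threshold over the predicted-peptide posteriors.  At
#' threshold `t`: precision is correct-above-threshold over
#' predicted-above-threshold, recall is correct-above-threshold over all
#' reads (so recall is denominated by the full read set).  One point is
#' emitted per distinct posterior plus a final zero-recall point.
#'
#' @param posterior Posterior of each prediction.
#' @param correct Logical: was the prediction correct.
#' @return data.frame with `threshold`, `precision`, `recall`.
#' @export
precision_recall_curve <- function(posterior, correct) {
  stopifnot(length(posterior) == length(correct))
  ok <- !is.na(posterior)
  posterior <- posterior[ok]
  correct <- as.logical(correct[ok])
  n <- length(posterior)
  ord <- order(posterior, decreasing = TRUE)
  p <- posterior[ord]
  cum_correct <- cumsum(correct[ord])
  cum_n <- seq_len(n)
  last <- !duplicated(p, fromLast = TRUE) # last index of each distinct value
  data.frame(
    threshold = c(p[last], Inf),
    precision = c(cum_correct[last] / cum_n[last], NA_real_),
    recall = c(cum_correct[last] / n, 0)
  )
}

#' Posterior calibration table
#'
#' Bins predictions by posterior into `n_bins` equal-width bins on [0, 1] and
#' reports, per bin, the mean posterior, the empirical accuracy and the
#' count.  Empty bins carry count 0 and `NA` accuracy.
#'
#' @param posterior Posterior of each prediction.
#' @param correct Logical: was the prediction correct.
#' @param n_bins Number of bins (>= 1).
#' @return data.frame with `bin_lo`, `bin_hi`, `mean_posterior`, `accuracy`,
#'   `count`.
#' @export
calibration_table <- function(posterior, correct, n_bins = 10L) {
  stopifnot(n_bins >= 1L, length(posterior) == length(correct))
  ok <- !is.na(posterior)
  posterior <- posterior[ok]
  correct <- as.logical(correct[ok])
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(posterior, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  out$mean_posterior <- vapply(seq_len(n_bins), function(b) {
    v <- posterior[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  out$accuracy <- vapply(seq_len(n_bins), function(b) {
    v <- correct[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  out$count <- tabulate(bin, n_bins)
  out
}
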