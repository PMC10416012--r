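# Slide-level aggregation and the metric suite.
#
# A slide's score is its fraction of positive tiles (tile scores binarized at
# `tile_cutoff`, strictly greater-than), and a slide is called positive when
# that fraction strictly exceeds the predictive threshold gamma. Gamma is
# chosen to maximize accuracy on the validation set it is reported on.

#' Aggregate tile predictions into a slide score
#'
#' @param scores numeric tile scores in \[0, 1\] for one slide
#' @param tile_cutoff a tile is positive when its score strictly exceeds this
#' @param slide_id identifier
#' @return list with `slide_id`, `fraction_positive`, `n_tiles`
#' @export
slide_score <- function(scores, tile_cutoff = 0.5, slide_id = "slide") {
  if (length(scores) == 0L)
    stop_stainpipe("no_tiles", "no tile predictions for slide")
  if (any(scores < 0 | scores > 1))
    stop_stainpipe("invalid_input", "tile scores must lie in [0, 1]")
  list(slide_id = slide_id,
       fraction_positive = mean(scores > tile_cutoff),
       n_tiles = length(scores))
}

#' Accuracy-maximal slide threshold
#'
#' Candidate thresholds are 0, 1, and the midpoints between consecutive
#' distinct sorted slide fractions; a slide is predicted positive when its
#' fraction strictly exceeds the candidate. Returns the smallest candidate
#' attaining the maximum accuracy (deterministic, sensitivity-favouring
#' tie-break).
#'
#' @param fractions numeric slide fractions in \[0, 1\]
#' @param labels binary slide labels
#' @return list with `gamma` and `accuracy`
#' @export
select_threshold <- function(fractions, labels) {
  y <- as.numeric(labels)
  stopifnot(length(fractions) >= 1L, length(y) == length(fractions),
            all(y %in% c(0, 1)))
  u <- sort(unique(fractions))
  cand <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
  acc <- vapply(cand, function(g) mean((fractions > g) == (y == 1)),
                numeric(1))
  best <- which(acc >= max(acc) - 1e-12)[1]  # cand ascending => smallest
  list(gamma = cand[best], accuracy = acc[best])
}

#' Confusion-matrix metrics at a threshold
#'
#' Positive prediction: fraction strictly greater than `gamma`. Metrics with a
#' zero denominator are reported as 0 and flagged in `undefined`.
#' F1 = 2 S P / (S + P).
#'
#' @param fractions slide fractions (or tile scores, for tile-level metrics)
#' @param labels binary truth
#' @param gamma decision threshold in \[0, 1\]
#' @param level `"slide"` or `"tile"` (annotation only)
#' @return a `metrics_report` list: level, gamma, counts tp/fp/tn/fn,
#'   accuracy, sensitivity, specificity, precision, f1, undefined flags
#' @export
compute_metrics <- function(fractions, labels, gamma, level = "slide") {
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), gamma >= 0, gamma <= 1)
  pred <- fractions > gamma
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else {
    undefined <- c(undefined, "f1"); 0
  }
  structure(list(level = level, gamma = gamma,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(y),
                 sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "%s-level metrics @ gamma = %.3f\n  accuracy %.3f  sensitivity %.3f  specificity %.3f  precision %.3f  F1 %.3f\n  counts: TP %d  FP %d  TN %d  FN %d\n",
    x$level, x$gamma, x$accuracy, x$sensitivity, x$specificity, x$precision,
    x$f1, x$tp, x$fp, x$tn, x$fn))
  if (length(x$undefined))
    cat("  (zero-denominator, reported as 0:", paste(x$undefined, collapse = ", "), ")\n")
  invisible(x)
}

#' ROC curve and trapezoidal AUC over slide fractions
#'
#' Sweeps thresholds from above the largest fraction down through every
#' distinct fraction (prediction rule: fraction > threshold), yielding a
#' monotone curve from (0, 0) to (1, 1).
#'
#' @param fractions slide fractions
#' @param labels binary truth, both classes present
#' @return list with `thresholds` (descending), `fpr`, `tpr`, `auc`
#' @export
roc_and_auc <- function(fractions, labels) {
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L)
    stop_stainpipe("undefined_roc", "ROC requires both classes")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  thr <- c(Inf, sort(unique(fractions), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(fractions > t & y == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(fractions > t & y == 0) / n_neg, 0)
  # threshold just below the minimum closes the curve at (1, 1)
  thr <- c(thr, min(fractions) - 1)
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc)
}

#' Percentile bootstrap confidence interval for a slide-level metric
#'
#' Resamples slides with replacement and takes the percentile interval of the
#' metric. This is a documented stand-in for unavailable analytic intervals.
#'
#' @param metric `function(fractions, labels)` returning a scalar
#' @param fractions slide fractions
#' @param labels binary truth
#' @param n_boot resamples (default 1000)
#' @param level confidence level (default 0.95)
#' @param seed integer seed
#' @return list with `lower`, `upper`, `level`, `n_boot`
#' @export
bootstrap_ci <- function(metric, fractions, labels, n_boot = 1000L,
                         level = 0.95, seed = 1L) {
  n <- length(fractions)
  stopifnot(n >= 2L, length(labels) == n)
  y <- as.numeric(labels)
  stats <- with_stream(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric(fractions[idx], y[idx])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- stats::quantile(stats, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  list(lower = q[1], upper = q[2], level = level, n_boot = n_boot)
}
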