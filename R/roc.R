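#' Confusion counts for old/new judgment
#'
#' @param old Logical vector of verdicts (`TRUE` = judged old).
#' @param truth Logical vector of ground truth (`TRUE` = actually old).
#' @return A one-row tibble with `hits`, `false_alarms`, `misses`,
#'   `correct_rejections`, `hit_rate` and `fa_rate` (rates are `NaN` when
#'   the corresponding class is absent).
#' @export
confusion_counts <- function(old, truth) {
  stopifnot(length(old) == length(truth))
  old <- as.logical(old); truth <- as.logical(truth)
  tibble::tibble(
    hits = sum(old & truth),
    false_alarms = sum(old & !truth),
    misses = sum(!old & truth),
    correct_rejections = sum(!old & !truth),
    hit_rate = sum(old & truth) / sum(truth),
    fa_rate = sum(old & !truth) / sum(!truth)
  )
}

#' ROC curve from similarity scores
#'
#' Sweeps a classification threshold over the unique similarity values
#' (ties share a threshold), scoring a probe as "old" when its similarity
#' is at or above the threshold, and traces the resulting
#' (false-positive rate, true-positive rate) curve from (0, 0) to (1, 1).
#' The area under the curve is the trapezoidal rule over those points,
#' which equals the probability that a random old probe outscores a random
#' new one (ties counting half) — the signal-detection summary of how well
#' graded familiarity separates old from new.
#'
#' @param scores Numeric similarity scores.
#' @param labels Ground truth: logical (`TRUE` = old) or `"old"`/`"new"`.
#' @return An object of class `hm_roc`: list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_old`, `n_new`.
#' @examples
#' roc_curve(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))$auc
#' @export
roc_curve <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- as.character(labels) == "old"
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_old <- sum(labels); n_new <- sum(!labels)
  if (n_old == 0L || n_new == 0L)
    stop("ROC needs at least one old and one new label", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_old, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_new, numeric(1))
  pts <- tibble::tibble(threshold = c(Inf, thr, -Inf),
                        fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_old = n_old, n_new = n_new),
            class = "hm_roc")
}

#' @export
print.hm_roc <- function(x, ...) {
  cat("<hm_roc> AUC = ", signif(x$auc, 4), " (", x$n_old, " old, ",
      x$n_new, " new)\n", sep = "")
  invisible(x)
}

#' @describeIn roc_curve Threshold sweep points as a tibble.
#' @param x An `hm_roc` object.
#' @param ... Unused.
#' @method tidy hm_roc
#' @export
tidy.hm_roc <- function(x, ...) x$points

#' @describeIn roc_curve One-row summary with `auc`, `n_old`, `n_new`.
#' @method glance hm_roc
#' @export
glance.hm_roc <- function(x, ...)
  tibble::tibble(auc = x$auc, n_old = x$n_old, n_new = x$n_new)

#' @describeIn roc_curve ROC step curve with the chance diagonal.
#' @param object An `hm_roc` object.
#' @method autoplot hm_roc
#' @export
autoplot.hm_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-alarm rate", y = "hit rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}
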