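#' Binary confusion matrix with AMD as the positive class
#'
#' Rows of the conceptual matrix are true labels, columns predicted labels;
#' `TP` counts AMD scans called AMD, `TN` normal scans called NORMAL.
#'
#' @param truth,estimate character vectors over `{"AMD", "NORMAL"}`, equal
#'   length.
#' @return a `confusion_matrix`: list with integer `TP`, `FN`, `FP`, `TN`.
#' @export
#' @examples
#' confusion_matrix(c("AMD", "AMD", "NORMAL"), c("AMD", "NORMAL", "NORMAL"))
confusion_matrix <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have the same length")
  }
  ok <- c("AMD", "NORMAL")
  bad <- setdiff(unique(c(truth, estimate)), ok)
  if (length(bad) > 0) {
    abort(sprintf("unknown label(s): %s (expected AMD / NORMAL)",
                  paste(bad, collapse = ", ")))
  }
  new_confusion_matrix(
    TP = sum(truth == "AMD" & estimate == "AMD"),
    FN = sum(truth == "AMD" & estimate == "NORMAL"),
    FP = sum(truth == "NORMAL" & estimate == "AMD"),
    TN = sum(truth == "NORMAL" & estimate == "NORMAL"))
}

#' Build a confusion matrix directly from counts
#'
#' @param TP,FN,FP,TN non-negative integer counts (AMD positive).
#' @return a `confusion_matrix`.
#' @export
new_confusion_matrix <- function(TP, FN, FP, TN) {
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("confusion-matrix counts must be non-negative integers")
  }
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(true = c("AMD", "NORMAL"),
                              predicted = c("AMD", "NORMAL")))
  print(m)
  invisible(x)
}

# Ratio in percent; NA (metric absent) on a zero denominator rather than a
# fabricated 0.
pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Per-class classification metrics
#'
#' For the positive (AMD) class: sensitivity = TP/(TP+FN), precision =
#' TP/(TP+FP), F1 = harmonic mean of the two. The NORMAL row is computed
#' with the class roles swapped. Per-class *accuracy* is the class recall
#' (the convention under which published per-class tables for this detector
#' are reproduced); the overall accuracy (TP+TN)/total is available from
#' [global_accuracy()]. Values are unrounded percentages; round at the
#' reporting layer with [round_half_up()].
#'
#' @param cm a `confusion_matrix`.
#' @return tibble with columns `class`, `support`, `accuracy`,
#'   `sensitivity`, `precision`, `f1` (percent). Metrics with zero
#'   denominators are `NA`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  one <- function(class, tp, fn, fp) {
    sens <- pct(tp, tp + fn)
    prec <- pct(tp, tp + fp)
    f1 <- if (is.na(sens) || is.na(prec) || (sens + prec) == 0) NA_real_
          else 2 * prec * sens / (prec + sens)
    tibble(class = class, support = tp + fn, accuracy = sens,
           sensitivity = sens, precision = prec, f1 = f1)
  }
  bind_rows(one("AMD", cm$TP, cm$FN, cm$FP),
            one("NORMAL", cm$TN, cm$FP, cm$FN))
}

#' Support-weighted average metrics
#'
#' Each per-class metric averaged with weights equal to the class supports.
#'
#' @param cm a `confusion_matrix`.
#' @return one-row tibble with `accuracy`, `sensitivity`, `precision`, `f1`
#'   (unrounded percent).
#' @export
weighted_metrics <- function(cm) {
  per <- class_metrics(cm)
  if (any(per$support == 0)) {
    abort("weighted metrics require both class supports > 0")
  }
  w <- per$support / sum(per$support)
  summarise(per,
            accuracy = sum(w * .data$accuracy),
            sensitivity = sum(w * .data$sensitivity),
            precision = sum(w * .data$precision),
            f1 = sum(w * .data$f1))
}

#' Overall accuracy (TP + TN) / total
#'
#' @param cm a `confusion_matrix`.
#' @return unrounded percent.
#' @export
global_accuracy <- function(cm) {
  pct(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN)
}

#' ROC curve by threshold sweep
#'
#' Higher scores mean more AMD-like (the LOF convention). Tied scores are
#' grouped at a single threshold.
#'
#' @param scores numeric scores, one per sample.
#' @param truth labels over `{"AMD", "NORMAL"}`.
#' @return tibble with `threshold`, `fpr`, `tpr`, ordered from (0, 0) to
#'   (1, 1).
#' @export
roc_curve <- function(scores, truth) {
  if (length(scores) != length(truth)) abort("`scores` and `truth` lengths differ")
  pos <- truth == "AMD"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) abort("ROC requires both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))          # tie groups
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- which(c(diff(grp) != 0, TRUE))        # last index of each group
  tibble(threshold = c(Inf, s[last]),
         fpr = c(0, fp[last] / n_neg),
         tpr = c(0, tp[last] / n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of [roc_curve()]; with ties grouped this equals
#' the normalized Mann-Whitney U statistic with half credit for tied pairs.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  rc <- roc_curve(scores, truth)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

#' Full evaluation report
#'
#' Bundles the confusion matrix, per-class and support-weighted metrics,
#' overall accuracy and (when continuous scores are supplied and both
#' classes are present) the ROC curve and AUC.
#'
#' @param truth,estimate labels over `{"AMD", "NORMAL"}`.
#' @param scores optional continuous scores (higher = more AMD-like) for
#'   ROC/AUC.
#' @return a `metrics_report` list: `confusion`, `per_class`, `weighted`,
#'   `global_accuracy`, `auc` (`NA` when undefined), `roc` (tibble or
#'   `NULL`).
#' @export
metrics_report <- function(truth, estimate, scores = NULL) {
  cm <- confusion_matrix(truth, estimate)
  both <- length(unique(truth)) == 2
  auc <- NA_real_; roc <- NULL
  if (!is.null(scores) && both) {
    roc <- roc_curve(scores, truth)
    auc <- roc_auc(scores, truth)
  }
  structure(list(confusion = cm, per_class = class_metrics(cm),
                 weighted = if (both) weighted_metrics(cm) else NULL,
                 global_accuracy = global_accuracy(cm),
                 auc = auc, roc = roc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (true x predicted):\n")
  print(x$confusion)
  cat("\nPer-class metrics (%):\n")
  print(as.data.frame(mutate(x$per_class,
    across(c("accuracy", "sensitivity", "precision", "f1"),
           function(v) round_half_up(v, 2)))), row.names = FALSE)
  if (!is.null(x$weighted)) {
    cat(sprintf("\nWeighted average: accuracy %.2f  sensitivity %.2f  precision %.2f  F1 %.2f\n",
                round_half_up(x$weighted$accuracy, 2),
                round_half_up(x$weighted$sensitivity, 2),
                round_half_up(x$weighted$precision, 2),
                round_half_up(x$weighted$f1, 2)))
  }
  if (!is.na(x$auc)) cat(sprintf("AUC: %.4f\n", round_half_up(x$auc, 4)))
  invisible(x)
}

#' Tidy a metrics report
#'
#' One row per class plus a `Weighted Average` row, percentages rounded
#' half-up to 2 decimals (matching how such tables are conventionally
#' printed); AUC to 4 decimals on the weighted row.
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  per <- mutate(x$per_class,
                across(c("accuracy", "sensitivity", "precision", "f1"),
                       function(v) round_half_up(v, 2)),
                auc = NA_real_)
  rows <- per
  if (!is.null(x$weighted)) {
    w <- mutate(x$weighted,
                across(everything(), function(v) round_half_up(v, 2)),
                class = "Weighted Average",
                support = sum(per$support),
                auc = if (is.na(x$auc)) NA_real_ else round_half_up(x$auc, 4))
    rows <- bind_rows(per, w)
  }
  select(rows, "class", "support", "accuracy", "sensitivity",
         "precision", "f1", "auc")
}

#' Glance at a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return one-row tibble: `n`, `accuracy` (overall, %), `weighted_accuracy`
#'   (%), `auc`.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  cm <- x$confusion
  tibble(n = cm$TP + cm$FN + cm$FP + cm$TN,
         accuracy = x$global_accuracy,
         weighted_accuracy = if (is.null(x$weighted)) NA_real_ else x$weighted$accuracy,
         auc = x$auc)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
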