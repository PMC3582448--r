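#' Confusion counts for the binary lincRNA/PCT task
#'
#' True positives are lincRNAs predicted non-coding, false positives PCTs
#' predicted non-coding, true negatives PCTs predicted coding, false
#' negatives lincRNAs predicted coding.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Sensitivity (true positive rate)
#'
#' `TP / (TP + FN)`: the fraction of lincRNAs predicted non-coding.
#'
#' @param c a [confusion_counts()].
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0) {
    stop("sensitivity undefined: no positive instances (TP + FN = 0)",
         call. = FALSE)
  }
  c$tp / (c$tp + c$fn)
}

#' Specificity (true negative rate)
#'
#' `TN / (TN + FP)`: the fraction of PCTs predicted coding.
#'
#' @param c a [confusion_counts()].
#' @return Specificity in `[0, 1]`.
#' @export
specificity <- function(c) {
  if (c$tn + c$fp == 0) {
    stop("specificity undefined: no negative instances (TN + FP = 0)",
         call. = FALSE)
  }
  c$tn / (c$tn + c$fp)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any marginal
#' is zero the coefficient is defined as 0 with a warning (the standard
#' convention).
#'
#' @param c a [confusion_counts()].
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  tn <- as.numeric(c$tn); fn <- as.numeric(c$fn)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(marg == 0)) {
    warning("MCC has a zero marginal; returning 0 by convention",
            call. = FALSE)
    return(0)
  }
  (tp * tn - fp * fn) / sqrt(prod(marg))
}

#' ROC curve
#'
#' Sweeps thresholds over the distinct score values in descending order,
#' grouping tied scores into one step, and anchors the curve at (0,0) and
#' (1,1). Positives are the `noncoding` class; scores are "higher = more
#' non-coding".
#'
#' @param scores numeric scores.
#' @param labels character labels in `{"noncoding", "coding"}` (or a logical
#'   vector, `TRUE` = positive).
#' @return Data frame of class `roc_curve` with columns `fpr` and `tpr`,
#'   both non-decreasing from 0 to 1.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  stopifnot(length(scores) == length(pos))
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(p)[last_of_tie] / n_pos
  fpr <- cumsum(!p)[last_of_tie] / n_neg
  structure(data.frame(fpr = c(0, fpr), tpr = c(0, tpr)),
            class = c("roc_curve", "data.frame"))
}

#' Area under a ROC curve
#'
#' Trapezoidal area under the curve. Agrees with the rank-statistic
#' computation of [auc_from_scores()] for curves built by [roc_curve()].
#'
#' @param curve a [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  dx <- diff(curve$fpr)
  my <- (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2
  sum(dx * my)
}

#' AUC by the rank (Mann-Whitney) statistic
#'
#' @param scores numeric scores (higher = more non-coding).
#' @param labels labels as in [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(scores, labels) {
  pos <- as_positive(labels)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate predictions against truth labels
#'
#' Aligns predictions and truth by transcript id and reports the confusion
#' counts, sensitivity, specificity, MCC and AUC in one structured report.
#'
#' @param preds prediction data frame (`transcript_id`, `label`,
#'   `noncoding_score`), e.g. from [predict.linc_model()] or
#'   [read_predictions()].
#' @param truth data frame with columns `transcript_id` and `label` giving
#'   the true class of every predicted transcript.
#' @return An object of class `eval_report`: a list with `counts`
#'   ([confusion_counts()]), `sensitivity`, `specificity`, `mcc`, `auc` and
#'   `n`.
#' @export
evaluate_predictions <- function(preds, truth) {
  missing <- setdiff(preds$transcript_id, truth$transcript_id)
  if (length(missing)) {
    stop("no truth label for: ", paste(utils::head(missing, 10L),
                                       collapse = ", "),
         if (length(missing) > 10L) ", ...", call. = FALSE)
  }
  true_label <- truth$label[match(preds$transcript_id, truth$transcript_id)]
  pos <- as_positive(true_label)
  pred_pos <- as_positive(preds$label)
  counts <- confusion_counts(tp = sum(pos & pred_pos),
                             fp = sum(!pos & pred_pos),
                             tn = sum(!pos & !pred_pos),
                             fn = sum(pos & !pred_pos))
  structure(list(counts = counts,
                 sensitivity = sensitivity(counts),
                 specificity = specificity(counts),
                 mcc = suppressWarnings(mcc(counts)),
                 auc = auc_from_scores(preds$noncoding_score, true_label),
                 n = nrow(preds)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  c <- x$counts
  cat(sprintf("Evaluation over %d transcripts\n", x$n))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", c$tp, c$fp, c$tn, c$fn))
  cat(sprintf("  sensitivity  %s%%\n", format_percent(x$sensitivity)))
  cat(sprintf("  specificity  %s%%\n", format_percent(x$specificity)))
  cat(sprintf("  MCC          %.3f\n", x$mcc))
  cat(sprintf("  AUC          %.3f\n", x$auc))
  invisible(x)
}

#' Format a proportion as a percentage with one decimal
#'
#' Rounds half-up (so 0.96056 prints as "96.1"), matching how accuracies are
#' conventionally tabulated.
#'
#' @param x proportion in `[0, 1]`.
#' @return Character, e.g. `"96.1"`.
#' @export
format_percent <- function(x) {
  sprintf("%.1f", floor(x * 1000 + 0.5) / 10)
}

#' Write an evaluation report as TSV
#'
#' @param report an [evaluate_predictions()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  lines <- c("metric\tvalue",
             sprintf("n\t%d", report$n),
             sprintf("tp\t%d", report$counts$tp),
             sprintf("fp\t%d", report$counts$fp),
             sprintf("tn\t%d", report$counts$tn),
             sprintf("fn\t%d", report$counts$fn),
             sprintf("sensitivity_pct\t%s", format_percent(report$sensitivity)),
             sprintf("specificity_pct\t%s", format_percent(report$specificity)),
             sprintf("mcc\t%.3f", report$mcc),
             sprintf("auc\t%.3f", report$auc))
  writeLines(lines, path)
  invisible(path)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (!all(labels %in% c("noncoding", "coding"))) {
    stop("labels must be 'noncoding' or 'coding'", call. = FALSE)
  }
  labels == "noncoding"
}
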