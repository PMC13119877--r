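# Evaluation metrics: accuracy, macro precision/recall/F1, mean average
# precision (all-point precision-recall integration), segmental F1 at 25%
# overlap, and the temporal stability score.

#' Average precision of a ranked class
#'
#' Exact integral of the stepwise precision-recall curve: samples are ranked
#' by decreasing score and precision is accumulated at every positive
#' (`AP = sum_k P(k) * dR(k)`). An 11-point interpolated variant is
#' available.
#'
#' @param scores Numeric scores (higher = more confident positive).
#' @param positives Logical (or 0/1) ground-truth positives.
#' @param eleven_point Use 11-point interpolation instead of the exact
#'   integral.
#' @return AP in `[0, 1]` (`NA` when there are no positives).
#' @export
average_precision <- function(scores, positives, eleven_point = FALSE) {
  positives <- as.logical(positives)
  n_pos <- sum(positives)
  if (n_pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- positives[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / n_pos
  if (eleven_point) {
    return(mean(vapply(seq(0, 1, by = 0.1), function(r) {
      ok <- rec >= r
      if (!any(ok)) 0 else max(prec[ok])
    }, numeric(1))))
  }
  sum(prec[y]) / n_pos
}

# Run-length segments of a label sequence: data.frame(label, start, end).
label_segments <- function(labels) {
  r <- rle(as.integer(labels))
  end <- cumsum(r$lengths)
  data.frame(label = r$values, start = end - r$lengths + 1L, end = end)
}

#' Segmental F1 at an overlap threshold
#'
#' Segments are maximal runs of a frame-level label sequence. Each predicted
#' segment is greedily matched (in temporal order) to the not-yet-matched
#' ground-truth segment of the same label with the highest interval
#' intersection-over-union; a match with IoU at or above `overlap` counts as
#' a true positive, otherwise the predicted segment is a false positive, and
#' unmatched ground-truth segments are false negatives.
#'
#' @param pred,truth Frame-level integer label vectors of equal length.
#' @param overlap IoU threshold (0.25 for F1@25).
#' @return `list(f1=, tp=, fp=, fn=)`.
#' @export
segmental_f1 <- function(pred, truth, overlap = 0.25) {
  stopif(length(pred) != length(truth), "pred and truth must have equal length")
  ps <- label_segments(pred)
  ts <- label_segments(truth)
  matched <- rep(FALSE, nrow(ts))
  tp <- 0L
  for (i in seq_len(nrow(ps))) {
    cand <- which(ts$label == ps$label[i] & !matched)
    if (length(cand) == 0) next
    inter <- pmax(0, pmin(ps$end[i], ts$end[cand]) - pmax(ps$start[i], ts$start[cand]) + 1)
    union <- pmax(ps$end[i], ts$end[cand]) - pmin(ps$start[i], ts$start[cand]) + 1
    iou <- inter / union
    j <- cand[which.max(iou)]
    if (max(iou) >= overlap) {
      tp <- tp + 1L
      matched[j] <- TRUE
    }
  }
  fp <- nrow(ps) - tp
  fn <- sum(!matched)
  f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  list(f1 = f1, tp = tp, fp = fp, fn = fn)
}

#' Temporal stability of frame-level predictions
#'
#' `1 - (1/(T-1)) * sum_t || y_t - y_{t-1} ||` with the Euclidean norm on
#' successive prediction vectors, averaged over windows. Constant
#' predictions give 1; the score is bounded below by `1 - sqrt(2)` for
#' probability vectors.
#'
#' @param phase_probs List of `[T, P]` probability matrices (one per
#'   window), or a single matrix.
#' @return Mean stability.
#' @export
stability_score <- function(phase_probs) {
  if (is.matrix(phase_probs)) phase_probs <- list(phase_probs)
  vals <- vapply(phase_probs, function(Y) {
    T <- nrow(Y)
    if (T < 2) return(1)
    1 - mean(sqrt(rowSums(diff(Y)^2)))
  }, numeric(1))
  mean(vals)
}

#' Full classification + segmentation metrics report
#'
#' One-vs-rest counts per class give macro-averaged precision, recall and
#' F1; accuracy is the fraction of correct window-level predictions; mAP
#' averages [average_precision()] over classes; segmental F1@25 and the
#' stability score summarize the frame-level phase output.
#'
#' @param predictions `[N, C]` class score/probability matrix (or a length-N
#'   vector of hard labels, which supports all metrics except mAP).
#' @param labels Length-N integer class labels in `1..C`.
#' @param phase_predictions Optional list of per-window `[T, P]` phase
#'   probability matrices.
#' @param phase_labels Optional list of per-window frame-level phase labels.
#' @param n_classes Number of classes (inferred when `predictions` is a
#'   matrix).
#' @param eleven_point Use 11-point AP interpolation.
#' @return A `metrics_report` list: `accuracy`, `precision`, `recall`, `f1`,
#'   `map`, `f1_at_25`, `stability`, `per_class_ap`, `confusion`.
#' @export
compute_metrics <- function(predictions, labels, phase_predictions = NULL,
                            phase_labels = NULL, n_classes = NULL,
                            eleven_point = FALSE) {
  if (is.matrix(predictions)) {
    C <- ncol(predictions)
    pred <- max.col(predictions, ties.method = "first")
    scores <- predictions
  } else {
    pred <- as.integer(predictions)
    C <- n_classes %||% max(c(pred, labels))
    scores <- NULL
  }
  labels <- as.integer(labels)
  stopif(length(pred) != length(labels), "predictions and labels length mismatch")
  N <- length(labels)
  conf <- matrix(0L, C, C, dimnames = list(pred = NULL, true = NULL))
  for (i in seq_len(N)) conf[pred[i], labels[i]] <- conf[pred[i], labels[i]] + 1L
  acc <- sum(diag(conf)) / N
  prec <- rec <- f1 <- numeric(C)
  for (c in seq_len(C)) {
    tp <- conf[c, c]
    fp <- sum(conf[c, ]) - tp
    fn <- sum(conf[, c]) - tp
    prec[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[c] <- if (prec[c] + rec[c] == 0) 0 else
      2 * prec[c] * rec[c] / (prec[c] + rec[c])
  }
  ap <- rep(NA_real_, C)
  if (!is.null(scores)) {
    for (c in seq_len(C)) {
      ap[c] <- average_precision(scores[, c], labels == c, eleven_point)
    }
  }
  f1_25 <- NA_real_
  stab <- NA_real_
  if (!is.null(phase_predictions) && !is.null(phase_labels)) {
    stopif(length(phase_predictions) != length(phase_labels),
           "phase prediction/label length mismatch")
    segs <- mapply(function(Y, lab) {
      pl <- if (is.matrix(Y)) max.col(Y, ties.method = "first") else as.integer(Y)
      r <- segmental_f1(pl, lab, overlap = 0.25)
      c(r$tp, r$fp, r$fn)
    }, phase_predictions, phase_labels)
    tp <- sum(segs[1, ]); fp <- sum(segs[2, ]); fn <- sum(segs[3, ])
    f1_25 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    if (is.matrix(phase_predictions[[1]])) {
      stab <- stability_score(phase_predictions)
    }
  }
  out <- list(accuracy = acc, precision = mean(prec), recall = mean(rec),
              f1 = mean(f1), map = if (all(is.na(ap))) NA_real_ else
                mean(ap, na.rm = TRUE),
              f1_at_25 = f1_25, stability = stab,
              per_class_ap = ap, confusion = conf, n = N)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n=%d  acc %.4f | P %.4f R %.4f F1 %.4f",
                     " | mAP %s | F1@25 %s | stability %s\n"),
              x$n, x$accuracy, x$precision, x$recall, x$f1,
              ifelse(is.na(x$map), "-", sprintf("%.4f", x$map)),
              ifelse(is.na(x$f1_at_25), "-", sprintf("%.4f", x$f1_at_25)),
              ifelse(is.na(x$stability), "-", sprintf("%.4f", x$stability))))
  invisible(x)
}
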