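#' DNK-masked KL-divergence loss for one sample
#'
#' The per-character loss is the KL divergence from the one-hot ground
#' truth to the predicted label distribution, which for one-hot truth
#' reduces to `-log p(true label)`. A character whose ground truth is DNK
#' contributes zero. The returned value is the mean over characters, the
#' quantity back-propagated during training.
#'
#' @param pred numeric matrix (characters x 3) of predicted probabilities;
#'   rows must sum to 1. Columns are (YES, NO, DNK).
#' @param truth character or integer vector of ground-truth labels, one per
#'   character ("YES"/"NO"/"DNK" or 1/2/3).
#' @param eps probability floor before taking logs.
#' @return scalar mean loss.
#' @export
kld_loss <- function(pred, truth, eps = 1e-8) {
  pred <- as.matrix(pred)
  if (ncol(pred) != 3) stop_cfg("pred must have 3 columns (YES, NO, DNK)")
  if (is.character(truth)) truth <- match(truth, label_levels)
  if (length(truth) != nrow(pred) || anyNA(truth)) {
    stop_cfg("truth must give one YES/NO/DNK label per character")
  }
  if (any(abs(rowSums(pred) - 1) > 1e-6)) {
    stop_cfg("pred rows must sum to 1")
  }
  per_char <- ifelse(truth == LBL_DNK, 0,
                     -log(pmax(pred[cbind(seq_len(nrow(pred)), truth)],
                               eps)))
  mean(per_char)
}

#' Per-character classification metrics from binarized predictions
#'
#' Computes TP/TN/FP/FN, accuracy, recall, precision, F1 and the normalized
#' confusion matrix per character, plus macro averages. (frame, character)
#' pairs whose ground truth is DNK are excluded. F1 is defined as 0 when
#' there are no true positives.
#'
#' @param pred logical (or 0/1) matrix, samples x characters: predicted YES.
#' @param truth integer label matrix, samples x characters (1 = YES,
#'   2 = NO, 3 = DNK).
#' @return object of class `metrics_report`: `per_character` data frame,
#'   `confusion` list, and `macro` named vector.
#' @export
evaluate_metrics <- function(pred, truth) {
  pred <- as.matrix(pred)
  truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stop_cfg("dimension mismatch")
  if (nrow(pred) == 0) stop_cfg("empty input")
  rows <- lapply(seq_len(ncol(pred)), function(c) {
    live <- truth[, c] != LBL_DNK
    p <- as.logical(pred[live, c])
    t <- truth[live, c] == LBL_YES
    tp <- sum(p & t); tn <- sum(!p & !t); fp <- sum(p & !t); fn <- sum(!p & t)
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (tp == 0) 0 else 2 / (1 / recall + 1 / precision)
    data.frame(character = c, TP = tp, TN = tn, FP = fp, FN = fn,
               accuracy = (tp + tn) / (tp + tn + fp + fn),
               recall = recall, precision = precision, f1 = f1)
  })
  per_char <- do.call(rbind, rows)
  confusion <- lapply(seq_len(ncol(pred)), function(c) {
    r <- per_char[c, ]
    n_yes <- r$TP + r$FN; n_no <- r$TN + r$FP
    matrix(c(if (n_yes) c(r$TP, r$FN) / n_yes else c(NA, NA),
             if (n_no) c(r$FP, r$TN) / n_no else c(NA, NA)),
           2, byrow = TRUE,
           dimnames = list(truth = c("YES", "NO"), pred = c("YES", "NO")))
  })
  macro <- c(accuracy = mean(per_char$accuracy),
             recall = mean(per_char$recall, na.rm = TRUE),
             precision = mean(per_char$precision, na.rm = TRUE),
             f1 = mean(per_char$f1))
  structure(list(per_character = per_char, confusion = confusion,
                 macro = macro), class = "metrics_report")
}

#' @export
#' @method print metrics_report
print.metrics_report <- function(x, ...) {
  cat("metrics_report (macro): accuracy", sprintf("%.3f", x$macro["accuracy"]),
      " F1", sprintf("%.3f", x$macro["f1"]), "\n")
  print(x$per_character, row.names = FALSE)
  invisible(x)
}
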