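#' Build Yes/No/DNK frame labels from a timeline
#'
#' A (frame, character) pair is labelled YES when the character occupies the
#' frame. Inside an ambiguity interval (e.g. a dialogue whose partners
#' alternate on screen), a character listed for the interval but currently
#' absent receives DNK -- the frame is visually ambiguous for that character
#' rather than evidence of absence. All other pairs are NO.
#'
#' @param timeline a `character_timeline`.
#' @param ambiguity optional data frame with `start_s`, `end_s` and a
#'   `chars` list-column of character indices; defaults to the timeline's
#'   own dialogue intervals.
#' @return an object of class `frame_label_table`: `frames` and a
#'   `labels` integer matrix (frames x characters; 1 = YES, 2 = NO,
#'   3 = DNK).
#' @export
build_frame_labels <- function(timeline, ambiguity = timeline$dialogue) {
  stopifnot(inherits(timeline, "character_timeline"))
  occ <- timeline$occupancy
  labels <- matrix(LBL_NO, nrow(occ), ncol(occ))
  labels[occ] <- LBL_YES
  if (!is.null(ambiguity) && nrow(ambiguity)) {
    ft <- timeline$frames$time_s
    seen <- matrix(FALSE, nrow(occ), ncol(occ))
    for (k in seq_len(nrow(ambiguity))) {
      rows <- which(ft >= ambiguity$start_s[k] & ft < ambiguity$end_s[k])
      chars <- ambiguity$chars[[k]]
      if (any(seen[rows, chars])) {
        stop_cfg("overlapping ambiguity intervals with shared characters")
      }
      seen[rows, chars] <- TRUE
      for (c in chars) {
        absent <- rows[!occ[rows, c]]
        labels[absent, c] <- LBL_DNK
      }
    }
  }
  structure(list(frames = timeline$frames, labels = labels,
                 n_characters = ncol(occ)),
            class = "frame_label_table")
}

#' @export
#' @method print frame_label_table
print.frame_label_table <- function(x, ...) {
  frac <- table(factor(x$labels, 1:3, label_levels)) / length(x$labels)
  cat("frame_label_table:", nrow(x$labels), "frames x",
      ncol(x$labels), "characters; ",
      paste(sprintf("%s %.3f", names(frac), frac), collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate frame-level detections to cut-level presence
#'
#' Mirrors the cut-level denoising filter used to compare frame detections
#' against reference annotations: on the full 30 fps grid, a character is
#' present in a cut longer than 1.3 s when detected in more than 40% of its
#' frames, and in a shorter cut when detected in at least 12 frames.
#'
#' @param detections logical matrix (frames x characters) of per-frame
#'   detections on the `fps` grid.
#' @param frame_times_s frame times matching `detections` rows.
#' @param cuts data frame with `start_s`, `end_s` (non-overlapping).
#' @param long_cut_s cut-length threshold in seconds.
#' @param min_frames detection count rule for short cuts.
#' @param min_fraction detection fraction rule for long cuts.
#' @return an object of class `cut_label_table`: `cuts` plus a logical
#'   `present` matrix (cuts x characters).
#' @export
aggregate_frames_to_cuts <- function(detections, frame_times_s, cuts,
                                     long_cut_s = 1.3, min_frames = 12,
                                     min_fraction = 0.4) {
  detections <- as.matrix(detections)
  stopifnot(nrow(detections) == length(frame_times_s))
  n_cut <- nrow(cuts)
  present <- matrix(FALSE, n_cut, ncol(detections))
  idx <- findInterval(frame_times_s, cuts$start_s, rightmost.closed = FALSE)
  for (k in seq_len(n_cut)) {
    rows <- which(idx == k & frame_times_s < cuts$end_s[k])
    if (!length(rows)) next
    det <- colSums(detections[rows, , drop = FALSE])
    len <- cuts$end_s[k] - cuts$start_s[k]
    present[k, ] <- if (len > long_cut_s) {
      det > min_fraction * length(rows)
    } else {
      det >= min_frames
    }
  }
  structure(list(cuts = cuts, present = present), class = "cut_label_table")
}

#' Normalized confusion matrices against reference cut labels
#'
#' TP and FN are normalized by the number of reference-YES cuts, TN and FP
#' by the number of reference-NO cuts, per character and pooled. Rows of the
#' returned 2x2 matrices are (truth YES, truth NO) and columns (predicted
#' YES, predicted NO); an undefined row (no truth cuts of that class) is NA.
#'
#' @param pred,truth `cut_label_table`s over the same cut set.
#' @return list with `per_character` (list of 2x2 matrices) and `pooled`.
#' @export
confusion_vs_reference <- function(pred, truth) {
  stopifnot(inherits(pred, "cut_label_table"),
            inherits(truth, "cut_label_table"),
            nrow(pred$present) == nrow(truth$present))
  one <- function(p, t) {
    n_yes <- sum(t); n_no <- sum(!t)
    row_yes <- if (n_yes) c(sum(p & t), sum(!p & t)) / n_yes else c(NA, NA)
    row_no <- if (n_no) c(sum(p & !t), sum(!p & !t)) / n_no else c(NA, NA)
    matrix(c(row_yes, row_no), 2, byrow = TRUE,
           dimnames = list(truth = c("YES", "NO"), pred = c("YES", "NO")))
  }
  per_char <- lapply(seq_len(ncol(pred$present)), function(c) {
    one(pred$present[, c], truth$present[, c])
  })
  pooled <- one(as.vector(pred$present), as.vector(truth$present))
  list(per_character = per_char, pooled = pooled)
}
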