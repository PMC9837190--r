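#' Build windowed training samples around frame times
#'
#' One sample per eligible frame: the 60 rate samples covering one second
#' before and one second after the frame (half-open `[t - 1, t + 1)` at
#' 30 Hz; the frame time is the left edge of sample 31 of 60, so the window
#' is symmetric about the frame). Frames whose window would cross the
#' recording edge or touch an excluded artifact sample are dropped and
#' counted.
#'
#' Windows are stored by reference into the rate matrix (centre column per
#' sample) and materialised per batch, which keeps an 18,900-sample set
#' cheap to hold in memory.
#'
#' @param rates a `rate_matrix` (30 Hz for the canonical 60-step window).
#' @param labels a `frame_label_table`.
#' @param window_s window length in seconds.
#' @return an object of class `window_sample_set`: sample frame indices and
#'   times, label matrix, window geometry and the dropped-frame count.
#' @export
make_window_samples <- function(rates, labels, window_s = 2) {
  stopifnot(inherits(rates, "rate_matrix"),
            inherits(labels, "frame_label_table"))
  hz <- rates$sample_hz
  steps <- round(window_s * hz)
  half <- steps %/% 2
  centre <- round((labels$frames$time_s - rates$origin_s) * hz) + 1L
  lo <- centre - half
  hi <- centre + half - 1L
  n_samp <- ncol(rates$rates)
  ok <- lo >= 1L & hi <= n_samp
  if (any(rates$excluded)) {
    bad_idx <- which(rates$excluded)
    ok[ok] <- vapply(which(ok), function(i) {
      !any(bad_idx >= lo[i] & bad_idx <= hi[i])
    }, TRUE)
  }
  if (!any(ok)) stop_cfg("no eligible frames for windowing")
  structure(list(
    rates = rates, centre = centre[ok], lo = lo[ok],
    frame_idx = labels$frames$frame_idx[ok],
    time_s = labels$frames$time_s[ok],
    labels = labels$labels[ok, , drop = FALSE],
    steps = steps, n_units = nrow(rates$rates),
    n_dropped = sum(!ok)
  ), class = "window_sample_set")
}

#' @export
#' @method print window_sample_set
print.window_sample_set <- function(x, ...) {
  cat("window_sample_set:", length(x$centre), "samples of",
      x$steps, "x", x$n_units, "(", x$n_dropped, "frames dropped )\n")
  invisible(x)
}

# Materialise windows i as a batch x steps x units array. Knocked units
# are zeroed, or replaced by a fixed per-unit value when `knock_values`
# is supplied (mean imputation).
window_batch <- function(ws, idx, knock_units = NULL, knock_values = NULL) {
  B <- length(idx)
  X <- array(0, c(B, ws$steps, ws$n_units))
  r <- ws$rates$rates
  for (b in seq_len(B)) {
    cols <- ws$lo[idx[b]]:(ws$lo[idx[b]] + ws$steps - 1L)
    X[b, , ] <- t(r[, cols, drop = FALSE])
  }
  if (!is.null(knock_units) && length(knock_units)) {
    for (k in seq_along(knock_units)) {
      X[, , knock_units[k]] <-
        if (is.null(knock_values)) 0 else knock_values[k]
    }
  }
  X
}

#' 5-fold cross-validation plan with train/validation/test splits
#'
#' Samples are shuffled once, split into `n_folds` equal test groups; within
#' each fold the remaining samples are split 87.5% / 12.5% into training and
#' validation (70% / 10% / 20% of the total for 5 folds). Test sets across
#' folds partition the samples.
#'
#' @param n number of samples.
#' @param n_folds number of folds.
#' @param seed shuffle seed.
#' @return an object of class `fold_plan`: per fold, integer index vectors
#'   `train`, `validation`, `test`.
#' @export
make_fold_plan <- function(n, n_folds = 5, seed = 1L) {
  with_seed(seed, {
    perm <- sample.int(n)
    grp <- rep(seq_len(n_folds), each = ceiling(n / n_folds))[seq_len(n)]
    folds <- lapply(seq_len(n_folds), function(f) {
      test <- perm[grp == f]
      rest <- perm[grp != f]
      n_val <- round(length(rest) * 0.125)
      list(validation = rest[seq_len(n_val)],
           train = rest[-seq_len(n_val)],
           test = test)
    })
    structure(list(folds = folds, n = n, n_folds = n_folds, seed = seed),
              class = "fold_plan")
  })
}

#' @export
#' @method print fold_plan
print.fold_plan <- function(x, ...) {
  f1 <- x$folds[[1]]
  cat("fold_plan:", x$n_folds, "folds over", x$n, "samples ( train",
      length(f1$train), "/ val", length(f1$validation), "/ test",
      length(f1$test), ")\n")
  invisible(x)
}
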