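#' Fit a character-presence decoder to windowed population activity
#'
#' Trains an LSTM (two hidden layers, then two fully connected layers with
#' LeakyReLU and batch normalization) or a CNN (three 3x3 convolution
#' layers with LeakyReLU and batch normalization, one 2x2 max-pool, two
#' fully connected layers) mapping a 60-step x N-unit firing-rate window to
#' a (characters x 3) probability matrix over {YES, NO, DNK}, one softmax
#' per character row. Training minimises the DNK-masked KL-divergence loss
#' with Adam (no class weighting); within each cross-validation fold the
#' epoch checkpoint with the best validation macro F1 is kept.
#'
#' @param windows a `window_sample_set` from [make_window_samples()].
#' @param arch `"lstm"` or `"cnn"`.
#' @param folds a [make_fold_plan()]; defaults to a 5-fold plan.
#' @param fold_subset which folds to fit (default all); fitting one fold is
#'   a cheap approximation used for large simulation sweeps.
#' @param hidden LSTM hidden units per layer.
#' @param fc_dim width of the first fully connected layer.
#' @param channels CNN channel widths for the three convolution layers.
#' @param epochs maximum training epochs (the checkpoint with the best
#'   validation F1 within them is returned).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param train_max,val_max optional caps on the number of training /
#'   validation samples per fold (deterministic subsample given `seed`).
#' @param test_max optional cap on test samples used for fold metrics.
#' @param patience stop a fold early after this many epochs without
#'   validation improvement.
#' @param seed master seed; fold f uses `seed + f` internally.
#' @param verbose print per-epoch progress.
#' @return an object of class `pop_decoder`.
#' @export
fit_decoder <- function(windows, arch = c("lstm", "cnn"), folds = NULL,
                        fold_subset = NULL, hidden = 128, fc_dim = 128,
                        channels = c(16, 32, 64), epochs = 100,
                        batch_size = 64, lr = 1e-3, train_max = NULL,
                        val_max = NULL, test_max = NULL, patience = Inf,
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(windows, "window_sample_set"))
  arch <- match.arg(arch)
  n <- length(windows$centre)
  n_char <- ncol(windows$labels)
  if (is.null(folds)) folds <- make_fold_plan(n, seed = seed)
  stopifnot(inherits(folds, "fold_plan"), folds$n == n)
  use_folds <- fold_subset %||% seq_len(folds$n_folds)
  cap <- function(idx, k, s) {
    if (is.null(k) || length(idx) <= k) idx
    else with_seed(s, sample(idx, k))
  }
  fits <- list()
  metrics <- list()
  for (f in use_folds) {
    fl <- folds$folds[[f]]
    tr <- cap(fl$train, train_max, seed + 1000 + f)
    va <- cap(fl$validation, val_max, seed + 2000 + f)
    te <- cap(fl$test, test_max, seed + 3000 + f)
    net <- nn_init(arch, n_units = windows$n_units, steps = windows$steps,
                   n_char = n_char, hidden = hidden, fc_dim = fc_dim,
                   channels = channels, seed = seed + f)
    net <- nn_train_core(net, windows, tr, va, epochs = epochs,
                         batch_size = batch_size, lr = lr, seed = seed + f,
                         patience = patience, verbose = verbose)
    P_te <- net_predict(net, windows, te)
    y_te <- windows$labels[te, , drop = FALSE]
    pred_yes <- P_te[, (seq_len(n_char) - 1) * 3 + 1, drop = FALSE] > 0.5
    rep_f <- evaluate_metrics(pred_yes, y_te)
    rep_f$mean_kld <- mean(rowMeans(kld_per_character(P_te, y_te, n_char)))
    fits[[as.character(f)]] <- net
    metrics[[as.character(f)]] <- rep_f
  }
  structure(list(arch = arch, fits = fits, folds = folds,
                 fold_ids = use_folds, metrics = metrics,
                 unit_ids = windows$rates$unit_ids,
                 units = windows$rates$units, n_char = n_char,
                 steps = windows$steps,
                 config = list(hidden = hidden, fc_dim = fc_dim,
                               channels = channels, epochs = epochs,
                               batch_size = batch_size, lr = lr,
                               seed = seed)),
            class = "pop_decoder")
}

#' @export
#' @method print pop_decoder
print.pop_decoder <- function(x, ...) {
  f1 <- vapply(x$metrics, function(m) m$macro["f1"], 0)
  cat("pop_decoder (", x$arch, "):", length(x$fits), "fold model(s),",
      length(x$unit_ids), "units,", x$n_char, "characters\n")
  cat("  test macro F1 per fold:", paste(sprintf("%.3f", f1),
                                         collapse = " "), "\n")
  invisible(x)
}

#' @export
#' @method summary pop_decoder
summary.pop_decoder <- function(object, ...) {
  per <- lapply(object$metrics, `[[`, "per_character")
  avg <- Reduce(`+`, lapply(per, function(d) as.matrix(d[, -1]))) /
    length(per)
  out <- data.frame(character = per[[1]]$character, avg)
  cat("Fold-averaged test metrics (", length(per), "fold(s) ):\n")
  print(out, row.names = FALSE, digits = 3)
  invisible(out)
}

#' @export
#' @method plot pop_decoder
plot.pop_decoder <- function(x, ...) {
  hs <- lapply(x$fits, `[[`, "history")
  graphics::plot(NULL, xlim = c(1, max(vapply(hs, nrow, 0))),
                 ylim = c(0, 1), xlab = "epoch",
                 ylab = "validation macro F1",
                 main = paste("decoder training (", x$arch, ")"))
  for (i in seq_along(hs)) {
    graphics::lines(hs[[i]]$epoch, hs[[i]]$val_f1, col = i)
  }
  invisible(x)
}

#' Predict character activations from a fitted decoder
#'
#' The model activation is the predicted probability of YES per character,
#' in `[0, 1]`; the binarized label is 1 when the activation exceeds 0.5.
#' With `fold = "average"` the activations of all fold models are averaged.
#'
#' @param object a `pop_decoder`.
#' @param windows a `window_sample_set` over the same units (same order).
#' @param idx sample indices to predict (default all).
#' @param fold `"average"` or a fold id present in the fit.
#' @param knock_units integer positions (in the decoder's unit order) whose
#'   input columns are zeroed before prediction.
#' @param ... unused.
#' @return an object of class `activation_trace`: `activation` matrix
#'   (samples x characters), `binarized`, `time_s`, and the full
#'   probability array.
#' @export
#' @method predict pop_decoder
predict.pop_decoder <- function(object, windows, idx = NULL,
                                fold = "average", knock_units = NULL, ...) {
  stopifnot(inherits(windows, "window_sample_set"))
  if (!identical(windows$rates$unit_ids, object$unit_ids)) {
    missing <- setdiff(object$unit_ids, windows$rates$unit_ids)
    stop_cfg("unit mismatch between decoder and windows",
             if (length(missing)) paste0("; missing units: ",
                                         paste(missing, collapse = ",")))
  }
  idx <- idx %||% seq_along(windows$centre)
  nets <- if (identical(fold, "average")) object$fits
          else object$fits[as.character(fold)]
  P <- Reduce(`+`, lapply(nets, net_predict, ws = windows, idx = idx,
                          knock_units = knock_units)) / length(nets)
  act <- P[, (seq_len(object$n_char) - 1) * 3 + 1, drop = FALSE]
  structure(list(activation = act, binarized = act > 0.5,
                 time_s = windows$time_s[idx], probs = P,
                 fold_averaged = identical(fold, "average"),
                 n_char = object$n_char),
            class = "activation_trace")
}

#' @export
#' @method print activation_trace
print.activation_trace <- function(x, ...) {
  cat("activation_trace:", nrow(x$activation), "time points x",
      ncol(x$activation), "characters",
      if (x$fold_averaged) "(fold-averaged)" else "", "\n")
  invisible(x)
}

#' Chance-level metric distribution via label shuffling
#'
#' Character label vectors are permuted jointly across samples (preserving
#' their co-occurrence structure), the decoder is retrained per shuffle
#' with the same configuration, and test metrics are collected.
#'
#' @param windows a `window_sample_set`.
#' @param n_shuffles number of shuffled retrainings.
#' @param seed master seed (shuffle s uses `seed + s`).
#' @param ... passed to [fit_decoder()].
#' @return data frame of per-shuffle, per-character test F1 and accuracy,
#'   with a `band` attribute (mean and SD of macro F1).
#' @export
shuffled_chance <- function(windows, n_shuffles = 10, seed = 1L, ...) {
  stopifnot(n_shuffles >= 1)
  out <- list()
  for (s in seq_len(n_shuffles)) {
    ws <- windows
    perm <- with_seed(seed + s, sample.int(nrow(ws$labels)))
    ws$labels <- ws$labels[perm, , drop = FALSE]
    dec <- fit_decoder(ws, seed = seed + s, ...)
    per <- do.call(rbind, lapply(dec$metrics, `[[`, "per_character"))
    agg <- stats::aggregate(per[, c("f1", "accuracy")],
                            by = list(character = per$character), mean)
    out[[s]] <- data.frame(shuffle = s, agg)
  }
  res <- do.call(rbind, out)
  macro <- tapply(res$f1, res$shuffle, mean)
  attr(res, "band") <- c(mean = mean(macro), sd = stats::sd(macro))
  res
}

#' Classical baseline classifiers on flattened windows
#'
#' Three reference methods trained on the same folds as the deep decoders:
#' a prior-sampling Naive Bayes (labels drawn from each character's
#' training label marginal), one-vs-rest L2 logistic regression, and a
#' linear SVM, both on flattened 60 x N windows.
#'
#' @param windows a `window_sample_set`.
#' @param folds a [make_fold_plan()].
#' @param methods subset of `c("nb_prior", "logistic", "svm")`.
#' @param fold_subset folds to evaluate (default fold 1).
#' @param train_max,test_max caps on training / test samples per fold.
#' @param seed seed for the NB prior sampler and subsampling.
#' @return named list of `metrics_report` objects, one per method.
#' @export
baseline_classifiers <- function(windows, folds = NULL,
                                 methods = c("nb_prior", "logistic", "svm"),
                                 fold_subset = 1L, train_max = 2000,
                                 test_max = 2000, seed = 1L) {
  stopifnot(inherits(windows, "window_sample_set"))
  n <- length(windows$centre)
  n_char <- ncol(windows$labels)
  if (is.null(folds)) folds <- make_fold_plan(n, seed = seed)
  flatten <- function(idx) {
    X <- window_batch(windows, idx)
    matrix(X, length(idx))
  }
  reports <- list()
  for (m in methods) reports[[m]] <- list(pred = NULL, truth = NULL)
  for (f in fold_subset) {
    fl <- folds$folds[[f]]
    tr <- with_seed(seed + f, if (length(fl$train) > train_max) {
      sample(fl$train, train_max)
    } else fl$train)
    te <- with_seed(seed + 100 + f, if (length(fl$test) > test_max) {
      sample(fl$test, test_max)
    } else fl$test)
    y_tr <- windows$labels[tr, , drop = FALSE]
    y_te <- windows$labels[te, , drop = FALSE]
    needs_X <- any(c("logistic", "svm") %in% methods)
    if (needs_X) {
      X_tr <- flatten(tr)
      X_te <- flatten(te)
    }
    for (m in methods) {
      pred <- matrix(FALSE, length(te), n_char)
      for (c in seq_len(n_char)) {
        if (m == "nb_prior") {
          marg <- tabulate(y_tr[, c], 3) / nrow(y_tr)
          draw <- with_seed(seed + 17 * c + f,
                            sample.int(3, length(te), replace = TRUE,
                                       prob = marg))
          pred[, c] <- draw == LBL_YES
        } else {
          live_tr <- y_tr[, c] != LBL_DNK
          yy <- as.integer(y_tr[live_tr, c] == LBL_YES)
          if (length(unique(yy)) < 2) next
          if (m == "logistic") {
            fit <- glmnet::glmnet(X_tr[live_tr, ], yy, family = "binomial",
                                  alpha = 0, lambda = 0.01)
            pr <- stats::predict(fit, X_te, type = "response")
            pred[, c] <- pr[, 1] > 0.5
          } else {
            sv_idx <- which(live_tr)
            if (length(sv_idx) > 1500) {
              sv_idx <- with_seed(seed + 31 * c + f, sample(sv_idx, 1500))
            }
            fit <- e1071::svm(X_tr[sv_idx, ],
                              factor(y_tr[sv_idx, c] == LBL_YES,
                                     c(FALSE, TRUE)),
                              kernel = "linear", scale = FALSE)
            pred[, c] <- stats::predict(fit, X_te) == "TRUE"
          }
        }
      }
      reports[[m]]$pred <- rbind(reports[[m]]$pred, pred)
      reports[[m]]$truth <- rbind(reports[[m]]$truth, y_te)
    }
  }
  lapply(reports, function(r) evaluate_metrics(r$pred, r$truth))
}
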