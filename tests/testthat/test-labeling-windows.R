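toy_timeline <- function(occ, frame_rate = 7.5, dialogue = NULL) {
  n <- nrow(occ)
  dur <- n / frame_rate
  dlg <- dialogue %||% data.frame(start_s = numeric(0), end_s = numeric(0))
  if (is.null(dlg$chars)) dlg$chars <- list()
  structure(list(
    frames = data.frame(frame_idx = seq_len(n) - 1L,
                        time_s = (seq_len(n) - 1) / frame_rate),
    occupancy = occ, size = occ * 0.2,
    cuts = data.frame(cut_id = 1L, start_s = 0, end_s = dur,
                      scene_id = 1L),
    scenes = data.frame(scene_id = 1L, start_s = 0, end_s = dur),
    scene_chars = matrix(TRUE, 1, ncol(occ)), dialogue = dlg,
    config = timeline_config(n_characters = ncol(occ), duration_s = dur,
                             frame_rate_hz = frame_rate)
  ), class = "character_timeline")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("dialogue partners absent from a frame are labelled DNK", {
  # frames alternate A-only / B-only inside a dialogue listing {A, B}
  occ <- cbind(rep(c(TRUE, FALSE), 8), rep(c(FALSE, TRUE), 8))
  tl <- toy_timeline(occ)
  dlg <- data.frame(start_s = 0, end_s = 16 / 7.5)
  dlg$chars <- list(c(1L, 2L))
  lab <- build_frame_labels(tl, dlg)
  expect_true(all(lab$labels[!occ[, 1], 1] == 3L))
  expect_true(all(lab$labels[!occ[, 2], 2] == 3L))
  expect_true(all(lab$labels[occ] == 1L))
  # no ambiguity intervals -> no DNK anywhere
  lab0 <- build_frame_labels(tl, NULL)
  expect_false(any(lab0$labels == 3L))
  # overlapping contradictory intervals -> error
  dlg2 <- data.frame(start_s = c(0, 0.5), end_s = c(1.5, 2))
  dlg2$chars <- list(c(1L, 2L), c(1L, 2L))
  expect_error(build_frame_labels(tl, dlg2), "overlapping")
})

test_that("windows cover one second before and after the frame", {
  st <- tiny_study()
  ws <- st$windows
  k <- which(abs(ws$time_s - 10.0) < 1e-9)
  expect_length(k, 1)
  X <- popvision:::window_batch(ws, k)
  # frame at 10.0 s with rates from 0 s at 30 Hz: samples 270..329
  # (0-based), i.e. columns 271..330
  expect_equal(X[1, , ], t(st$rates$rates[, 271:330]),
               ignore_attr = TRUE)
  # frames whose window would underrun the origin are dropped
  expect_false(any(ws$time_s < 1))
  # one sample per eligible frame
  expect_equal(length(ws$centre) + ws$n_dropped, nrow(st$labels$frames))
})

test_that("windowing rejects an empty eligible set", {
  st <- tiny_study()
  lab <- st$labels
  lab$frames <- lab$frames[1:3, ]      # all within 1 s of the origin
  lab$labels <- lab$labels[1:3, , drop = FALSE]
  expect_error(make_window_samples(st$rates, lab), "eligible")
})

test_that("cut aggregation applies the length-conditional rule", {
  cuts <- data.frame(start_s = c(0, 1.3, 3.3), end_s = c(1.3, 3.3, 5.3))
  n <- 159
  tt <- (seq_len(n) - 1) / 30
  det <- matrix(FALSE, n, 1)
  # cut 1: 39 frames (1.3 s), 12 detections -> present (short-cut rule)
  det[1:12, 1] <- TRUE
  # cut 2: 60 frames (2.0 s), 20 detections (33%) -> absent (40% rule)
  det[40:59, 1] <- TRUE
  # cut 3: 60 frames, 25 detections (41.7%) -> present
  det[100:124, 1] <- TRUE
  out <- aggregate_frames_to_cuts(det, tt, cuts)
  expect_equal(as.vector(out$present), c(TRUE, FALSE, TRUE))
})

test_that("cut aggregation is monotone in detections", {
  set.seed(21)
  cuts <- data.frame(start_s = c(0, 2), end_s = c(2, 3))
  tt <- (0:89) / 30
  for (i in 1:20) {
    det <- matrix(runif(90) < 0.4, 90, 1)
    more <- det
    more[sample(which(!det), 5)] <- TRUE
    a <- aggregate_frames_to_cuts(det, tt, cuts)$present
    b <- aggregate_frames_to_cuts(more, tt, cuts)$present
    expect_true(all(b[a]))   # present never flips to absent
  }
})

test_that("cut-level confusion matrices normalize by truth counts", {
  n <- 100
  truth_v <- c(rep(TRUE, 10), rep(FALSE, 90))
  pred_v <- truth_v
  pred_v[1:2] <- FALSE            # catches 8 of 10 YES
  pred_v[11:19] <- TRUE           # mislabels 9 of 90 NO
  mk <- function(v) structure(list(
    cuts = data.frame(start_s = seq_len(n) - 1, end_s = seq_len(n)),
    present = matrix(v, n, 1)), class = "cut_label_table")
  cf <- confusion_vs_reference(mk(pred_v), mk(truth_v))
  expect_equal(cf$per_character[[1]],
               matrix(c(0.8, 0.2, 0.1, 0.9), 2, byrow = TRUE,
                      dimnames = list(truth = c("YES", "NO"),
                                      pred = c("YES", "NO"))))
  expect_equal(rowSums(cf$pooled), c(YES = 1, NO = 1))
  # perfect prediction -> identity matrix
  cfp <- confusion_vs_reference(mk(truth_v), mk(truth_v))
  expect_equal(unname(cfp$per_character[[1]]), diag(2))
})

test_that("fold plans partition samples as 70/10/20", {
  fp <- make_fold_plan(1000, seed = 4)
  all_test <- sort(unlist(lapply(fp$folds, `[[`, "test")))
  expect_equal(all_test, 1:1000)   # test sets partition the samples
  f <- fp$folds[[2]]
  expect_equal(sort(c(f$train, f$validation, f$test)), 1:1000)
  expect_equal(length(f$test), 200)
  expect_equal(length(f$validation), 100)
  expect_equal(length(f$train), 700)
})
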