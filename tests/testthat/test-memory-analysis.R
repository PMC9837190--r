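test_that("clip presence applies the two-threshold rule", {
  frac <- rbind(c(0.6, 0.1), c(0.0, 0.3))
  size <- rbind(c(0.3, 0.05), c(0, 0.2))
  p <- clip_presence(frac, size, prevalence_threshold = 0.5,
                     size_threshold = 0)
  expect_equal(p, rbind(c(TRUE, FALSE), c(FALSE, FALSE)))
  # thresholds (0, 0): presence is "appears at least once"
  p0 <- clip_presence(frac, size, 0, 0)
  expect_equal(p0, frac > 0)
  # the size threshold can veto a frequent but tiny character
  p2 <- clip_presence(frac, size, prevalence_threshold = 0.25,
                      size_threshold = 0.25)
  expect_equal(p2, rbind(c(TRUE, FALSE), c(FALSE, FALSE)))
})

test_that("association matrices implement the duration-ratio formula", {
  scenes <- rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))
  A <- association_matrix(scenes, c(10, 10, 20))
  expect_equal(A[1, 2], 10 / 30)
  expect_equal(A[2, 1], 10 / 20)
  expect_equal(diag(A), c(1, 1))
  # a character co-occurring with nobody: off-diagonals zero
  s2 <- rbind(c(TRUE, FALSE), c(FALSE, TRUE))
  A2 <- association_matrix(s2, c(5, 5))
  expect_equal(A2[1, 2], 0)
  expect_equal(A2[2, 1], 0)
  # a character that never appears has an undefined column
  s3 <- cbind(c(TRUE, TRUE), c(FALSE, FALSE))
  A3 <- association_matrix(s3, c(5, 5))
  expect_true(all(is.na(A3[, 2])))
})

test_that("planted co-occurrence is recovered from generated scenes", {
  tl <- generate_character_timeline(timeline_config(duration_s = 2520),
                                    seed = 4)
  A <- association_matrix(tl)
  expect_lt(max(abs(A - tl$planted$cooccurrence), na.rm = TRUE), 0.05)
})

test_that("coactivation matrices count conditional activations", {
  act <- matrix(FALSE, 10, 2)
  act[1:4, 2] <- TRUE
  act[1:3, 1] <- TRUE
  M <- coactivation_matrix(act)
  expect_equal(M[1, 2], 0.75)
  expect_equal(diag(M), c(1, 1))
  # identical activation patterns give all ones
  same <- cbind(act[, 2], act[, 2])
  expect_true(all(coactivation_matrix(same) == 1))
  # a never-activated conditioning character is undefined
  act0 <- cbind(act[, 1], rep(FALSE, 10))
  expect_true(all(is.na(coactivation_matrix(act0)[, 2])))
})

test_that("association-coactivation correlation uses off-diagonals only", {
  set.seed(8)
  A <- matrix(runif(16), 4, 4); diag(A) <- 1
  out <- correlate_association_coactivation(A, A^2)  # monotone transform
  expect_equal(out$r, 1)
  expect_equal(out$n, 12)
})

test_that("phase comparison detects a uniform response-time increase", {
  set.seed(9)
  cm_clip <- matrix(runif(16, 0.2, 0.6), 4, 4)
  cm_resp <- cm_clip + 0.1
  out <- compare_phase_coactivation(cm_clip, cm_resp)
  expect_lt(out$p, 0.01)
  expect_equal(out$median_diff, 0.1)
  # identical matrices: no evidence of a difference
  expect_equal(compare_phase_coactivation(cm_clip, cm_clip)$p, 1)
  expect_warning(compare_phase_coactivation(matrix(1, 2, 2) * NA,
                                            matrix(1, 2, 2) * NA),
                 "underpowered")
})

test_that("the activation GLM recovers planted effects", {
  set.seed(10)
  n <- 200
  clips <- data.frame(clip_id = 1:n, onset_s = (1:n) * 8 - 8,
                      offset_s = (1:n) * 8 - 3,
                      response_onset_s = (1:n) * 8 - 3,
                      response_offset_s = (1:n) * 8,
                      is_target = rep(c(TRUE, FALSE), n / 2),
                      response_seen = runif(n) < 0.5,
                      source_onset_s = runif(n, 0, 100))
  presence <- matrix(runif(n * 4) < 0.3, n, 4)
  act <- 0.39 * presence + 0.24 * clips$response_seen +
    matrix(rnorm(n * 4, sd = 0.3), n, 4)
  g <- glm_activation(act, clips, presence)
  est <- g$coefficients$estimate[match(c("presence", "seen"),
                                       g$coefficients$term)]
  expect_lt(abs(est[1] - 0.39), 0.1)
  expect_lt(abs(est[2] - 0.24), 0.1)
  # degenerate design: constant presence errors with the column named
  expect_error(glm_activation(act, clips, matrix(TRUE, n, 4)),
               "presence")
})

test_that("appearance frequency is a cumulative fraction in [0, 1]", {
  tl <- generate_character_timeline(timeline_config(duration_s = 300),
                                    seed = 1)
  clips <- data.frame(source_onset_s = c(10, 150, 290))
  af <- appearance_frequency(tl, clips)
  expect_true(all(af >= 0 & af <= 1))
  expect_equal(dim(af), c(3, 4))
  # late clips approach the overall prevalence
  expect_equal(unname(af[3, ]), unname(colMeans(tl$occupancy)),
               tolerance = 0.05)
})

test_that("an empty MTL set makes the knockout GLM the identity", {
  cfg <- timeline_config(duration_s = 300, prevalence = 0.2)
  tl2 <- generate_character_timeline(cfg, seed = 12)
  pop <- population_spec(4, regions = c("occipital", "frontal"),
                         units_per_region = 6, gain = 4,
                         tuned_fraction = 1, seed = 1)
  st <- simulate_study(cfg, pop, seed = 1, artifact_screen = FALSE)
  dec <- fit_decoder(st$windows, "lstm", hidden = 6, fc_dim = 6,
                     epochs = 1, fold_subset = 1, train_max = 400,
                     val_max = 100, test_max = 100, seed = 1)
  ms <- generate_memory_session(memory_session_spec(n_clips = 100,
                                                    clip_len_s = 3,
                                                    response_len_s = 2),
                                st$timeline, tl2, pop, seed = 2)
  expect_warning(res <- mtl_knockout_memory_glm(dec, ms), "no MTL units")
  expect_identical(res$intact$coefficients, res$knocked$coefficients)
})

test_that("memory-clip decoding does not beat held-out movie decoding", {
  cfg <- timeline_config(duration_s = 600, prevalence = 0.2)
  pop <- population_spec(4, regions = c("occipital", "hippocampus"),
                         units_per_region = c(10, 6), gain = 4,
                         tuned_fraction = 1, baseline_hz = c(3, 7),
                         seed = 2)
  st <- simulate_study(cfg, pop, seed = 2, artifact_screen = FALSE)
  dec <- fit_decoder(st$windows, "lstm", hidden = 16, fc_dim = 16,
                     epochs = 3, lr = 2e-3, fold_subset = 1,
                     train_max = 2000, val_max = 300, test_max = 600,
                     seed = 2)
  movie_acc <- mean(dec$metrics[["1"]]$per_character$accuracy)
  tl2 <- generate_character_timeline(cfg, seed = 77)
  ms <- generate_memory_session(
    memory_session_spec(n_clips = 120, clip_len_s = 4, response_len_s = 2),
    st$timeline, tl2, pop, seed = 3)
  tr <- session_activations(dec, ms)
  act_max <- phase_max_activation(tr, ms$clips, "clip")
  pres <- clip_presence(ms$presence_frac, prevalence_threshold = 0.2)
  clip_acc <- mean((act_max > 0.5) == pres)
  expect_gt(movie_acc, 0.8)            # the decoder genuinely decodes
  expect_lte(clip_acc, movie_acc + 0.02)
})
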