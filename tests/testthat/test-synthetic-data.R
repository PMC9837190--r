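test_that("timeline prevalence converges to the configured values", {
  tl <- generate_character_timeline(
    timeline_config(duration_s = 2520, prevalence = 0.15), seed = 1)
  expect_true(all(abs(colMeans(tl$occupancy) - 0.15) <= 0.03))
})

test_that("timeline respects structural invariants", {
  tl <- generate_character_timeline(timeline_config(duration_s = 600),
                                    seed = 3)
  expect_true(all(diff(tl$frames$time_s) > 0))
  expect_true(all(tl$size >= 0 & tl$size <= 0.5))
  expect_true(all(tl$size[!tl$occupancy] == 0))
  # cuts tile the episode without overlap
  expect_true(all(tl$cuts$end_s > tl$cuts$start_s))
  expect_equal(tl$cuts$start_s[-1], tl$cuts$end_s[-nrow(tl$cuts)])
  # every frame falls in exactly one cut
  idx <- findInterval(tl$frames$time_s, tl$cuts$start_s)
  expect_true(all(idx >= 1 & idx <= nrow(tl$cuts)))
})

test_that("zero prevalence silences a character and bad configs error", {
  tl <- generate_character_timeline(
    timeline_config(prevalence = c(0.15, 0.15, 0, 0.15), duration_s = 400),
    seed = 2)
  expect_false(any(tl$occupancy[, 3]))
  expect_error(timeline_config(duration_s = -1), "positive")
  expect_error(timeline_config(frame_rate_hz = 0), "positive")
  expect_error(timeline_config(prevalence = 1.2), "0, 1")
})

test_that("timeline generation is deterministic given the seed", {
  cfg <- timeline_config(duration_s = 400)
  expect_identical(generate_character_timeline(cfg, seed = 9),
                   generate_character_timeline(cfg, seed = 9))
})

test_that("default label mix matches the study's YES/NO/DNK proportions", {
  tl <- generate_character_timeline(timeline_config(), seed = 1)
  lab <- build_frame_labels(tl)
  frac <- tabulate(lab$labels, 3) / length(lab$labels)
  expect_gte(frac[1], 0.07); expect_lte(frac[1], 0.13)
  expect_gte(frac[3], 0.01); expect_lte(frac[3], 0.04)
})

test_that("an untuned unit fires as a homogeneous Poisson process", {
  cfg <- timeline_config(duration_s = 1000, prevalence = 0.15)
  tl <- generate_character_timeline(cfg, seed = 1)
  pop <- population_spec(4, regions = "occipital", units_per_region = 1,
                         baseline_hz = c(1, 1), tuned_fraction = 0,
                         seed = 1)
  sp <- simulate_spikes(tl, pop, seed = 4)
  n <- nrow(sp$spikes)
  expect_gte(n, qpois(0.005, 1000))
  expect_lte(n, qpois(0.995, 1000))
})

test_that("all-unit gains of 1 give presence-independent rates", {
  cfg <- timeline_config(duration_s = 2520, prevalence = 0.15)
  tl <- generate_character_timeline(cfg, seed = 1)
  pop <- population_spec(4, regions = "occipital", units_per_region = 4,
                         baseline_hz = c(4, 4), tuned_fraction = 0,
                         seed = 1)
  sp <- simulate_spikes(tl, pop, seed = 5)
  # 100 ms bin counts split by character-1 presence at the bin midpoint
  counts <- colSums(popvision:::bin_spike_counts(sp, 0.1, 2520))
  mid <- (seq_along(counts) - 0.5) * 0.1
  fi <- pmin(floor(mid * 7.5) + 1, nrow(tl$frames))
  present <- tl$occupancy[fi, 1]
  d <- mean(counts[present]) - mean(counts[!present])
  se <- sqrt(var(counts[present]) / sum(present) +
               var(counts[!present]) / sum(!present))
  expect_lt(abs(d), 3 * se)
})

test_that("rho = 0 leaves within-region count correlations near zero", {
  cfg <- timeline_config(duration_s = 2520, prevalence = 0.15)
  tl <- generate_character_timeline(cfg, seed = 1)
  pop <- population_spec(4, regions = "occipital", units_per_region = 6,
                         baseline_hz = c(4, 4), tuned_fraction = 0,
                         rho = 0, seed = 1)
  sp <- simulate_spikes(tl, pop, seed = 6)
  counts <- popvision:::bin_spike_counts(sp, 0.1, 2520)
  cm <- cor(t(counts))
  off <- cm[upper.tri(cm)]
  expect_gt(mean(off), -0.02)
  expect_lt(mean(off), 0.02)
})

test_that("spike conservation and determinism hold", {
  cfg <- timeline_config(duration_s = 200)
  tl <- generate_character_timeline(cfg, seed = 1)
  pop <- tiny_pop()
  sp1 <- simulate_spikes(tl, pop, seed = 7)
  sp2 <- simulate_spikes(tl, pop, seed = 7)
  expect_identical(sp1, sp2)
  per_unit <- table(factor(sp1$spikes$unit_id,
                           levels = pop$units$unit_id))
  expect_equal(sum(per_unit), nrow(sp1$spikes))
  expect_error(population_spec(rho = 2), "rho")
})

test_that("memory sessions have exactly half target clips", {
  cfg <- timeline_config(duration_s = 300)
  tl1 <- generate_character_timeline(cfg, seed = 1)
  tl2 <- generate_character_timeline(cfg, seed = 2)
  ms <- generate_memory_session(memory_session_spec(n_clips = 100),
                                tl1, tl2, tiny_pop(), seed = 1)
  expect_equal(sum(ms$clips$is_target), 50)
  expect_equal(sum(!ms$clips$is_target), 50)
  expect_warning(memory_session_spec(n_clips = 50), "range")
  expect_identical(
    generate_memory_session(memory_session_spec(120), tl1, tl2,
                            tiny_pop(), seed = 3),
    generate_memory_session(memory_session_spec(120), tl1, tl2,
                            tiny_pop(), seed = 3))
})

test_that("zero reinstatement gain leaves seen and unseen clips equal", {
  cfg <- timeline_config(duration_s = 300)
  tl1 <- generate_character_timeline(cfg, seed = 1)
  tl2 <- generate_character_timeline(cfg, seed = 2)
  pop <- tiny_pop()
  mtl <- which(pop$units$region %in% pop$mtl_regions)
  spec <- memory_session_spec(n_clips = 100, clip_len_s = 3,
                              response_len_s = 2, reinstatement_gain = 0)
  ok <- 0
  n_runs <- 20
  for (s in seq_len(n_runs)) {
    ms <- generate_memory_session(spec, tl1, tl2, pop, seed = 100 + s)
    counts <- popvision:::bin_spike_counts(ms$spikes,
                                           1, ms$spikes$duration_s)
    mtl_rate <- colSums(counts[mtl, , drop = FALSE])
    sec_clip <- pmin(floor((seq_along(mtl_rate) - 0.5) / 5) + 1, 100)
    per_clip <- tapply(mtl_rate, sec_clip, mean)
    p <- t.test(per_clip[ms$clips$response_seen],
                per_clip[!ms$clips$response_seen])$p.value
    if (p > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 0.9 * n_runs)
})

test_that("planted embeddings separate and flag faces as configured", {
  emb <- generate_embeddings(n_identities = 4, clusters_per_identity = 8,
                             noise_sd = 1, separation = 10, seed = 2)
  feats <- compute_cluster_features(emb)
  ids <- vapply(feats$clusters, `[[`, 0L, "identity")
  sil <- cluster::silhouette(ids, dist(feats$feature))
  expect_gt(mean(sil[, 3]), 0.8)

  e0 <- generate_embeddings(2, 4, faceless_fraction = 0, seed = 1)
  expect_true(all(unlist(lapply(e0$clusters, `[[`, "has_face"))))

  e1 <- generate_embeddings(1, 10, noise_sd = 1, seed = 3)
  f1 <- compute_cluster_features(e1)
  expect_lt(max(dist(f1$feature)), 4)
  expect_error(generate_embeddings(2, 4, noise_sd = -1), "non-negative")
})
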