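test_that("cluster features average face-bearing crops only", {
  e <- rbind(c(1, 1), c(3, 3), c(100, 100))
  cl <- list(cluster_id = 1L, embeddings = e,
             has_face = c(TRUE, TRUE, FALSE), frame_span = c(0, 1),
             identity = 1L)
  crops <- structure(list(clusters = list(cl), dim = 2, n_identities = 1),
                     class = "crop_cluster_set")
  f <- compute_cluster_features(crops)
  expect_equal(unname(f$feature[1, ]), c(2, 2))
  # identical crops give the crop itself
  cl2 <- cl; cl2$embeddings <- rbind(c(5, 5), c(5, 5))
  cl2$has_face <- c(TRUE, TRUE)
  crops2 <- structure(list(clusters = list(cl2), dim = 2,
                           n_identities = 1), class = "crop_cluster_set")
  expect_equal(unname(compute_cluster_features(crops2)$feature[1, ]),
               c(5, 5))
  # a cluster with 85% faceless crops is dropped
  cl3 <- cl
  cl3$embeddings <- matrix(rnorm(40), 20)
  cl3$has_face <- c(rep(FALSE, 17), rep(TRUE, 3))
  crops3 <- structure(list(clusters = list(cl, cl3), dim = 2,
                           n_identities = 1), class = "crop_cluster_set")
  f3 <- compute_cluster_features(crops3)
  expect_equal(f3$dropped, cl3$cluster_id)
  expect_equal(nrow(f3$feature), 1)
  expect_error(compute_cluster_features(
    structure(list(clusters = list(), dim = 2), class = "crop_cluster_set")),
    "empty")
})

test_that("cluster distance pools K nearest distances per member", {
  A <- scalar_cluster(c(0, 1))
  B <- scalar_cluster(10, id = 2L)
  expect_equal(cluster_distance(A, B, K = 1), 9.5)
  expect_equal(cluster_distance(A, A, K = 1), 0)
  # asymmetry witness on unequal sizes
  C1 <- scalar_cluster(c(0, 1, 2))
  C2 <- scalar_cluster(c(0, 10))
  expect_equal(cluster_distance(C1, C2, K = 1), 1)
  expect_equal(cluster_distance(C2, C1, K = 1), 4)
  # K larger than |B| clips with a warning
  expect_warning(d <- cluster_distance(A, B, K = 5), "clipped")
  expect_equal(d, 9.5)
  # the alternative pooling takes the K smallest nearest distances
  expect_equal(cluster_distance(A, B, K = 1, pool = "k_smallest_nearest"),
               9)
})

test_that("supernode formation separates planted identities", {
  emb <- generate_embeddings(4, 8, seed = 5)
  feats <- compute_cluster_features(emb)
  cfg <- clustering_config(k = 12, seed = 2)
  sn <- form_supernodes(feats, cfg)
  id_of <- function(ids) {
    vapply(emb$clusters[ids], `[[`, 0L, "identity")
  }
  for (s in sn$supernodes) {
    expect_length(unique(id_of(s$members)), 1)   # every supernode pure
  }
  # distortion threshold 0: nothing qualifies
  sn0 <- form_supernodes(feats, clustering_config(k = 12,
                                                  distortion_threshold = 0,
                                                  seed = 2))
  expect_length(sn0$supernodes, 0)
  expect_length(sn0$candidates, nrow(feats$feature))
  # determinism and the k > n guard
  sn2 <- form_supernodes(feats, cfg)
  expect_identical(lapply(sn$supernodes, `[[`, "members"),
                   lapply(sn2$supernodes, `[[`, "members"))
  expect_error(form_supernodes(feats, clustering_config(k = 999)),
               "exceeds")
})

test_that("candidate absorption respects the assignment threshold", {
  emb <- generate_embeddings(4, 8, seed = 5)
  feats <- compute_cluster_features(emb)
  cfg <- clustering_config(k = 12, seed = 2)
  sn <- form_supernodes(feats, cfg)
  ab <- absorb_candidates(sn$supernodes, sn$candidates, cfg)
  id_of <- function(ids) vapply(emb$clusters[ids], `[[`, 0L, "identity")
  for (s in ab$supernodes) {
    expect_length(unique(id_of(s$members)), 1)  # purity preserved
  }
  # an impossible threshold absorbs nothing and stops after one pass
  tight <- clustering_config(k = 12, assignment_threshold = 1e-9, seed = 2)
  ab0 <- absorb_candidates(sn$supernodes, sn$candidates, tight)
  expect_length(ab0$candidates, length(sn$candidates))
  expect_equal(ab0$iterations, 1)
  expect_error(absorb_candidates(list(), sn$candidates, cfg),
               "at least one supernode")
})

test_that("the full loop recovers planted identities in two iterations", {
  emb <- generate_embeddings(4, 10, seed = 3)
  out <- identity_clustering(emb, clustering_config(k = 12, seed = 1))
  expect_lte(out$iterations, 2)
  expect_equal(unname(out$purity), 1)
  expect_gte(out$completeness, 0.9)
  expect_length(out$components, 4)
})

test_that("graph fine-tuning splits distant groups and honors thresholds", {
  mk <- function(v, id, span) {
    cl <- scalar_cluster(v, id = id)
    cl$frame_span <- span
    cl
  }
  tight1 <- list(mk(c(0, 0.1), 1L, c(0, 1)), mk(c(0.2, 0.3), 2L, c(2, 3)))
  tight2 <- list(mk(c(50, 50.1), 3L, c(0, 1)), mk(c(50.2), 4L, c(2, 3)))
  comps <- finetune_graph(c(tight1, tight2), prune_threshold = 5)
  expect_length(comps, 2)
  expect_setequal(comps[[which(vapply(comps, function(x) 1L %in% x,
                                      TRUE))]], c(1L, 2L))
  # single cluster: one component
  expect_length(finetune_graph(tight1[1]), 1)
  # pruning threshold 0: all singletons
  expect_length(finetune_graph(c(tight1, tight2), prune_threshold = 0), 4)
  # overlapping frame spans forbid merging even at zero distance
  ov <- list(mk(c(0, 0.1), 1L, c(0, 5)), mk(c(0, 0.1), 2L, c(3, 8)))
  expect_length(finetune_graph(ov, prune_threshold = 5), 2)
})

test_that("purity and completeness follow their definitions", {
  emb <- generate_embeddings(4, 5, crops_per_cluster = 10, seed = 6)
  ids <- vapply(emb$clusters, `[[`, 0L, "cluster_id")
  planted <- vapply(emb$clusters, `[[`, 0L, "identity")
  # perfect recovery
  perfect <- lapply(1:4, function(k) ids[planted == k])
  expect_equal(unname(purity_completeness(perfect, emb)), c(1, 1))
  # everything in one component: purity ~ 1/4, completeness 1
  lump <- purity_completeness(list(ids), emb)
  expect_lt(abs(lump["purity"] - 0.25), 0.1)
  expect_equal(unname(lump["completeness"]), 1)
  # singletons: purity 1, completeness ~ 1 / clusters_per_identity
  single <- purity_completeness(as.list(ids), emb)
  expect_equal(unname(single["purity"]), 1)
  expect_lt(abs(single["completeness"] - 1 / 5), 0.1)
})
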