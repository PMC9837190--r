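#' Configuration for supernode clustering
#'
#' Thresholds default to `NULL`, meaning they are calibrated from the data:
#' the distortion threshold keeps the tighter half of the k-means
#' super-clusters, and the assignment threshold is half the median
#' inter-supernode centroid distance.
#'
#' @param k k-means cluster count; chosen deliberately larger than the
#'   expected identity count so impure super-clusters exist and dissolve.
#' @param K neighbour count for the cluster distance.
#' @param distortion_threshold accept a super-cluster as a supernode when
#'   its mean squared distance to centroid is below this.
#' @param assignment_threshold maximum distance at which a candidate is
#'   absorbed by its nearest supernode.
#' @param growth_threshold stop iterating when no supernode grows by more
#'   than this fraction.
#' @param prune_threshold edge-weight threshold for graph fine-tuning.
#' @param seed k-means seed.
#' @return an object of class `clustering_config`.
#' @export
clustering_config <- function(k = 12, K = 5, distortion_threshold = NULL,
                              assignment_threshold = NULL,
                              growth_threshold = 0.05,
                              prune_threshold = NULL, seed = 1L) {
  stopifnot(k >= 1, K >= 1, growth_threshold > 0)
  structure(list(k = k, K = K,
                 distortion_threshold = distortion_threshold,
                 assignment_threshold = assignment_threshold,
                 growth_threshold = growth_threshold,
                 prune_threshold = prune_threshold, seed = seed),
            class = "clustering_config")
}

#' Per-cluster mean face embeddings
#'
#' Averages the embeddings of face-bearing crops per crop cluster. A
#' cluster losing more than 80% of its crops for lack of facial features
#' is removed (and reported in the `dropped` attribute).
#'
#' @param crops a `crop_cluster_set`.
#' @param max_faceless maximum tolerated faceless fraction.
#' @return data-free list of cluster features: `cluster_id`, `feature`
#'   (matrix rows), `n_crops`, plus the filtered `clusters`.
#' @export
compute_cluster_features <- function(crops, max_faceless = 0.8) {
  stopifnot(inherits(crops, "crop_cluster_set"))
  if (!length(crops$clusters)) stop_cfg("empty crop cluster set")
  keep <- vapply(crops$clusters, function(cl) {
    mean(!cl$has_face) <= max_faceless
  }, TRUE)
  kept <- crops$clusters[keep]
  features <- t(vapply(kept, function(cl) {
    colMeans(cl$embeddings[cl$has_face, , drop = FALSE])
  }, numeric(crops$dim)))
  structure(list(cluster_id = vapply(kept, `[[`, 0L, "cluster_id"),
                 feature = features,
                 n_crops = vapply(kept, function(cl) sum(cl$has_face), 0),
                 clusters = kept,
                 dropped = vapply(crops$clusters[!keep], `[[`, 0L,
                                  "cluster_id")),
            class = "cluster_features")
}

# Face-bearing crop embeddings of a cluster (or a merged member list).
face_crops <- function(cl) cl$embeddings[cl$has_face, , drop = FALSE]

#' Directed cluster distance
#'
#' For each face crop in A, its K nearest distances to the face crops of B
#' are pooled; the median of the pool is the distance from A to B
#' (Euclidean metric on embeddings). Asymmetric in general. K larger than
#' |B| is clipped with a warning.
#'
#' @param A,B crop clusters (lists with `embeddings` and `has_face`).
#' @param K neighbour count.
#' @param pool `"per_member_k"` pools each member's K nearest distances
#'   (the default reading); `"k_smallest_nearest"` takes the K smallest of
#'   the per-member nearest distances instead.
#' @return scalar distance.
#' @export
cluster_distance <- function(A, B, K = 5,
                             pool = c("per_member_k",
                                      "k_smallest_nearest")) {
  pool <- match.arg(pool)
  ea <- face_crops(A); eb <- face_crops(B)
  stopifnot(nrow(ea) > 0, nrow(eb) > 0)
  if (K > nrow(eb)) {
    warning("K clipped to |B| = ", nrow(eb), call. = FALSE)
    K <- nrow(eb)
  }
  d2 <- outer(rowSums(ea^2), rowSums(eb^2), `+`) - 2 * tcrossprod(ea, eb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  pooled <- if (pool == "per_member_k") {
    apply(d, 1, function(row) sort(row)[seq_len(K)])
  } else {
    nearest <- apply(d, 1, min)
    sort(nearest)[seq_len(min(K, length(nearest)))]
  }
  stats::median(pooled)
}

merge_clusters <- function(members) {
  list(cluster_id = members[[1]]$cluster_id,
       embeddings = do.call(rbind, lapply(members, `[[`, "embeddings")),
       has_face = unlist(lapply(members, `[[`, "has_face")),
       frame_span = range(unlist(lapply(members, `[[`, "frame_span"))),
       members = unlist(lapply(members, function(m) {
         m$members %||% m$cluster_id
       })),
       member_spans = do.call(rbind, lapply(members, function(m) {
         m$member_spans %||% matrix(m$frame_span, 1)
       })),
       member_clusters = unlist(lapply(members, function(m) {
         m$member_clusters %||% list(m)
       }), recursive = FALSE))
}

#' Form supernodes by k-means over cluster features
#'
#' Runs k-means with a deliberately large k; super-clusters whose
#' distortion (mean squared distance to the centroid) falls below the
#' threshold become supernodes, the rest dissolve into candidate crop
#' clusters.
#'
#' @param feats a `cluster_features` object.
#' @param config a [clustering_config()].
#' @return list with `supernodes` (each a merged crop cluster with a
#'   `members` id vector), `candidates` (single crop clusters) and the
#'   distortion per super-cluster.
#' @export
form_supernodes <- function(feats, config) {
  stopifnot(inherits(feats, "cluster_features"))
  n <- nrow(feats$feature)
  if (config$k > n) stop_cfg("k exceeds the number of cluster features")
  km <- with_seed(config$seed,
                  stats::kmeans(feats$feature, config$k, nstart = 5,
                                iter.max = 50))
  distortion <- vapply(seq_len(config$k), function(g) {
    rows <- km$cluster == g
    if (!any(rows)) return(Inf)
    mean(rowSums(sweep(feats$feature[rows, , drop = FALSE], 2,
                       km$centers[g, ])^2))
  }, 0)
  thr <- config$distortion_threshold %||% stats::median(distortion)
  supernodes <- list()
  candidates <- list()
  for (g in seq_len(config$k)) {
    rows <- which(km$cluster == g)
    if (!length(rows)) next
    if (distortion[g] < thr && length(rows) >= 1) {
      supernodes[[length(supernodes) + 1]] <-
        merge_clusters(feats$clusters[rows])
    } else {
      candidates <- c(candidates, feats$clusters[rows])
    }
  }
  list(supernodes = supernodes, candidates = candidates,
       distortion = distortion, threshold = thr)
}

#' Absorb candidate crop clusters into supernodes
#'
#' Each candidate is assigned to the supernode with the smallest cluster
#' distance, provided that distance is below the assignment threshold.
#' After a pass, any supernode that grew by more than the growth threshold
#' triggers another iteration, in which each supernode is treated as a
#' single merged cluster. Terminates in at most `length(candidates)`
#' iterations.
#'
#' @param supernodes,candidates output of [form_supernodes()].
#' @param config a [clustering_config()].
#' @return list with the final `supernodes`, remaining `candidates` and
#'   the number of `iterations` run.
#' @export
absorb_candidates <- function(supernodes, candidates, config) {
  if (!length(supernodes)) stop_cfg("need at least one supernode")
  thr <- config$assignment_threshold %||% {
    cents <- do.call(rbind, lapply(supernodes, function(s) {
      colMeans(face_crops(s))
    }))
    if (nrow(cents) > 1) stats::median(stats::dist(cents)) / 2 else Inf
  }
  iter <- 0
  repeat {
    iter <- iter + 1
    if (!length(candidates)) break
    sizes0 <- vapply(supernodes, function(s) length(s$has_face), 0)
    absorbed <- rep(FALSE, length(candidates))
    for (ci in seq_along(candidates)) {
      # distance to a supernode: minimum over its member crop clusters in
      # the first pass; later passes treat the supernode as one cluster
      dists <- vapply(supernodes, function(s) {
        if (iter == 1 && !is.null(s$member_clusters)) {
          min(vapply(s$member_clusters, function(m) {
            suppressWarnings(cluster_distance(candidates[[ci]], m,
                                              config$K))
          }, 0))
        } else {
          suppressWarnings(cluster_distance(candidates[[ci]], s, config$K))
        }
      }, 0)
      best <- which.min(dists)
      if (dists[best] < thr) {
        supernodes[[best]] <- merge_clusters(list(supernodes[[best]],
                                                  candidates[[ci]]))
        absorbed[ci] <- TRUE
      }
    }
    candidates <- candidates[!absorbed]
    sizes1 <- vapply(supernodes, function(s) length(s$has_face), 0)
    growth <- (sizes1 - sizes0) / pmax(sizes0, 1)
    if (all(growth <= config$growth_threshold) ||
        iter > max(1, length(candidates))) {
      break
    }
  }
  list(supernodes = supernodes, candidates = candidates,
       iterations = iter, assignment_threshold = thr)
}

#' Fine-tune clusters into identity components via a pruned graph
#'
#' Builds the complete graph on cluster centroids with Euclidean edge
#' weights, removes edges above the pruning threshold and edges between
#' clusters whose frame spans overlap (the same character cannot be on
#' screen twice at once), and returns the connected components.
#'
#' @param clusters list of crop clusters (supernodes and leftover
#'   candidates).
#' @param prune_threshold edge-weight threshold; `NULL` uses half the
#'   median pairwise centroid distance.
#' @return list of components, each an integer vector of member cluster
#'   ids.
#' @export
finetune_graph <- function(clusters, prune_threshold = NULL) {
  stopifnot(length(clusters) >= 1)
  if (length(clusters) == 1) {
    return(list(clusters[[1]]$members %||% clusters[[1]]$cluster_id))
  }
  cents <- do.call(rbind, lapply(clusters, function(s) {
    colMeans(face_crops(s))
  }))
  D <- as.matrix(stats::dist(cents))
  thr <- prune_threshold %||% (stats::median(D[upper.tri(D)]) / 2)
  # a merged cluster carries the spans of all its members; two clusters
  # conflict when any pair of member spans overlaps in time (the same
  # character cannot be on screen twice at once)
  spans <- lapply(clusters, function(s) {
    s$member_spans %||% matrix(s$frame_span %||% c(NA, NA), 1)
  })
  spans_overlap <- function(a, b) {
    if (anyNA(a) || anyNA(b)) return(FALSE)
    for (i in seq_len(nrow(a))) {
      if (any(a[i, 1] < b[, 2] & b[, 1] < a[i, 2])) return(TRUE)
    }
    FALSE
  }
  n <- length(clusters)
  edges <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] <= thr && thr > 0 &&
          !spans_overlap(spans[[i]], spans[[j]])) {
        edges <- rbind(edges, c(i, j))
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(k) {
    unlist(lapply(clusters[comp == k], function(s) {
      s$members %||% s$cluster_id
    }))
  })
}

#' Purity and completeness of an identity assignment
#'
#' Purity is the crop-weighted mean over components of the largest planted
#' identity fraction; completeness is the weighted mean over planted
#' identities of the largest fraction captured by a single component.
#'
#' @param components list of integer vectors of cluster ids.
#' @param crops the `crop_cluster_set` with planted identities.
#' @return named vector `c(purity, completeness)`.
#' @export
purity_completeness <- function(components, crops) {
  id_of <- vapply(crops$clusters, `[[`, 0L, "identity")
  size_of <- vapply(crops$clusters, function(cl) length(cl$has_face), 0)
  cid <- vapply(crops$clusters, `[[`, 0L, "cluster_id")
  comp_of <- rep(NA_integer_, length(cid))
  for (k in seq_along(components)) {
    comp_of[match(components[[k]], cid)] <- k
  }
  ok <- !is.na(comp_of)
  tab <- tapply(size_of[ok], list(comp_of[ok], id_of[ok]), sum,
                default = 0)
  comp_sizes <- rowSums(tab)
  purity <- sum(apply(tab, 1, max)) / sum(comp_sizes)
  id_sizes <- colSums(tab)
  completeness <- sum(apply(tab, 2, max)) / sum(id_sizes)
  c(purity = purity, completeness = completeness)
}

#' Run the full supernode pipeline on a crop cluster set
#'
#' Feature averaging, k-means supernode formation, iterative candidate
#' absorption, and graph fine-tuning, in one call.
#'
#' @param crops a `crop_cluster_set`.
#' @param config a [clustering_config()].
#' @return list with `components`, `supernodes`, `iterations`, and (when
#'   planted identities exist) `purity` and `completeness`.
#' @export
identity_clustering <- function(crops, config = clustering_config()) {
  feats <- compute_cluster_features(crops)
  sn <- form_supernodes(feats, config)
  ab <- absorb_candidates(sn$supernodes, sn$candidates, config)
  comps <- finetune_graph(c(ab$supernodes, ab$candidates),
                          config$prune_threshold)
  out <- list(components = comps, supernodes = ab$supernodes,
              iterations = ab$iterations)
  if (!is.null(crops$clusters[[1]]$identity)) {
    pc <- purity_completeness(comps, crops)
    out$purity <- pc["purity"]
    out$completeness <- pc["completeness"]
  }
  out
}
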