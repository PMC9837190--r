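#' Generate planted crop-cluster embeddings
#'
#' Fixture generator for the identity-clustering stage: each planted
#' identity has a Gaussian centroid in embedding space; crop clusters are
#' drawn around their identity's centroid and individual crop embeddings
#' around the cluster mean. A configurable fraction of crops is flagged as
#' faceless (no usable facial features). Frame spans are laid out so that
#' clusters of the same identity never overlap in time.
#'
#' @param n_identities number of planted identities.
#' @param clusters_per_identity crop clusters per identity.
#' @param crops_per_cluster expected crops per cluster.
#' @param dim embedding dimension (128 matches a typical face-embedding net).
#' @param separation distance scale between identity centroids.
#' @param noise_sd within-cluster embedding noise (must be non-negative).
#' @param faceless_fraction fraction of crops flagged as lacking a face.
#' @param seed integer seed.
#' @return an object of class `crop_cluster_set`: a list of clusters, each
#'   with `cluster_id`, `embeddings` (crops x dim), `has_face`,
#'   `frame_span` (start, end) and hidden `identity`.
#' @export
generate_embeddings <- function(n_identities = 4, clusters_per_identity = 10,
                                crops_per_cluster = 12, dim = 128,
                                separation = 10, noise_sd = 1,
                                faceless_fraction = 0.2, seed = 1L) {
  if (n_identities < 1) stop_cfg("n_identities must be >= 1")
  if (noise_sd < 0) stop_cfg("noise_sd must be non-negative")
  with_seed(seed, {
    # distances are parameterised on the embedding scale, independent of
    # dim: identity centroids sit ~`separation` apart, crop embeddings
    # scatter ~`noise_sd` around their cluster centre
    centroids <- matrix(stats::rnorm(n_identities * dim, sd = separation /
                                       sqrt(2 * dim)), n_identities)
    clusters <- list()
    cid <- 0L
    span_clock <- rep(0, n_identities)
    order_ids <- rep(seq_len(n_identities), clusters_per_identity)
    for (id in order_ids) {
      cid <- cid + 1L
      n_crop <- max(2L, stats::rpois(1, crops_per_cluster))
      centre <- centroids[id, ] +
        stats::rnorm(dim, sd = noise_sd / (2 * sqrt(dim)))
      emb <- matrix(stats::rnorm(n_crop * dim, sd = noise_sd / sqrt(dim)),
                    n_crop) +
        matrix(centre, n_crop, dim, byrow = TRUE)
      has_face <- stats::runif(n_crop) >= faceless_fraction
      span <- c(span_clock[id], span_clock[id] + n_crop / 7.5)
      span_clock[id] <- span[2] + 5
      clusters[[cid]] <- list(cluster_id = cid, embeddings = emb,
                              has_face = has_face, frame_span = span,
                              identity = id)
    }
    structure(list(clusters = clusters, dim = dim,
                   n_identities = n_identities, noise_sd = noise_sd),
              class = "crop_cluster_set")
  })
}

#' @export
#' @method print crop_cluster_set
print.crop_cluster_set <- function(x, ...) {
  cat("crop_cluster_set:", length(x$clusters), "crop clusters,",
      x$n_identities, "planted identities, dim", x$dim, "\n")
  invisible(x)
}
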