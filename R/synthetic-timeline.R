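#' Configuration for a synthetic character timeline
#'
#' Describes the stimulus statistics that the timeline generator emulates: a
#' continuous episode (default 42 min) carved into scenes and cuts, with a
#' small cast whose members are each on screen for a modest fraction of
#' frames (characters are sparse: every character is absent most of the
#' time), plus dialogue intervals that produce visually ambiguous frames.
#'
#' @param n_characters number of decoded characters.
#' @param duration_s episode length in seconds.
#' @param frame_rate_hz label frame rate; 7.5 Hz corresponds to 30 fps
#'   downsampled by a factor of 4.
#' @param prevalence per-character target fraction of frames present
#'   (recycled to `n_characters`).
#' @param cooccurrence optional matrix of target conditional probabilities
#'   `P(i present | j present)` with unit diagonal. When `NULL` a mild
#'   positive association (lift 1.5 over independence) is used.
#' @param mean_scene_s mean scene length in seconds; scene character sets are
#'   resampled per scene.
#' @param scene_shape Gamma shape for scene durations (larger = more regular).
#' @param mean_cut_s mean cut length in seconds within a scene.
#' @param dialogue_rate_per_min expected number of dialogue (shot/reverse-shot)
#'   intervals per minute; these drive DNK labels downstream.
#' @param dialogue_len_s maximum length of one dialogue interval.
#' @param alt_block_s shot length during a dialogue alternation.
#' @param size_shape two Beta shape parameters for on-screen character size
#'   (scaled to `[0, 0.5]`, i.e. at most half the frame).
#' @return an object of class `timeline_config`.
#' @export
timeline_config <- function(n_characters = 4,
                            duration_s = 2520,
                            frame_rate_hz = 7.5,
                            prevalence = c(0.18, 0.13, 0.11, 0.08),
                            cooccurrence = NULL,
                            mean_scene_s = 4,
                            scene_shape = 6,
                            mean_cut_s = 2.5,
                            dialogue_rate_per_min = 1.2,
                            dialogue_len_s = 4,
                            alt_block_s = 1,
                            size_shape = c(2, 4)) {
  if (duration_s <= 0) stop_cfg("duration_s must be positive")
  if (frame_rate_hz <= 0) stop_cfg("frame_rate_hz must be positive")
  if (n_characters < 1) stop_cfg("need at least one character")
  prevalence <- rep_len(prevalence, n_characters)
  if (any(prevalence < 0 | prevalence > 1)) {
    stop_cfg("prevalence must lie in [0, 1]")
  }
  if (!is.null(cooccurrence)) {
    cooccurrence <- as.matrix(cooccurrence)
    if (!all(dim(cooccurrence) == n_characters)) {
      stop_cfg("cooccurrence must be ", n_characters, " x ", n_characters)
    }
    if (any(cooccurrence < 0 | cooccurrence > 1)) {
      stop_cfg("cooccurrence entries must lie in [0, 1]")
    }
    if (any(abs(diag(cooccurrence) - 1) > 1e-12)) {
      stop_cfg("cooccurrence must have unit diagonal")
    }
  }
  structure(list(
    n_characters = n_characters, duration_s = duration_s,
    frame_rate_hz = frame_rate_hz, prevalence = prevalence,
    cooccurrence = cooccurrence, mean_scene_s = mean_scene_s,
    scene_shape = scene_shape, mean_cut_s = mean_cut_s,
    dialogue_rate_per_min = dialogue_rate_per_min,
    dialogue_len_s = dialogue_len_s, alt_block_s = alt_block_s,
    size_shape = size_shape
  ), class = "timeline_config")
}

# Joint distribution over character subsets matching per-character marginals
# and pairwise joint-presence targets, by iterative proportional fitting on
# the 2^C subset states. Characters with zero prevalence get zero mass.
fit_subset_distribution <- function(q, p_joint, max_iter = 400, tol = 1e-10) {
  C <- length(q)
  states <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), C)))
  colnames(states) <- NULL
  pi <- rep(1 / nrow(states), nrow(states))
  zero <- which(q <= 0)
  if (length(zero)) {
    pi[rowSums(states[, zero, drop = FALSE]) > 0] <- 0
    pi <- pi / sum(pi)
  }
  active <- setdiff(seq_len(C), zero)
  pairs <- if (length(active) >= 2) utils::combn(active, 2) else NULL
  rescale <- function(pi, mask, target) {
    tot <- sum(pi[mask])
    if (tot > 0 && target >= 0) pi[mask] <- pi[mask] * (target / tot)
    pi
  }
  for (it in seq_len(max_iter)) {
    old <- pi
    for (i in active) {
      m <- states[, i]
      pi <- rescale(pi, m, q[i])
      pi <- rescale(pi, !m, 1 - q[i])
    }
    if (!is.null(pairs)) {
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1, k]; j <- pairs[2, k]
        p11 <- min(p_joint[i, j], q[i], q[j])
        p11 <- max(p11, q[i] + q[j] - 1, 0)
        pi <- rescale(pi, states[, i] & states[, j], p11)
        pi <- rescale(pi, states[, i] & !states[, j], q[i] - p11)
        pi <- rescale(pi, !states[, i] & states[, j], q[j] - p11)
        pi <- rescale(pi, !states[, i] & !states[, j], 1 - q[i] - q[j] + p11)
      }
    }
    pi <- pi / sum(pi)
    if (max(abs(pi - old)) < tol) break
  }
  # achieved pairwise conditionals P(i | j)
  cond <- diag(1, C)
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      if (i == j) next
      qj <- sum(pi[states[, j]])
      cond[i, j] <- if (qj > 0) sum(pi[states[, i] & states[, j]]) / qj else NA_real_
    }
  }
  marg <- vapply(seq_len(C), function(i) sum(pi[states[, i]]), 0)
  list(states = states, pmf = pi, conditional = cond, marginal = marg)
}

default_joint_presence <- function(q, lift = 1.5) {
  C <- length(q)
  p <- outer(q, q) * lift
  lim <- outer(q, q, pmin) * 0.9
  p <- pmin(p, lim)
  diag(p) <- q
  p
}

#' Generate a synthetic character timeline
#'
#' Builds a scene-first timeline: scene durations are Gamma distributed,
#' each scene receives a character subset drawn from a joint subset
#' distribution fitted (by iterative proportional fitting) to the configured
#' prevalences and pairwise co-occurrence targets, and subsets are allocated
#' to scenes by a proportional quota schedule (randomly permuted) so the
#' planted conditional probabilities are directly recoverable. Scenes are
#' subdivided into cuts; on-screen character size is resampled per cut.
#' Dialogue intervals alternate single-character shots inside multi-character
#' scenes; the temporarily off-screen dialogue partner is the source of DNK
#' labels downstream.
#'
#' @param config a [timeline_config()].
#' @param seed integer seed; the output is deterministic given the seed.
#' @return an object of class `character_timeline` with elements `frames`
#'   (frame index and time), `occupancy` and `size` (frames x characters),
#'   `cuts`, `scenes`, `scene_chars`, `dialogue` (ambiguity intervals with a
#'   `chars` list-column) and `planted` (the fitted subset distribution and
#'   its conditional co-occurrence matrix).
#' @export
generate_character_timeline <- function(config, seed = 1L) {
  stopifnot(inherits(config, "timeline_config"))
  with_seed(seed, {
    C <- config$n_characters
    q <- config$prevalence
    p_joint <- if (is.null(config$cooccurrence)) {
      default_joint_presence(q)
    } else {
      # symmetrise the implied joint: P(i|j) q_j and P(j|i) q_i must agree
      (config$cooccurrence * rep(q, each = C) +
        t(config$cooccurrence) * q) / 2
    }
    dist <- fit_subset_distribution(q, p_joint)

    n_frames <- round(config$duration_s * config$frame_rate_hz)
    frame_t <- (seq_len(n_frames) - 1) / config$frame_rate_hz
    frames <- data.frame(frame_idx = seq_len(n_frames) - 1L, time_s = frame_t)

    # scenes: Gamma durations tiling the episode
    mean_s <- config$mean_scene_s
    n_guess <- ceiling(config$duration_s / mean_s * 1.6) + 8
    dur <- stats::rgamma(n_guess, shape = config$scene_shape,
                         scale = mean_s / config$scene_shape)
    dur <- pmax(dur, 0.8)
    ends <- cumsum(dur)
    n_sc <- which(ends >= config$duration_s)[1]
    if (is.na(n_sc)) n_sc <- n_guess
    dur <- dur[seq_len(n_sc)]
    ends <- cumsum(dur)
    ends[n_sc] <- config$duration_s
    starts <- c(0, ends[-n_sc])
    scenes <- data.frame(scene_id = seq_len(n_sc), start_s = starts,
                         end_s = ends)

    # duration-proportional quota allocation of subsets over scenes:
    # scene durations (largest first) are greedily assigned to the subset
    # type with the largest remaining duration deficit, so the
    # duration-weighted subset shares track the fitted distribution and
    # the planted conditional probabilities are recoverable
    target_dur <- dist$pmf / sum(dist$pmf) * sum(dur)
    live_types <- which(dist$pmf > 0)
    dur_alloc <- rep(0, length(dist$pmf))
    subset_idx <- integer(n_sc)
    for (s in order(dur, decreasing = TRUE)) {
      pick <- live_types[which.max(target_dur[live_types] -
                                     dur_alloc[live_types])]
      subset_idx[s] <- pick
      dur_alloc[pick] <- dur_alloc[pick] + dur[s]
    }
    scene_chars <- dist$states[subset_idx, , drop = FALSE]

    # cuts within scenes
    cut_list <- vector("list", n_sc)
    for (s in seq_len(n_sc)) {
      len <- ends[s] - starts[s]
      bounds <- 0
      while (bounds[length(bounds)] < len) {
        bounds <- c(bounds, bounds[length(bounds)] +
                      stats::rexp(1, 1 / config$mean_cut_s))
      }
      bounds[length(bounds)] <- len
      if (length(bounds) > 2 && diff(bounds)[length(bounds) - 1] < 0.4) {
        bounds <- bounds[-(length(bounds) - 1)]
      }
      cut_list[[s]] <- data.frame(start_s = starts[s] + bounds[-length(bounds)],
                                  end_s = starts[s] + bounds[-1],
                                  scene_id = s)
    }
    cuts <- do.call(rbind, cut_list)
    cuts <- data.frame(cut_id = seq_len(nrow(cuts)), cuts)

    # frame-level occupancy/size from scene subsets and per-cut sizes
    f_scene <- findInterval(frame_t, starts, rightmost.closed = TRUE)
    f_cut <- findInterval(frame_t, cuts$start_s, rightmost.closed = TRUE)
    occupancy <- scene_chars[f_scene, , drop = FALSE]
    size <- matrix(0, n_frames, C)
    cut_size <- matrix(0.5 * stats::rbeta(nrow(cuts) * C,
                                          config$size_shape[1],
                                          config$size_shape[2]),
                       nrow(cuts), C)
    size_full <- cut_size[f_cut, , drop = FALSE]
    size[occupancy] <- size_full[occupancy]

    # dialogue alternations in multi-character scenes
    n_dlg <- round(config$duration_s / 60 * config$dialogue_rate_per_min)
    cand <- which(rowSums(scene_chars) >= 2 &
                    dur >= 2 * config$alt_block_s)
    picked <- if (n_dlg > 0 && length(cand) > 0) {
      sample(cand, min(n_dlg, length(cand)))
    } else integer(0)
    dlg <- list()
    for (s in picked) {
      members <- which(scene_chars[s, ])
      len <- min(config$dialogue_len_s, dur[s])
      mid <- (starts[s] + ends[s]) / 2
      d0 <- max(starts[s], mid - len / 2)
      d1 <- min(ends[s], d0 + len)
      in_dlg <- which(frame_t >= d0 & frame_t < d1)
      if (!length(in_dlg)) next
      blk <- floor((frame_t[in_dlg] - d0) / config$alt_block_s)
      order_m <- sample(members)
      vis <- order_m[(blk %% length(members)) + 1]
      for (c in members) {
        off <- in_dlg[vis != c]
        occupancy[off, c] <- FALSE
        size[off, c] <- 0
      }
      dlg[[length(dlg) + 1]] <- list(start_s = d0, end_s = d1,
                                     chars = members)
    }
    dialogue <- if (length(dlg)) {
      data.frame(start_s = vapply(dlg, `[[`, 0, "start_s"),
                 end_s = vapply(dlg, `[[`, 0, "end_s"))
    } else {
      data.frame(start_s = numeric(0), end_s = numeric(0))
    }
    dialogue$chars <- lapply(dlg, `[[`, "chars")

    structure(list(
      frames = frames, occupancy = occupancy, size = size, cuts = cuts,
      scenes = scenes, scene_chars = scene_chars, dialogue = dialogue,
      config = config,
      planted = list(pmf = dist$pmf, states = dist$states,
                     cooccurrence = dist$conditional,
                     marginal = dist$marginal)
    ), class = "character_timeline")
  })
}

#' @export
#' @method print character_timeline
print.character_timeline <- function(x, ...) {
  cat("character_timeline:", nrow(x$frames), "frames,",
      ncol(x$occupancy), "characters,",
      nrow(x$cuts), "cuts,", nrow(x$scenes), "scenes\n")
  cat("  presence fractions:",
      paste(sprintf("%.3f", colMeans(x$occupancy)), collapse = " "), "\n")
  invisible(x)
}
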