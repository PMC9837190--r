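#' Specify a synthetic clip-recognition memory session
#'
#' The session presents short clips, half drawn from the watched episode
#' (targets) and half from an unwatched one (lures), each followed by a
#' response window in which the simulated participant reports whether the
#' clip was seen before. Subjective responses follow a two-parameter
#' confusion model (hit rate for targets, false-alarm rate for lures).
#' Clips marked "seen" carry an additive reinstatement drive: MTL-tagged
#' tuned units are driven toward the clip's characters during both the clip
#' and the response window.
#'
#' @param n_clips number of clips; the behavioural protocol ranges over
#'   100-300 clips (values outside that range give a warning, not an error).
#' @param clip_len_s clip length in seconds.
#' @param response_len_s response-window length following each clip.
#' @param hit_rate probability of responding "seen" to a target clip.
#' @param false_alarm_rate probability of responding "seen" to a lure clip.
#' @param reinstatement_gain strength of the reinstatement drive in units of
#'   the tuned gain excess (0 disables reinstatement; 1 drives a tuned MTL
#'   unit at half of its full-size visual response).
#' @return an object of class `memory_session_spec`.
#' @export
memory_session_spec <- function(n_clips = 150, clip_len_s = 5,
                                response_len_s = 3,
                                hit_rate = 0.7, false_alarm_rate = 0.2,
                                reinstatement_gain = 1) {
  if (n_clips < 100 || n_clips > 300) {
    warning("n_clips outside the usual 100-300 range", call. = FALSE)
  }
  stopifnot(clip_len_s > 0, response_len_s > 0,
            hit_rate >= 0, hit_rate <= 1,
            false_alarm_rate >= 0, false_alarm_rate <= 1,
            reinstatement_gain >= 0)
  structure(list(n_clips = as.integer(n_clips), clip_len_s = clip_len_s,
                 response_len_s = response_len_s, target_fraction = 0.5,
                 hit_rate = hit_rate, false_alarm_rate = false_alarm_rate,
                 reinstatement_gain = reinstatement_gain),
            class = "memory_session_spec")
}

#' Generate a synthetic memory-test session
#'
#' Exactly half of the clips are targets cut from `timeline`; lures come
#' from the disjoint `timeline_lure`. Spiking during a clip is driven by the
#' clip's visible characters through the same tuning model as movie viewing;
#' response windows are at baseline except for the reinstatement drive of
#' "seen" clips, which is restricted to MTL-tagged units.
#'
#' @param spec a [memory_session_spec()].
#' @param timeline the watched episode's `character_timeline` (target source).
#' @param timeline_lure a second, disjoint timeline supplying lure content.
#' @param pop a [population_spec()].
#' @param seed integer seed.
#' @return an object of class `memory_session`: `clips` (onsets, offsets,
#'   response windows, is_target, response_seen), per-clip per-character
#'   `presence_frac` and `max_size`, the session `spikes`, and `mtl_units`.
#' @export
generate_memory_session <- function(spec, timeline, timeline_lure, pop,
                                    seed = 1L) {
  stopifnot(inherits(spec, "memory_session_spec"),
            inherits(timeline, "character_timeline"),
            inherits(timeline_lure, "character_timeline"),
            inherits(pop, "population_spec"))
  with_seed(seed, {
    n <- spec$n_clips
    n_target <- floor(n / 2)
    is_target <- sample(rep(c(TRUE, FALSE), c(n_target, n - n_target)))
    trial_len <- spec$clip_len_s + spec$response_len_s
    onset <- (seq_len(n) - 1) * trial_len
    offset <- onset + spec$clip_len_s
    src <- ifelse(is_target, 1L, 2L)
    pick_src_onset <- function(tl) {
      stats::runif(1, 0, tl$config$duration_s - spec$clip_len_s)
    }
    src_onset <- vapply(src, function(s) {
      pick_src_onset(if (s == 1L) timeline else timeline_lure)
    }, 0)
    seen <- ifelse(is_target,
                   stats::runif(n) < spec$hit_rate,
                   stats::runif(n) < spec$false_alarm_rate)

    C <- pop$n_characters
    presence_frac <- matrix(0, n, C)
    max_size <- matrix(0, n, C)
    for (k in seq_len(n)) {
      tl <- if (src[k] == 1L) timeline else timeline_lure
      ft <- tl$frames$time_s
      rows <- which(ft >= src_onset[k] & ft < src_onset[k] + spec$clip_len_s)
      if (length(rows)) {
        presence_frac[k, ] <- colMeans(tl$occupancy[rows, , drop = FALSE])
        max_size[k, ] <- apply(tl$size[rows, , drop = FALSE], 2, max)
      }
    }

    # session spiking on the 100 ms epoch grid
    dur <- n * trial_len
    n_ep <- ceiling(dur * 10)
    t_mid <- (seq_len(n_ep) - 1) * 0.1 + 0.05
    trial <- pmin(floor(t_mid / trial_len) + 1L, n)
    in_clip <- (t_mid - onset[trial]) < spec$clip_len_s
    U <- nrow(pop$units)
    M <- matrix(1, n_ep, U)
    # visual drive during clip viewing, from the source timeline
    for (k in seq_len(n)) {
      eps <- which(trial == k & in_clip)
      if (!length(eps)) next
      tl <- if (src[k] == 1L) timeline else timeline_lure
      t_src <- src_onset[k] + (t_mid[eps] - onset[k])
      M[eps, ] <- tuning_multiplier(t_src, tl, pop)
    }
    # reinstatement drive for remembered clips, MTL units only
    mtl <- pop$units$region %in% pop$mtl_regions
    if (spec$reinstatement_gain > 0 && any(mtl)) {
      for (k in which(seen)) {
        eps <- which(trial == k)
        chars <- which(presence_frac[k, ] > 0.2)
        if (!length(eps) || !length(chars)) next
        drive <- rep(1, U)
        for (c in chars) {
          drive <- drive * (1 + spec$reinstatement_gain *
                              (pop$gains[, c] - 1) * 0.5)
        }
        drive[!mtl] <- 1
        M[eps, ] <- sweep(M[eps, , drop = FALSE], 2, drive, `*`)
      }
    }
    G <- region_gain_noise(n_ep, pop)
    rate <- sweep(M, 2, pop$units$baseline_hz, `*`) *
      G[, match(pop$units$region, colnames(G)), drop = FALSE]
    counts <- matrix(stats::rpois(length(rate), rate * 0.1), n_ep)
    spikes <- structure(list(
      spikes = spikes_from_counts(counts, (seq_len(n_ep) - 1) * 0.1, 0.1),
      units = pop$units, duration_s = dur), class = "spike_dataset")

    clips <- data.frame(
      clip_id = seq_len(n), onset_s = onset, offset_s = offset,
      response_onset_s = offset, response_offset_s = offset + spec$response_len_s,
      is_target = is_target, response_seen = seen,
      source_onset_s = src_onset)
    structure(list(clips = clips, presence_frac = presence_frac,
                   max_size = max_size, spikes = spikes,
                   mtl_units = which(mtl), spec = spec),
              class = "memory_session")
  })
}

#' @export
#' @method print memory_session
print.memory_session <- function(x, ...) {
  cat("memory_session:", nrow(x$clips), "clips (",
      sum(x$clips$is_target), "targets ),",
      sum(x$clips$response_seen), "marked seen\n")
  invisible(x)
}
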