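#' Decode character activations over a memory session
#'
#' Bins and resamples the session spikes, builds prediction windows on a
#' regular grid and returns the fold-averaged activation trace together
#' with its time base.
#'
#' @param decoder a `pop_decoder` trained on movie viewing.
#' @param session a `memory_session`.
#' @param grid_hz prediction grid rate (windows are centred on this grid).
#' @param knock_units unit ids to zero out before decoding (e.g. all MTL
#'   units); positions are resolved against the decoder's unit order.
#' @return an `activation_trace` over the session.
#' @export
session_activations <- function(decoder, session, grid_hz = 7.5,
                                knock_units = NULL) {
  stopifnot(inherits(decoder, "pop_decoder"),
            inherits(session, "memory_session"))
  rates <- bin_and_resample(session$spikes)
  n_frames <- floor(session$spikes$duration_s * grid_hz)
  frames <- data.frame(frame_idx = seq_len(n_frames) - 1L,
                       time_s = (seq_len(n_frames) - 1) / grid_hz)
  labels <- structure(list(
    frames = frames,
    labels = matrix(LBL_NO, n_frames, decoder$n_char),
    n_characters = decoder$n_char), class = "frame_label_table")
  ws <- make_window_samples(rates, labels)
  pos <- if (is.null(knock_units)) NULL else {
    p <- match(knock_units, decoder$unit_ids)
    p[!is.na(p)]
  }
  predict(decoder, ws, knock_units = pos)
}

#' Character presence in a clip from frame labels
#'
#' A character is present in a clip when its occurrence fraction (share of
#' clip frames with a positive detection) reaches `prevalence_threshold`
#' and its maximum on-screen size reaches `size_threshold`.
#'
#' @param presence_frac clips x characters occurrence fractions.
#' @param max_size clips x characters maximum size fractions.
#' @param prevalence_threshold minimum occurrence fraction in `[0, 1]`.
#' @param size_threshold minimum of the per-clip maximum size in `[0, 1]`.
#' @return logical clips x characters matrix.
#' @export
clip_presence <- function(presence_frac, max_size = NULL,
                          prevalence_threshold = 0.2, size_threshold = 0) {
  stopifnot(prevalence_threshold >= 0, prevalence_threshold <= 1,
            size_threshold >= 0, size_threshold <= 1)
  pres <- presence_frac >= prevalence_threshold & presence_frac > 0
  if (prevalence_threshold == 0) pres <- presence_frac > 0
  if (!is.null(max_size) && size_threshold > 0) {
    pres <- pres & (max_size >= size_threshold)
  }
  pres
}

#' Summed activation per clip over a short analysis window
#'
#' Sums the activation trace per character over a 2 s window aligned to
#' the clip onset, the clip offset, or the 2 s immediately preceding the
#' response, with an inclusive-left / exclusive-right convention.
#'
#' @param trace an `activation_trace` over the session.
#' @param clips the session's clip table.
#' @param align `"onset"`, `"offset"` or `"pre_response"`.
#' @param window_s window length in seconds.
#' @return clips x characters matrix of summed activations.
#' @export
clip_activation_sum <- function(trace, clips, align = c("onset", "offset",
                                                        "pre_response"),
                                window_s = 2) {
  align <- match.arg(align)
  t0 <- switch(align,
               onset = clips$onset_s,
               offset = clips$offset_s,
               pre_response = clips$response_offset_s - window_s)
  out <- matrix(0, nrow(clips), ncol(trace$activation))
  for (k in seq_len(nrow(clips))) {
    rows <- trace$time_s >= t0[k] & trace$time_s < t0[k] + window_s
    out[k, ] <- colSums(trace$activation[rows, , drop = FALSE])
  }
  out
}

#' Per-clip maximum activation within a behavioural phase
#'
#' The per-character maximum of the activation trace within each clip's
#' viewing window or its response window; the input to
#' [coactivation_matrix()].
#'
#' @param trace an `activation_trace` over the session.
#' @param clips the session's clip table.
#' @param phase `"clip"` (viewing) or `"response"`.
#' @return clips x characters matrix of maximum activations.
#' @export
phase_max_activation <- function(trace, clips,
                                 phase = c("clip", "response")) {
  phase <- match.arg(phase)
  t0 <- if (phase == "clip") clips$onset_s else clips$response_onset_s
  t1 <- if (phase == "clip") clips$offset_s else clips$response_offset_s
  out <- matrix(0, nrow(clips), ncol(trace$activation))
  for (k in seq_len(nrow(clips))) {
    rows <- trace$time_s >= t0[k] & trace$time_s < t1[k]
    if (any(rows)) {
      out[k, ] <- apply(trace$activation[rows, , drop = FALSE], 2, max)
    }
  }
  out
}

#' GLM of clip activations on presence, memory and clip type
#'
#' Models the per-(clip, character) summed activation as a Gaussian
#' identity-link GLM of (1) whether the character is in the clip,
#' (2) whether the participant marked the clip as seen, and (3) whether
#' the clip is a target. Optional terms add the presence x seen
#' interaction and the character's appearance frequency (cumulative YES
#' fraction up to the clip's source timestamp).
#'
#' @param activation clips x characters summed activations.
#' @param clips clip table with `response_seen` and `is_target`.
#' @param presence logical clips x characters matrix from
#'   [clip_presence()].
#' @param interaction add the presence:seen interaction term.
#' @param appearance_freq optional clips x characters covariate.
#' @return object of class `glm_result`: coefficient table (estimate, SE,
#'   p), the fitted `glm`, and the model data.
#' @export
glm_activation <- function(activation, clips, presence,
                           interaction = FALSE, appearance_freq = NULL) {
  stopifnot(nrow(activation) == nrow(clips),
            all(dim(activation) == dim(presence)))
  if (nrow(clips) < 30) stop_cfg("need at least 30 clips for the GLM")
  C <- ncol(activation)
  d <- data.frame(
    activation = as.vector(activation),
    presence = as.numeric(as.vector(presence)),
    seen = as.numeric(rep(clips$response_seen, C)),
    target = as.numeric(rep(clips$is_target, C)))
  form <- activation ~ presence + seen + target
  if (interaction) form <- stats::update(form, . ~ . + presence:seen)
  if (!is.null(appearance_freq)) {
    d$appearance_freq <- as.vector(appearance_freq)
    form <- stats::update(form, . ~ . + appearance_freq)
  }
  const <- vapply(d[-1], function(x) stats::var(x) == 0, TRUE)
  if (any(const)) {
    stop_cfg("constant predictor column(s): ",
             paste(names(d[-1])[const], collapse = ","))
  }
  fit <- stats::glm(form, data = d, family = stats::gaussian())
  if (any(is.na(stats::coef(fit)))) {
    stop_cfg("rank-deficient design; collinear columns: ",
             paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                   collapse = ","))
  }
  s <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                    p = s[, 4], row.names = NULL)
  structure(list(coefficients = tab, fit = fit, data = d),
            class = "glm_result")
}

#' @export
#' @method print glm_result
print.glm_result <- function(x, ...) {
  cat("glm_result (Gaussian identity link):\n")
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Memory GLM before and after MTL knockout
#'
#' Fits the activation GLM on the intact session decoding and again after
#' zeroing all MTL units at the decoder input (re-evaluation, no
#' retraining). With no MTL units the knockout is the identity and the two
#' results coincide.
#'
#' @param decoder a `pop_decoder`.
#' @param session a `memory_session`.
#' @param mtl_regions region names counted as MTL.
#' @param prevalence_threshold passed to [clip_presence()].
#' @return list with `intact` and `knocked` `glm_result`s and the MTL unit
#'   ids.
#' @export
mtl_knockout_memory_glm <- function(decoder, session,
                                    mtl_regions = c("hippocampus",
                                                    "amygdala",
                                                    "entorhinal",
                                                    "parahippocampal"),
                                    prevalence_threshold = 0.2) {
  mtl_ids <- decoder$unit_ids[decoder$units$region %in% mtl_regions]
  if (!length(mtl_ids)) {
    warning("no MTL units; knockout is the identity", call. = FALSE)
  }
  pres <- clip_presence(session$presence_frac,
                        prevalence_threshold = prevalence_threshold)
  tr0 <- session_activations(decoder, session)
  a0 <- clip_activation_sum(tr0, session$clips)
  g0 <- glm_activation(a0, session$clips, pres)
  if (length(mtl_ids)) {
    tr1 <- session_activations(decoder, session, knock_units = mtl_ids)
    a1 <- clip_activation_sum(tr1, session$clips)
    g1 <- glm_activation(a1, session$clips, pres)
  } else {
    g1 <- g0
  }
  list(intact = g0, knocked = g1, mtl_units = mtl_ids)
}

#' Character association matrix from scene co-occurrence
#'
#' `P(i | j)` is the summed duration of scenes in which both characters are
#' present divided by the summed duration of scenes in which the
#' conditioned character `j` is present. The diagonal is 1 for any
#' character appearing in at least one scene; the column of a character
#' that never appears is undefined (NA).
#'
#' @param scene_chars logical scenes x characters membership matrix (or a
#'   `character_timeline`, whose scenes are used).
#' @param durations_s scene durations (ignored for a timeline input).
#' @return characters x characters matrix of conditional probabilities.
#' @export
association_matrix <- function(scene_chars, durations_s = NULL) {
  if (inherits(scene_chars, "character_timeline")) {
    tl <- scene_chars
    durations_s <- tl$scenes$end_s - tl$scenes$start_s
    scene_chars <- tl$scene_chars
  }
  scene_chars <- as.matrix(scene_chars)
  stopifnot(nrow(scene_chars) == length(durations_s))
  C <- ncol(scene_chars)
  A <- matrix(NA_real_, C, C)
  denom <- as.vector(crossprod(scene_chars, durations_s))
  for (j in seq_len(C)) {
    if (denom[j] == 0) next
    for (i in seq_len(C)) {
      both <- scene_chars[, i] & scene_chars[, j]
      A[i, j] <- sum(durations_s[both]) / denom[j]
    }
  }
  A
}

#' Conditional coactivation probabilities of model activations
#'
#' `P(i | j)` is the number of trials in which characters i and j are both
#' activated (maximum activation in the phase above `threshold`) divided
#' by the number of trials in which the conditioned character j is
#' activated; undefined (NA) when j is never activated.
#'
#' @param max_activation clips x characters per-phase maximum activations,
#'   or a logical activation matrix.
#' @param threshold activation threshold.
#' @return characters x characters conditional probability matrix.
#' @export
coactivation_matrix <- function(max_activation, threshold = 0.5) {
  act <- if (is.logical(max_activation)) max_activation else
    max_activation > threshold
  C <- ncol(act)
  M <- matrix(NA_real_, C, C)
  for (j in seq_len(C)) {
    nj <- sum(act[, j])
    if (nj == 0) next
    for (i in seq_len(C)) {
      M[i, j] <- sum(act[, i] & act[, j]) / nj
    }
  }
  M
}

#' Spearman correlation of association and coactivation matrices
#'
#' Rank correlation over the off-diagonal entries; diagonal values are
#' excluded and undefined pairs dropped pairwise.
#'
#' @param A association matrix.
#' @param Cm coactivation matrix of the same dimension.
#' @return list with `r`, `p` and `n` (number of pairs used).
#' @export
correlate_association_coactivation <- function(A, Cm) {
  stopifnot(all(dim(A) == dim(Cm)))
  off <- row(A) != col(A)
  a <- A[off]; b <- Cm[off]
  ok <- !is.na(a) & !is.na(b)
  ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Compare coactivation between response time and clip viewing
#'
#' Wilcoxon signed-rank test over the paired defined entries of the two
#' phase matrices; reports the median difference (response minus clip).
#'
#' @param cm_clip coactivation matrix during clip viewing.
#' @param cm_response coactivation matrix during response time.
#' @return list with `p`, `median_diff` and `n_pairs`.
#' @export
compare_phase_coactivation <- function(cm_clip, cm_response) {
  stopifnot(all(dim(cm_clip) == dim(cm_response)))
  a <- as.vector(cm_clip); b <- as.vector(cm_response)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 6) warning("fewer than 6 pairs; test underpowered",
                           call. = FALSE)
  d <- b[ok] - a[ok]
  p <- if (all(d == 0)) 1 else
    stats::wilcox.test(b[ok], a[ok], paired = TRUE, exact = FALSE)$p.value
  list(p = p, median_diff = stats::median(d), n_pairs = sum(ok))
}

#' Appearance-frequency covariate for the activation GLM
#'
#' For each clip and character, the cumulative fraction of movie frames up
#' to the clip's source timestamp in which the character was present.
#'
#' @param timeline the watched `character_timeline`.
#' @param clips the session clip table (uses `source_onset_s`).
#' @return clips x characters matrix in `[0, 1]`.
#' @export
appearance_frequency <- function(timeline, clips) {
  cum <- apply(timeline$occupancy, 2, cumsum)
  n_at <- findInterval(clips$source_onset_s, timeline$frames$time_s)
  n_at[n_at < 1] <- 1
  sweep(cum[n_at, , drop = FALSE], 1, n_at, `/`)
}
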