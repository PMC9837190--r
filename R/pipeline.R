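#' Simulate a movie-viewing recording and build its training windows
#'
#' Convenience wrapper running the full generative and preprocessing
#' pipeline: timeline, Poisson spiking, low-rate unit filtering, artifact
#' screening, binning/resampling and window construction.
#'
#' @param config a [timeline_config()].
#' @param pop a [population_spec()].
#' @param seed master seed (spiking uses `seed + 1`).
#' @param artifact_screen run [detect_artifact_bins()] and propagate the
#'   mask.
#' @return list with `timeline`, `spikes`, `rates`, `labels`, `windows`.
#' @export
simulate_study <- function(config = timeline_config(),
                           pop = population_spec(), seed = 1L,
                           artifact_screen = TRUE) {
  tl <- generate_character_timeline(config, seed)
  sp <- simulate_spikes(tl, pop, seed + 1)
  sp <- filter_low_rate_units(sp)
  mask <- if (artifact_screen) detect_artifact_bins(sp) else NULL
  rates <- bin_and_resample(sp, artifact_mask = mask)
  labels <- build_frame_labels(tl)
  ws <- make_window_samples(rates, labels)
  list(timeline = tl, spikes = sp, rates = rates, labels = labels,
       windows = ws)
}
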