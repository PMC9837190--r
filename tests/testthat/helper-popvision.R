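# Shared small fixtures, built once per test run.

# A short recording with strong tuning: cheap to simulate, decodable by a
# tiny network in a couple of epochs.
tiny_pop <- function(seed = 1, gain = 4, rho = 0) {
  population_spec(
    n_characters = 4,
    regions = c("occipital", "hippocampus"),
    units_per_region = c(8, 4), electrodes_per_region = 4,
    baseline_hz = c(2, 6), gain = gain, tuned_fraction = 1,
    rho = rho, seed = seed)
}

tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(
        timeline_config(duration_s = 300, prevalence = 0.2),
        tiny_pop(), seed = 1, artifact_screen = FALSE)
    }
    cache
  }
})

tiny_decoder <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- tiny_study()
      cache <<- fit_decoder(st$windows, "lstm", hidden = 8, fc_dim = 8,
                            epochs = 2, lr = 2e-3, fold_subset = 1,
                            train_max = 800, val_max = 200, test_max = 200,
                            seed = 1)
    }
    cache
  }
})

# A hand-built crop cluster for distance tests: scalar embeddings given as
# one-column matrices.
scalar_cluster <- function(values, id = 1L, faces = TRUE) {
  list(cluster_id = id,
       embeddings = matrix(values, ncol = 1),
       has_face = rep_len(faces, length(values)),
       frame_span = c(0, 1), identity = 1L)
}
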