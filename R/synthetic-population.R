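#' Specify a synthetic neural population
#'
#' Units are organised by brain region, hemisphere and microwire electrode
#' (8 electrodes per region by default). Each unit has a baseline Poisson
#' rate and one multiplicative gain per character; a gain of 1 means the
#' unit is untuned to that character. Tuning emulates a population-level
#' "footprint": a discriminative activity pattern present when a character
#' is on screen, with the drive scaled by the character's on-screen size.
#'
#' @param n_characters number of characters units can be tuned to.
#' @param regions character vector of region names.
#' @param units_per_region units recorded per region (recycled).
#' @param electrodes_per_region microwires per region; units are assigned to
#'   electrodes round-robin.
#' @param baseline_hz range (min, max) of uniform baseline rates in Hz.
#' @param gain multiplicative rate gain of a tuned unit at reference
#'   character size.
#' @param tuned_fraction fraction of units per region that are tuned; tuned
#'   units are assigned characters round-robin. Ignored when `gains` given.
#' @param gains optional explicit units x characters gain matrix.
#' @param latency_s response latency of the tuning drive, seconds.
#' @param rho within-region correlation strength in `[0, 1]`, implemented as
#'   a shared multiplicative log-normal gain per region per 100 ms epoch
#'   (log-sd `rho`, unit mean).
#' @param mtl_regions region names treated as medial temporal lobe for
#'   memory reinstatement.
#' @param size_ref reference on-screen size at which a tuned unit expresses
#'   exactly `gain`; drive scales linearly in size.
#' @param seed seed for the randomly drawn baselines.
#' @return an object of class `population_spec` with a `units` data frame
#'   and a `gains` matrix.
#' @export
population_spec <- function(n_characters = 4,
                            regions = c("occipital", "superior_temporal",
                                        "parahippocampal", "hippocampus",
                                        "amygdala"),
                            units_per_region = 8,
                            electrodes_per_region = 8,
                            baseline_hz = c(2, 8),
                            gain = 3,
                            tuned_fraction = 0.5,
                            gains = NULL,
                            latency_s = 0.15,
                            rho = 0,
                            mtl_regions = c("hippocampus", "amygdala",
                                            "entorhinal", "parahippocampal"),
                            size_ref = 1 / 6,
                            seed = 1L) {
  if (rho < 0 || rho > 1) stop_cfg("rho must lie in [0, 1]")
  if (any(baseline_hz < 0)) stop_cfg("baseline rates must be non-negative")
  units_per_region <- rep_len(units_per_region, length(regions))
  with_seed(seed, {
    n_units <- sum(units_per_region)
    region <- rep(regions, units_per_region)
    electrode <- unlist(lapply(units_per_region, function(n) {
      ((seq_len(n) - 1) %% electrodes_per_region) + 1L
    }))
    hemi <- rep(rep_len(c("L", "R"), length(regions)), units_per_region)
    baseline <- stats::runif(n_units, baseline_hz[1], baseline_hz[2])
    if (is.null(gains)) {
      gains <- matrix(1, n_units, n_characters)
      for (r in regions) {
        idx <- which(region == r)
        n_tuned <- round(tuned_fraction * length(idx))
        if (n_tuned > 0) {
          tuned <- idx[seq_len(n_tuned)]
          chars <- ((seq_along(tuned) - 1) %% n_characters) + 1L
          gains[cbind(tuned, chars)] <- gain
        }
      }
    } else {
      gains <- as.matrix(gains)
      stopifnot(nrow(gains) == n_units, ncol(gains) == n_characters)
    }
    if (any(gains < 0)) stop_cfg("gains must be non-negative")
    units <- data.frame(
      unit_id = seq_len(n_units), region = region, hemisphere = hemi,
      electrode_id = electrode, baseline_hz = baseline,
      latency_s = rep(latency_s, n_units),
      stringsAsFactors = FALSE
    )
    structure(list(units = units, gains = gains, rho = rho,
                   n_characters = n_characters,
                   electrodes_per_region = electrodes_per_region,
                   mtl_regions = mtl_regions, size_ref = size_ref),
              class = "population_spec")
  })
}

# Per-epoch tuning multiplier for every unit given frame-level occupancy and
# size. `w` is size / size_ref (0 when absent), evaluated latency-shifted.
tuning_multiplier <- function(t_epoch, timeline, pop) {
  U <- nrow(pop$units)
  C <- pop$n_characters
  M <- matrix(1, length(t_epoch), U)
  for (lat in unique(pop$units$latency_s)) {
    u_idx <- which(pop$units$latency_s == lat)
    ft <- t_epoch - lat
    fi <- floor(ft * timeline$config$frame_rate_hz) + 1L
    fi[fi < 1L] <- 1L
    fi[fi > nrow(timeline$frames)] <- nrow(timeline$frames)
    w <- (timeline$size[fi, , drop = FALSE] / pop$size_ref) *
      timeline$occupancy[fi, , drop = FALSE]
    for (c in seq_len(C)) {
      M[, u_idx] <- M[, u_idx] *
        (1 + outer(w[, c], pop$gains[u_idx, c] - 1))
    }
  }
  M[M < 0] <- 0
  M
}

# Shared per-region multiplicative gain noise (unit mean log-normal).
region_gain_noise <- function(n_epochs, pop) {
  regions <- unique(pop$units$region)
  G <- matrix(1, n_epochs, length(regions))
  colnames(G) <- regions
  if (pop$rho > 0) {
    z <- matrix(stats::rnorm(n_epochs * length(regions)), n_epochs)
    G[] <- exp(pop$rho * z - pop$rho^2 / 2)
  }
  G
}

#' Simulate population spike trains from a character timeline
#'
#' Each unit fires as an inhomogeneous Poisson process on a 100 ms epoch
#' grid: rate = baseline x character-tuning multiplier (latency-shifted,
#' scaled by on-screen size) x shared within-region log-normal gain noise.
#' Optional synchronous bursts can be injected as artifact fixtures.
#'
#' @param timeline a `character_timeline`.
#' @param pop a [population_spec()].
#' @param seed integer seed; output is deterministic given the seed.
#' @param inject_bursts optional vector of times (s); at each, every unit
#'   receives `burst_spikes` extra spikes within the containing 100 ms bin.
#' @param burst_spikes spikes added per unit per injected burst.
#' @return an object of class `spike_dataset`: `spikes` (unit_id, time_s),
#'   `units` metadata, and `duration_s`.
#' @export
simulate_spikes <- function(timeline, pop, seed = 1L, inject_bursts = NULL,
                            burst_spikes = 3L) {
  stopifnot(inherits(timeline, "character_timeline"),
            inherits(pop, "population_spec"))
  with_seed(seed, {
    dur <- timeline$config$duration_s
    n_ep <- ceiling(dur * 10)
    t0 <- (seq_len(n_ep) - 1) * 0.1
    M <- tuning_multiplier(t0 + 0.05, timeline, pop)
    G <- region_gain_noise(n_ep, pop)
    rate <- sweep(M, 2, pop$units$baseline_hz, `*`) *
      G[, match(pop$units$region, colnames(G)), drop = FALSE]
    counts <- matrix(stats::rpois(length(rate), rate * 0.1), n_ep)
    spikes <- spikes_from_counts(counts, t0, 0.1)
    if (!is.null(inject_bursts)) {
      for (tb in inject_bursts) {
        ep <- floor(tb / 0.1) * 0.1
        extra <- data.frame(
          unit_id = rep(seq_len(nrow(pop$units)), each = burst_spikes),
          time_s = ep + stats::runif(burst_spikes * nrow(pop$units), 0, 0.1))
        spikes <- rbind(spikes, extra)
      }
      spikes <- spikes[order(spikes$unit_id, spikes$time_s), ]
      rownames(spikes) <- NULL
    }
    structure(list(spikes = spikes, units = pop$units, duration_s = dur),
              class = "spike_dataset")
  })
}

# Expand an epochs x units count matrix into a spike table with uniform
# spike times within each epoch.
spikes_from_counts <- function(counts, t0, width) {
  tot <- sum(counts)
  if (tot == 0) {
    return(data.frame(unit_id = integer(0), time_s = numeric(0)))
  }
  nz <- which(counts > 0, arr.ind = TRUE)
  k <- counts[nz]
  unit <- rep.int(nz[, 2], k)
  ep <- rep.int(nz[, 1], k)
  tt <- t0[ep] + stats::runif(tot, 0, width)
  ord <- order(unit, tt)
  data.frame(unit_id = as.integer(unit[ord]), time_s = tt[ord])
}

#' @export
#' @method print spike_dataset
print.spike_dataset <- function(x, ...) {
  cat("spike_dataset:", nrow(x$units), "units,", nrow(x$spikes),
      "spikes over", x$duration_s, "s\n")
  invisible(x)
}
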