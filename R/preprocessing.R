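#' Discard units with a mean firing rate below 0.05 Hz
#'
#' Units whose event count divided by the recording duration falls below
#' 0.05 Hz are removed; a unit at exactly 0.05 Hz is retained (the rule
#' discards rates strictly below threshold).
#'
#' @param spikes a `spike_dataset`.
#' @param duration_s recording duration; defaults to the dataset's own.
#' @param min_rate_hz rate threshold in Hz.
#' @return the filtered `spike_dataset`.
#' @export
filter_low_rate_units <- function(spikes, duration_s = spikes$duration_s,
                                  min_rate_hz = 0.05) {
  stopifnot(inherits(spikes, "spike_dataset"))
  if (duration_s <= 0) stop_cfg("duration_s must be positive")
  if (nrow(spikes$units) == 0) return(spikes)
  counts <- tabulate(spikes$spikes$unit_id, nbins = max(spikes$units$unit_id))
  keep_ids <- spikes$units$unit_id[
    counts[spikes$units$unit_id] / duration_s >= min_rate_hz]
  spikes$units <- spikes$units[spikes$units$unit_id %in% keep_ids, ,
                               drop = FALSE]
  rownames(spikes$units) <- NULL
  spikes$spikes <- spikes$spikes[spikes$spikes$unit_id %in% keep_ids, ,
                                 drop = FALSE]
  rownames(spikes$spikes) <- NULL
  spikes
}

# Units x bins spike-count matrix on a half-open [t, t + width) grid.
bin_spike_counts <- function(spikes, bin_s, duration_s) {
  n_bins <- ceiling(duration_s / bin_s)
  unit_ids <- spikes$units$unit_id
  m <- matrix(0L, length(unit_ids), n_bins)
  rownames(m) <- unit_ids
  if (nrow(spikes$spikes)) {
    b <- floor(spikes$spikes$time_s / bin_s) + 1L
    ok <- b >= 1L & b <= n_bins
    u <- match(spikes$spikes$unit_id, unit_ids)
    tab <- table(factor(u[ok], levels = seq_along(unit_ids)),
                 factor(b[ok], levels = seq_len(n_bins)))
    m[] <- as.integer(tab)
  }
  m
}

#' Flag artifact bins with synchronous multi-region activity
#'
#' Operates on 100 ms binned counts. A bin is an artifact when the
#' population z-scored total count exceeds `z_pop` and at least
#' `min_regions` distinct regions are simultaneously above their own
#' per-region z threshold. This automates the study protocol's visual
#' inspection step with an explicit, reproducible two-threshold criterion.
#'
#' @param spikes a `spike_dataset`.
#' @param bin_s bin width in seconds (100 ms grid).
#' @param z_pop population z-score threshold.
#' @param min_regions minimum number of simultaneously elevated regions.
#' @return logical vector, one entry per 100 ms bin (`TRUE` = excluded),
#'   with attribute `bin_s`.
#' @export
detect_artifact_bins <- function(spikes, bin_s = 0.1, z_pop = 5,
                                 min_regions = 3) {
  stopifnot(inherits(spikes, "spike_dataset"))
  counts <- bin_spike_counts(spikes, bin_s, spikes$duration_s)
  n_bins <- ncol(counts)
  regions <- unique(spikes$units$region)
  if (length(regions) < 2) {
    warning("fewer than 2 regions; no artifact detection possible",
            call. = FALSE)
    return(structure(rep(FALSE, n_bins), bin_s = bin_s))
  }
  zscore <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  pop_z <- zscore(colSums(counts))
  region_hot <- vapply(regions, function(r) {
    rows <- spikes$units$region == r
    zscore(colSums(counts[rows, , drop = FALSE])) > z_pop
  }, logical(n_bins))
  mask <- pop_z > z_pop & rowSums(region_hot) >= min_regions
  structure(as.logical(mask), bin_s = bin_s)
}

#' Bin spikes and resample to a uniform rate signal
#'
#' Spikes are counted in 20 ms bins, converted to rates (count / bin width)
#' and linearly interpolated from the bin centres onto a uniform output grid
#' (30 Hz by default, so a 2 s window spans 60 samples; 15 Hz is available
#' via `out_hz`). An artifact mask on the 100 ms grid is carried over to the
#' output samples.
#'
#' @param spikes a `spike_dataset`.
#' @param bin_ms raw bin width in milliseconds.
#' @param out_hz output sample rate in Hz.
#' @param artifact_mask optional logical mask from [detect_artifact_bins()].
#' @return an object of class `rate_matrix`: `rates` (units x samples,
#'   spikes/s), `sample_hz`, `origin_s`, `unit_ids`, `times_s` and
#'   `excluded` (logical per sample).
#' @export
bin_and_resample <- function(spikes, bin_ms = 20, out_hz = 30,
                             artifact_mask = NULL) {
  stopifnot(inherits(spikes, "spike_dataset"))
  if (out_hz <= 0) stop_cfg("out_hz must be positive")
  bin_s <- bin_ms / 1000
  counts <- bin_spike_counts(spikes, bin_s, spikes$duration_s)
  rate_raw <- counts / bin_s
  centres <- (seq_len(ncol(counts)) - 0.5) * bin_s
  n_out <- floor(spikes$duration_s * out_hz)
  t_out <- (seq_len(n_out) - 1) / out_hz
  rates <- t(apply(rate_raw, 1, function(y) {
    stats::approx(centres, y, xout = t_out, rule = 2)$y
  }))
  if (nrow(counts) == 1) rates <- matrix(rates, nrow = 1)
  excluded <- rep(FALSE, n_out)
  if (!is.null(artifact_mask) && any(artifact_mask)) {
    mb <- attr(artifact_mask, "bin_s") %||% 0.1
    bin_idx <- floor(t_out / mb) + 1L
    bin_idx[bin_idx > length(artifact_mask)] <- length(artifact_mask)
    excluded <- artifact_mask[bin_idx]
  }
  structure(list(rates = rates, sample_hz = out_hz, origin_s = 0,
                 unit_ids = spikes$units$unit_id, units = spikes$units,
                 times_s = t_out, excluded = excluded),
            class = "rate_matrix")
}

#' @export
#' @method print rate_matrix
print.rate_matrix <- function(x, ...) {
  cat("rate_matrix:", nrow(x$rates), "units x", ncol(x$rates),
      "samples at", x$sample_hz, "Hz;", sum(x$excluded),
      "excluded samples\n")
  invisible(x)
}

#' Subset a rate matrix by unit
#' @param x a `rate_matrix`.
#' @param unit_ids unit ids to keep (original ids, order preserved).
#' @return the subset `rate_matrix`.
#' @export
subset_units <- function(x, unit_ids) {
  stopifnot(inherits(x, "rate_matrix"))
  keep <- x$unit_ids %in% unit_ids
  x$rates <- x$rates[keep, , drop = FALSE]
  x$units <- x$units[keep, , drop = FALSE]
  x$unit_ids <- x$unit_ids[keep]
  x
}
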