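#' Write a synthetic dataset to plain-text files
#'
#' Writes the standard file set consumed by the pipeline: spikes.csv
#' (unit_id, time_s), units.csv, frames.csv, labels.csv (long format, one
#' row per frame x character), cuts.csv, scenes.csv, optional clips.csv,
#' embeddings.json, config.yaml and a run manifest (seeds and counts) in
#' manifest.json.
#'
#' @param dir output directory (created if missing).
#' @param spikes a `spike_dataset`.
#' @param timeline a `character_timeline`.
#' @param labels a `frame_label_table`.
#' @param session optional `memory_session`.
#' @param embeddings optional `crop_cluster_set`.
#' @param seeds named list of the seeds used, logged in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dir, spikes, timeline, labels, session = NULL,
                          embeddings = NULL, seeds = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                        row.names = FALSE)
  wr(spikes$spikes, "spikes.csv")
  wr(spikes$units[, c("unit_id", "region", "hemisphere", "electrode_id",
                      "baseline_hz")], "units.csv")
  wr(timeline$frames, "frames.csv")
  lab <- data.frame(
    frame_idx = rep(timeline$frames$frame_idx, ncol(labels$labels)),
    character = rep(seq_len(ncol(labels$labels)),
                    each = nrow(labels$labels)),
    label = label_levels[as.vector(labels$labels)])
  wr(lab, "labels.csv")
  wr(timeline$cuts, "cuts.csv")
  sc <- timeline$scenes
  sc$characters <- apply(timeline$scene_chars, 1, function(r) {
    paste(which(r), collapse = ";")
  })
  wr(sc, "scenes.csv")
  if (!is.null(session)) {
    wr(session$clips[, c("clip_id", "onset_s", "offset_s", "is_target",
                         "response_seen")], "clips.csv")
  }
  if (!is.null(embeddings)) {
    jsonlite::write_json(lapply(embeddings$clusters, function(cl) {
      list(cluster_id = cl$cluster_id,
           embeddings = unname(split(cl$embeddings,
                                     row(cl$embeddings))),
           has_face = cl$has_face, frame_span = cl$frame_span,
           identity = cl$identity)
    }), file.path(dir, "embeddings.json"), auto_unbox = TRUE,
    digits = NA)
  }
  yaml::write_yaml(unclass(timeline$config), file.path(dir, "config.yaml"))
  jsonlite::write_json(list(
    seeds = seeds, n_units = nrow(spikes$units),
    n_spikes = nrow(spikes$spikes), n_frames = nrow(timeline$frames),
    n_cuts = nrow(timeline$cuts), n_scenes = nrow(timeline$scenes),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a spike dataset written by [write_dataset()]
#' @param dir dataset directory.
#' @param duration_s recording duration; inferred from the last spike when
#'   missing from the manifest.
#' @return a `spike_dataset`.
#' @export
read_spike_dataset <- function(dir, duration_s = NULL) {
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  units <- utils::read.csv(file.path(dir, "units.csv"))
  units$latency_s <- units$latency_s %||% 0
  structure(list(spikes = spikes, units = units,
                 duration_s = duration_s %||% ceiling(max(spikes$time_s))),
            class = "spike_dataset")
}

#' Read a crop cluster set from embeddings.json
#' @param path path to an embeddings.json file.
#' @return a `crop_cluster_set`.
#' @export
read_embeddings <- function(path) {
  raw <- jsonlite::read_json(path)
  clusters <- lapply(raw, function(cl) {
    emb <- do.call(rbind, lapply(cl$embeddings, unlist))
    list(cluster_id = cl$cluster_id, embeddings = emb,
         has_face = unlist(cl$has_face),
         frame_span = unlist(cl$frame_span),
         identity = cl$identity %||% NA_integer_)
  })
  structure(list(clusters = clusters, dim = ncol(clusters[[1]]$embeddings),
                 n_identities = length(unique(vapply(clusters, `[[`, 0L,
                                                     "identity")))),
            class = "crop_cluster_set")
}

#' Write a rate matrix as CSV with a JSON sidecar
#'
#' The matrix goes to `<prefix>.csv` (one row per unit, one column per
#' sample); sample rate, time origin, unit order and the excluded-sample
#' mask go to `<prefix>.json`.
#'
#' @param rates a `rate_matrix`.
#' @param prefix output path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_rate_matrix <- function(rates, prefix) {
  stopifnot(inherits(rates, "rate_matrix"))
  utils::write.table(rates$rates, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(
    sample_hz = rates$sample_hz, origin_s = rates$origin_s,
    unit_ids = rates$unit_ids, excluded = which(rates$excluded)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a rate matrix written by [write_rate_matrix()]
#' @param prefix path prefix used when writing.
#' @param units optional unit metadata data frame.
#' @return a `rate_matrix`.
#' @export
read_rate_matrix <- function(prefix, units = NULL) {
  m <- as.matrix(utils::read.table(paste0(prefix, ".csv"), sep = ","))
  dimnames(m) <- NULL
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  excluded <- rep(FALSE, ncol(m))
  excluded[as.integer(unlist(side$excluded))] <- TRUE
  structure(list(rates = m, sample_hz = side$sample_hz,
                 origin_s = side$origin_s,
                 unit_ids = as.integer(side$unit_ids), units = units,
                 times_s = side$origin_s +
                   (seq_len(ncol(m)) - 1) / side$sample_hz,
                 excluded = excluded),
            class = "rate_matrix")
}

#' Write a window-sample manifest
#'
#' Records the sample count, window geometry, dropped-frame count and an
#' optional fold plan as JSON.
#'
#' @param ws a `window_sample_set`.
#' @param path output path.
#' @param folds optional `fold_plan`.
#' @return `path`, invisibly.
#' @export
write_windows_manifest <- function(ws, path, folds = NULL) {
  stopifnot(inherits(ws, "window_sample_set"))
  out <- list(n_samples = length(ws$centre), steps = ws$steps,
              n_units = ws$n_units, n_dropped = ws$n_dropped)
  if (!is.null(folds)) {
    out$fold_plan <- list(n_folds = folds$n_folds, seed = folds$seed,
                          test = lapply(folds$folds, `[[`, "test"))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}
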