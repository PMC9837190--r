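#' Knockout evaluation of a unit group
#'
#' Zeroes the input columns of the given units and re-evaluates the
#' decoder's DNK-masked KLD loss on the evaluation set, averaged over the
#' fitted fold models. The change relative to the intact input (baseline
#' subtracted on the identical evaluation set) is reported per character,
#' together with the form normalized by the number of knocked units.
#'
#' @param decoder a `pop_decoder`.
#' @param windows the `window_sample_set` to evaluate on (by default the
#'   whole training dataset matches the original protocol).
#' @param units unit ids to knock out (must belong to the decoder input).
#' @param eval_idx sample indices evaluated (default all).
#' @param baseline optional precomputed result of [knockout_baseline()] to
#'   avoid re-evaluating the intact model for every group.
#' @param impute `"zero"` replaces knocked inputs with zeros (the default
#'   perturbation); `"mean"` substitutes each unit's mean rate, for
#'   sensitivity analysis.
#' @return object of class `knockout_result`: per-character `delta_kld`,
#'   `normalized` (delta / n units), `n_units`, and per-character
#'   baseline/knocked losses.
#' @export
knockout_eval <- function(decoder, windows, units, eval_idx = NULL,
                          baseline = NULL, impute = c("zero", "mean")) {
  stopifnot(inherits(decoder, "pop_decoder"))
  impute <- match.arg(impute)
  if (length(units) == 0) stop_cfg("unit group must be nonempty")
  pos <- match(units, decoder$unit_ids)
  if (anyNA(pos)) {
    stop_cfg("unknown unit id(s): ",
             paste(units[is.na(pos)], collapse = ","))
  }
  eval_idx <- eval_idx %||% seq_along(windows$centre)
  if (is.null(baseline)) {
    baseline <- knockout_baseline(decoder, windows, eval_idx)
  }
  vals <- if (impute == "mean") rowMeans(windows$rates$rates)[pos] else NULL
  y <- windows$labels[eval_idx, , drop = FALSE]
  knocked <- per_char_loss_folds(decoder, windows, eval_idx, pos, y, vals)
  delta <- knocked - baseline$loss
  structure(list(delta_kld = delta, normalized = delta / length(pos),
                 n_units = length(pos), baseline_loss = baseline$loss,
                 knocked_loss = knocked, eval_checksum = baseline$checksum),
            class = "knockout_result")
}

#' Baseline (intact-input) per-character loss for knockout analyses
#' @param decoder a `pop_decoder`.
#' @param windows evaluation `window_sample_set`.
#' @param eval_idx sample indices (default all).
#' @return list with per-character `loss` and an evaluation-set `checksum`
#'   asserting that region and electrode knockouts share the same samples.
#' @export
knockout_baseline <- function(decoder, windows, eval_idx = NULL) {
  eval_idx <- eval_idx %||% seq_along(windows$centre)
  y <- windows$labels[eval_idx, , drop = FALSE]
  loss <- per_char_loss_folds(decoder, windows, eval_idx, NULL, y)
  list(loss = loss, checksum = sum(as.numeric(eval_idx)^2) %% 1e9)
}

per_char_loss_folds <- function(decoder, windows, eval_idx, knock_pos, y,
                                knock_values = NULL) {
  acc <- 0
  for (net in decoder$fits) {
    P <- net_predict(net, windows, eval_idx, knock_units = knock_pos,
                     knock_values = knock_values)
    acc <- acc + colMeans(kld_per_character(P, y, decoder$n_char))
  }
  acc / length(decoder$fits)
}

#' Region or electrode knockout sweep
#'
#' Applies [knockout_eval()] to every region (or every electrode within
#' every region), reusing one baseline evaluation. Hemispheres are kept as
#' distinct targets at the region scope via the `by_hemisphere` flag.
#'
#' @param decoder a `pop_decoder`.
#' @param windows evaluation `window_sample_set`.
#' @param scope `"region"` or `"electrode"`.
#' @param eval_idx evaluation sample indices (default all).
#' @param by_hemisphere split region targets by hemisphere.
#' @return data frame with columns scope, region, target, character,
#'   delta_kld, n_units, normalized; the baseline is attached as an
#'   attribute.
#' @export
knockout_analysis <- function(decoder, windows,
                              scope = c("region", "electrode"),
                              eval_idx = NULL, by_hemisphere = FALSE) {
  scope <- match.arg(scope)
  eval_idx <- eval_idx %||% seq_along(windows$centre)
  units <- decoder$units
  base <- knockout_baseline(decoder, windows, eval_idx)
  key <- if (by_hemisphere && scope == "region") {
    paste(units$region, units$hemisphere, sep = "/")
  } else {
    units$region
  }
  groups <- if (scope == "region") {
    split(units$unit_id, key)
  } else {
    split(units$unit_id, paste(units$region, units$electrode_id, sep = ":"))
  }
  rows <- lapply(names(groups), function(g) {
    ko <- knockout_eval(decoder, windows, groups[[g]], eval_idx,
                        baseline = base)
    data.frame(scope = scope,
               region = sub("[:/].*$", "", g), target = g,
               character = seq_along(ko$delta_kld),
               delta_kld = ko$delta_kld, n_units = ko$n_units,
               normalized = ko$normalized)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- base
  out
}

#' Region synergy: the whole versus the sum of its parts
#'
#' For each (region, character), subtracts the sum of the un-normalized
#' electrode-knockout loss changes from the un-normalized region-knockout
#' loss change. Positive values indicate that the region as a whole carries
#' more information than its electrodes do individually. A Wilcoxon
#' signed-rank test of the collected values against zero is reported per
#' region.
#'
#' @param region_ko data frame from `knockout_analysis(scope = "region")`.
#' @param electrode_ko data frame from
#'   `knockout_analysis(scope = "electrode")`; must cover every electrode
#'   of each region and share the evaluation set with `region_ko`.
#' @return object of class `synergy_summary`: per (region, character)
#'   `values` and a per-region `tests` data frame.
#' @export
synergy_statistic <- function(region_ko, electrode_ko) {
  b1 <- attr(region_ko, "baseline")
  b2 <- attr(electrode_ko, "baseline")
  if (!is.null(b1) && !is.null(b2) &&
      !isTRUE(all.equal(b1$checksum, b2$checksum))) {
    stop_cfg("region and electrode knockouts used different evaluation sets")
  }
  rows <- list()
  for (r in unique(region_ko$region)) {
    reg <- region_ko[region_ko$region == r, ]
    ele <- electrode_ko[electrode_ko$region == r, ]
    if (!nrow(ele)) stop_cfg("missing electrode knockouts for region ", r)
    n_ele_units <- sum(ele$n_units[!duplicated(ele$target)])
    n_reg_units <- sum(reg$n_units[!duplicated(reg$target)])
    if (n_ele_units != n_reg_units) {
      stop_cfg("electrode knockouts do not cover region ", r)
    }
    for (c in unique(reg$character)) {
      reg_delta <- sum(reg$delta_kld[reg$character == c])
      ele_sum <- sum(ele$delta_kld[ele$character == c])
      rows[[length(rows) + 1]] <- data.frame(
        region = r, character = c, region_delta = reg_delta,
        electrode_sum = ele_sum, synergy = reg_delta - ele_sum)
    }
  }
  values <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(split(values, values$region), function(d) {
    p <- if (nrow(d) >= 2 && any(d$synergy != 0)) {
      stats::wilcox.test(d$synergy, exact = FALSE)$p.value
    } else NA_real_
    data.frame(region = d$region[1], median_synergy = stats::median(d$synergy),
               p_value = p, n = nrow(d))
  }))
  rownames(tests) <- NULL
  structure(list(values = values, tests = tests),
            class = "synergy_summary")
}

#' @export
#' @method print synergy_summary
print.synergy_summary <- function(x, ...) {
  cat("synergy_summary (region knockout minus electrode sum):\n")
  print(x$tests, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Retrain decoders on an important / remaining region split
#'
#' Trains two decoders from scratch on the same folds: one restricted to
#' units from the regions deemed important, one on the remaining units.
#' The split must be balanced (unit counts within `balance_tol` of each
#' other, as a fraction of the total). Per-character test F1 values are
#' compared with a Wilcoxon rank-sum test.
#'
#' @param rates the full `rate_matrix`.
#' @param labels the `frame_label_table` used for windowing.
#' @param important_regions character vector of region names.
#' @param balance_tol allowed |n1 - n2| as a fraction of the total.
#' @param folds optional shared `fold_plan`.
#' @param ... passed to [fit_decoder()] for both models.
#' @return list with both decoders, their per-character F1 vectors, and
#'   the rank-sum p-value.
#' @export
split_retrain <- function(rates, labels, important_regions,
                          balance_tol = 0.2, folds = NULL, ...) {
  stopifnot(inherits(rates, "rate_matrix"))
  in_imp <- rates$units$region %in% important_regions
  n1 <- sum(in_imp); n2 <- sum(!in_imp)
  if (n1 == 0 || n2 == 0 ||
      abs(n1 - n2) > balance_tol * (n1 + n2)) {
    stop_cfg("split is unbalanced (", n1, " vs ", n2,
             " units); regroup regions to satisfy the balance constraint")
  }
  ws1 <- make_window_samples(subset_units(rates, rates$unit_ids[in_imp]),
                             labels)
  ws2 <- make_window_samples(subset_units(rates, rates$unit_ids[!in_imp]),
                             labels)
  if (is.null(folds)) folds <- make_fold_plan(length(ws1$centre))
  d1 <- fit_decoder(ws1, folds = folds, ...)
  d2 <- fit_decoder(ws2, folds = folds, ...)
  f1_imp <- unlist(lapply(d1$metrics, function(m) m$per_character$f1))
  f1_rest <- unlist(lapply(d2$metrics, function(m) m$per_character$f1))
  test <- stats::wilcox.test(f1_imp, f1_rest, exact = FALSE)
  list(important = d1, rest = d2, f1_important = f1_imp,
       f1_rest = f1_rest, p_value = test$p.value)
}

#' Exact Clopper-Pearson binomial confidence interval, in percent
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return named vector: percent, ci_lo, ci_hi (all in percent).
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  ci <- stats::binom.test(k, n, conf.level = conf)$conf.int * 100
  c(percent = 100 * k / n, ci_lo = ci[1], ci_hi = ci[2])
}

#' Binomial summaries of normalized knockout losses
#'
#' Pools normalized knockout loss values per region and reports, for each
#' region, the count and percentage above `threshold` with an exact 95%
#' Clopper-Pearson confidence interval (in percent).
#'
#' @param values numeric vector of normalized delta-KLD values pooled
#'   across participants and characters.
#' @param regions region name per value.
#' @param threshold importance threshold on the normalized loss.
#' @return data frame with region, k, n, percent, ci_lo, ci_hi.
#' @export
summarize_importance <- function(values, regions, threshold = 0.5) {
  stopifnot(length(values) == length(regions))
  out <- lapply(split(values, regions), function(v) {
    n <- length(v)
    if (n == 0) return(NULL)
    k <- sum(v > threshold)
    ci <- stats::binom.test(k, n)$conf.int * 100
    data.frame(k = k, n = n, percent = 100 * k / n,
               ci_lo = ci[1], ci_hi = ci[2])
  })
  keep <- !vapply(out, is.null, TRUE)
  res <- do.call(rbind, out[keep])
  data.frame(region = names(out)[keep], res, row.names = NULL)
}
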