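# Internal helpers shared across the pipeline.

# Run `code` under a fixed RNG seed and restore the caller's RNG state,
# so every generator is deterministic without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_cfg <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Label codes used throughout: 1 = YES, 2 = NO, 3 = DNK.
LBL_YES <- 1L
LBL_NO <- 2L
LBL_DNK <- 3L
label_levels <- c("YES", "NO", "DNK")
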