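# Run code with a temporary RNG state so package functions are
# deterministic for a given seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic fan-out of one master seed into n distinct child seeds,
# all below 2^31. Used by the ensemble generator and the pipeline stages.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Named per-stage seed derivation for the pipeline: master seed draws a
# fixed-length table, stages index it by name.
PIPELINE_STAGES_SEEDED <- c("generate", "bootstrap", "cluster", "classify")

stage_seed <- function(master_seed, stage) {
  idx <- match(stage, PIPELINE_STAGES_SEEDED)
  stopifnot(!is.na(idx))
  derive_seeds(master_seed, length(PIPELINE_STAGES_SEEDED))[idx]
}
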