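# Seed hygiene: every generator runs under its own seed and restores the
# caller's RNG state, so fixed seed => bit-identical output regardless of
# what ran before.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stage seed from a global seed; kept under 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(genome = 11L, methylome = 101L, expression = 211L,
               cohort = 307L, atlas = 401L, other = 503L)
  off <- offsets[[stage]] %||% 701L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)
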