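# Internal helpers: classed errors and seed management.

pp_stop <- function(msg, class = "pp_validation_error") {
  stop(errorCondition(msg, class = c(class, "pp_error")))
}

is_count <- function(x, lo = 0) {
  is.numeric(x) & is.finite(x) & x >= lo & x == floor(x)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
eval_with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministically derive `n` independent substream seeds from one seed.
# All derived seeds stay below 2^31 (R integers are 32-bit).
derive_seeds <- function(seed, n) {
  eval_with_seed(seed, sample.int(2147483646L, n))
}
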