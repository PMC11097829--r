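## internal helpers shared across the package

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this, so results depend only on
# the seeds recorded in configs/calls, never on ambient RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Per-iteration seed stream: XOR of the base seed with the iteration index,
# kept in 32-bit signed range.
derive_seed <- function(seed, i) {
  s <- bitwXor(as.integer(seed), as.integer(i))
  s %% .Machine$integer.max
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

stop_ctx <- function(..., call. = FALSE) stop(..., call. = call.)

`%||%` <- function(a, b) if (is.null(a)) b else a
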