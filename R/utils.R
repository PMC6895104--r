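# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Ceiling to the next multiple of `step`, with a floor of one step.
# A value already on a step multiple (up to float slack) stays put.
round_up_to_step <- function(x, step) {
  stopifnot(step > 0)
  k <- ceiling(x / step - 1e-9)
  max(step, k * step)
}

# Clamp integer indices into [1, n].
clamp_idx <- function(i, n) pmin.int(pmax.int(i, 1L), n)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)
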