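# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

fold_angle <- function(theta) pmin(theta, 180 - theta)

`%||%` <- function(a, b) if (is.null(a)) b else a
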