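## Seed plumbing: every stochastic routine takes an explicit integer seed,
## sets it locally, and restores the caller's RNG state on exit, so library
## code never perturbs the user's stream.

.pushSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.popSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

## Derive a child seed from a master seed and an index, staying inside the
## 32-bit signed range R requires.
.deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483587)
}

## Evaluate an expression under a local seed.
.withSeed <- function(seed, expr) {
  old <- .pushSeed(seed)
  on.exit(.popSeed(old), add = TRUE)
  force(expr)
}
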