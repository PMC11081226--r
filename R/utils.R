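# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random stream. A NULL seed leaves the ambient stream in place.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

## Derive a child seed from a master seed and a counter, kept inside the
## 32-bit integer range R requires.
deriveSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(counter) * 9973) %%
               2147483647)
}

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
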