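#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the previous RNG state, so
#' sub-computations can be made reproducible without disturbing the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
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
  expr
}

# derive a stream-specific 31-bit sub-seed from a base seed
.subseed <- function(seed, ...) {
  parts <- c(seed, ...)
  x <- 0
  for (p in parts) x <- (x * 1000003 + as.numeric(p) %% 2147483647) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}
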