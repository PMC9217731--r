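# Independent, replayable RNG streams.
#
# Every source of randomness in a simulated run (per-worker minibatch
# sampling, per-worker compute delays, the server's push gate, the server's
# privacy noise) draws from its own stream so that changing how often one
# component draws never desynchronizes the others. A stream is a saved
# .Random.seed that is swapped in around each draw.

#' Create an independent RNG stream
#'
#' @param seed Integer seed (< 2^31) initialising the stream.
#' @return An object of class `rng_stream`.
#' @examples
#' s <- rng_stream(42)
#' draw_with(s, runif(2))
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  env$seed <- as.integer(seed)
  class(env) <- "rng_stream"
  env
}

#' Evaluate an expression using a stream's RNG state
#'
#' Swaps the stream's saved state into `.Random.seed`, evaluates `expr`,
#' saves the advanced state back into the stream, and restores whatever
#' state the caller had.
#'
#' @param stream An [rng_stream()].
#' @param expr Expression performing random draws.
#' @return The value of `expr`.
#' @export
draw_with <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# Deterministically derive a sub-seed from a master seed and integer tags.
# Stays below 2^31 - 1; exact in double arithmetic (all intermediates < 2^53).
derive_seed <- function(master, ...) {
  tags <- c(...)
  h <- as.numeric(master) %% 2147483647
  for (tag in tags) {
    h <- (h * 48271 + as.numeric(tag) + 1) %% 2147483647
  }
  as.integer(h)
}
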