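# Independent resumable RNG streams.  Each stochastic component of the
# simulator (image-noise synthesis, swimmer reorientation, stage position
# sensing) draws from its own stream so that enabling or disabling one
# source never perturbs the sequence seen by another; this is what makes
# "noisy run equals noise-free run bit-for-bit inside the ROI" testable.

#' Create an independent random-number stream
#'
#' A stream is a small mutable object holding a private `.Random.seed`
#' state.  Draws are made with [with_stream()], which swaps the stream's
#' state into the global RNG, evaluates an expression, and swaps it back,
#' so streams never interfere with each other or with user code.
#'
#' @param seed Integer seed for the stream.
#' @return An object of class `rng_stream`.
#' @keywords internal
#' @export
new_rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(abs(seed) %% .Machine$integer.max))
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(env) <- "rng_stream"
  env
}

#' Evaluate an expression using a stream's RNG state
#'
#' @param stream An [new_rng_stream()] object; its state is advanced.
#' @param expr Expression performing random draws.
#' @return The value of `expr`.
#' @keywords internal
#' @export
with_stream <- function(stream, expr) {
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
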