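# Seed fan-out: one user-facing seed is expanded into independent named
# substreams so that adding a new consumer of randomness never perturbs
# the draws seen by existing ones.

#' Derive a substream seed from a master seed and a tag
#'
#' Deterministically maps a `(seed, tag)` pair to an integer seed below
#' 2^31.  Used internally to give each randomness consumer (sensor noise,
#' sweep ordering, ...) its own stream.
#'
#' @param seed Integer master seed.
#' @param tag Character label of the consumer.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 65536 * 48271 + h * 7919 + 1) %% 2147483647)
}

#' Create an isolated random-number stream
#'
#' Returns a generator object whose draws are reproducible from `seed`
#' and independent of (and invisible to) the global R RNG state.
#'
#' @param seed Integer seed for this stream.
#' @return An environment with a `rnorm(n, sd)` function.
#' @export
rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) {
    assign(".Random.seed", old, globalenv())
  } else {
    rm(".Random.seed", envir = globalenv())
  }
  env$rnorm <- function(n, sd = 1) {
    if (n == 0L) return(numeric(0))
    keep <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    assign(".Random.seed", env$state, globalenv())
    x <- stats::rnorm(n, sd = sd)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(keep)) {
      assign(".Random.seed", keep, globalenv())
    } else {
      rm(".Random.seed", envir = globalenv())
    }
    x
  }
  class(env) <- "rng_stream"
  env
}
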