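#' @useDynLib electrofish, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Named RNG streams.
#
# A single root seed is split into independent named streams so that adding a
# new consumer of randomness (e.g. a logging sampler) never perturbs the draws
# seen by existing consumers.  Each stream owns a saved copy of R's Mersenne
# Twister state; drawing from a stream swaps its state into .Random.seed,
# evaluates, and swaps back.

#' Derive a sub-seed from a root seed and a stream name
#'
#' Hashes `name` with a 31-multiplier polynomial rolling hash and folds it
#' into `root_seed` modulo 2^31 - 1, giving a deterministic, documented
#' splitting scheme: the same (root seed, name) pair always yields the same
#' sub-seed, and distinct names give (with overwhelming probability) distinct
#' streams.
#'
#' @param root_seed Integer root seed.
#' @param name Character scalar naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "world")
#' derive_seed(42, "policy")
derive_seed <- function(root_seed, name) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.character(name), length(name) == 1L)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  as.integer((abs(root_seed) + h) %% m)
}

#' Create a named RNG stream
#'
#' @param root_seed Integer root seed for the run.
#' @param name Stream name (hashed into the sub-seed).
#' @return An environment of class `rng_stream`.
#' @export
rng_stream <- function(root_seed, name = "default") {
  e <- new.env(parent = emptyenv())
  e$seed <- derive_seed(root_seed, name)
  e$name <- name
  e$state <- NULL
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression using a stream's RNG state
#'
#' Swaps the stream state into the global RNG, evaluates `expr`, saves the
#' advanced state back into the stream, and restores the previous global
#' state, so surrounding code is unaffected.
#'
#' @param stream An [rng_stream()].
#' @param expr Expression drawing random numbers.
#' @return The value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(stream$state)) {
    set.seed(stream$seed, kind = "Mersenne-Twister")
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  val <- force(expr)
  stream$state <- get(".Random.seed", envir = globalenv())
  val
}
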