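# Seeded RNG streams. Each stream owns a private .Random.seed so that
# simulations and optimizer runs are bit-reproducible under a fixed seed
# and never disturb (or depend on) the caller's global RNG state.

#' Create an isolated RNG stream
#'
#' @param seed integer seed.
#' @return an environment of class `rng_stream`.
#' @export
new_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion")
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  class(e) <- "rng_stream"
  e
}

.with_stream <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Draws from an RNG stream
#'
#' Thin wrappers around the base generators, executed on the stream's
#' private state.
#'
#' @param rng `rng_stream`; `n` number of draws.
#' @name rng-draws
#' @export
rng_unif <- function(rng, n = 1) .with_stream(rng, stats::runif(n))

#' @rdname rng-draws
#' @export
rng_norm <- function(rng, n = 1) .with_stream(rng, stats::rnorm(n))

#' @rdname rng-draws
#' @export
rng_pois <- function(rng, lambda) .with_stream(rng, stats::rpois(1, lambda))

#' @rdname rng-draws
#' @param n_max sample one integer from `1:n_max`.
#' @export
rng_int <- function(rng, n_max) .with_stream(rng, sample.int(n_max, 1L))

#' @rdname rng-draws
#' @param x vector to permute or sample from; `size` sample size.
#' @export
rng_sample <- function(rng, x, size = length(x)) {
  .with_stream(rng, x[sample.int(length(x), size)])
}
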