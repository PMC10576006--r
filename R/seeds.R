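#' Deterministic per-stream seeds from a single run seed
#'
#' Every generator in the package draws its randomness from its own stream so
#' that adding a new generator to a pipeline never shifts the random numbers
#' seen by existing ones. Streams are identified by fixed integer indices
#' (see [noise_streams]) and the per-stream seed is derived by a documented
#' counter scheme: `(seed + 10007 * stream) mod (2^31 - 1)`.
#'
#' @param seed integer run seed (any non-negative integer below 2^31).
#' @param stream integer stream index, >= 0.
#' @return an integer seed for `set.seed()`.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0,
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  as.integer((as.double(seed) + 10007 * as.double(stream)) %% 2147483647)
}

#' Fixed stream indices for the synthetic-data generators
#'
#' @format named integer vector.
#' @export
noise_streams <- c(
  bli        = 1L,
  titration  = 2L,
  relaxation = 3L,
  massphot   = 4L,
  interface  = 5L,
  pipeline   = 6L
)

#' Gaussian noise specification
#'
#' @param sd standard deviation (response units, ppm, or fraction depending
#'   on the consumer); must be >= 0.
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0, seed = 1L) {
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("noise sd must be a single non-negative number")
  structure(list(kind = "gaussian", sd = as.double(sd), seed = as.integer(seed)),
            class = "noise_spec")
}
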