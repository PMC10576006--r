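#' Mixture component specification for the mass-event generator
#'
#' @param mean,sd component mean and sd, kD (sd > 0).
#' @param weight mixing fraction.
#' @return list of class `mixture_component_spec`.
#' @export
mixture_component <- function(mean, sd = 6, weight = 1) {
  if (sd <= 0) stop("component sd must be > 0")
  if (weight < 0) stop("component weight must be >= 0")
  structure(list(mean = mean, sd = sd, weight = weight),
            class = "mixture_component_spec")
}

#' Generate synthetic mass-photometry events from a Gaussian mixture
#'
#' Event counts per component are multinomial in the weights; masses are
#' Gaussian within each component. The default per-component sd of 6 kD
#' stands in for typical instrument mass resolution. Events are range
#' filtered only when `instrument_range` is supplied.
#'
#' @param components list of [mixture_component()]s; weights must sum to 1
#'   within 1e-9.
#' @param n_events number of events (> 0).
#' @param seed integer seed.
#' @param instrument_range optional `(low, high)` kD detection window;
#'   `NULL` (default) keeps all events.
#' @return an [event_list()].
#' @export
gen_mp_events <- function(components, n_events, seed = 1L,
                          instrument_range = NULL) {
  if (!length(components)) stop("component list is empty")
  if (n_events <= 0) stop("n_events must be > 0")
  w <- vapply(components, `[[`, 0, "weight")
  if (any(w < 0)) stop("component weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-9) stop("component weights must sum to 1")
  set.seed(stream_seed(seed, noise_streams[["massphot"]]))
  comp <- sample.int(length(components), n_events, replace = TRUE, prob = w)
  mu <- vapply(components, `[[`, 0, "mean")
  sg <- vapply(components, `[[`, 0, "sd")
  masses <- stats::rnorm(n_events, mu[comp], sg[comp])
  if (is.null(instrument_range)) instrument_range <- c(-Inf, Inf)
  event_list(masses, instrument_range)
}
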