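#' Generate a synthetic BLI sensorgram set
#'
#' Simulates one trace per analyte concentration from any of the three
#' kinetic forward models and adds i.i.d. Gaussian noise per point (additive,
#' response units). With `noise$sd = 0` the traces equal the forward model
#' exactly, so generator + [fit_global()] form a closed recovery loop.
#' Default phase lengths are 400 s association / 400 s dissociation with five
#' analyte concentrations, matching common BLI practice for micromolar-KD
#' interactions.
#'
#' @param model one of [kinetic_models()].
#' @param params named parameter list for the model (see [simulate_model()]).
#' @param concentrations analyte concentrations, molar (all > 0).
#' @param t_assoc,t_dissoc phase lengths, s (> 0).
#' @param dt sampling interval, s.
#' @param noise a [noise_spec()]; sd in response units.
#' @return a [sensorgram_set()].
#' @export
gen_bli_dataset <- function(model, params,
                            concentrations = c(0.2, 0.6, 1.9, 5.6, 15) * 1e-6,
                            t_assoc = 400, t_dissoc = 400, dt = 2,
                            noise = noise_spec(0.02)) {
  model <- match.arg(model, kinetic_models())
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (t_assoc <= 0 || t_dissoc <= 0) stop("phase lengths must be > 0")
  rates <- unlist(params)
  rate_keys <- grep("^(kon|koff|ka|kd)", names(rates))
  if (any(rates[rate_keys] < 0) ||
      any(rates[grep("^(kon|koff|ka1|kd1)", names(rates))] <= 0))
    stop("rate constants must be positive")
  times <- seq(0, t_assoc + t_dissoc, by = dt)
  set.seed(stream_seed(noise$seed, noise_streams[["bli"]]))
  traces <- lapply(concentrations, function(C) {
    r <- simulate_model(model, params, C, times, t_assoc)
    if (noise$sd > 0) r <- r + stats::rnorm(length(r), 0, noise$sd)
    data.frame(time_s = times, response = r)
  })
  sensorgram_set(traces, concentrations, t_assoc,
                 ligand_id = "immobilized_ligand", analyte_id = model)
}
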