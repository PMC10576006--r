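#' Closed-form 1:1 Langmuir sensorgram
#'
#' Association follows \eqn{R(t) = R_{eq}(1 - e^{-(k_{on}C + k_{off})t})} with
#' \eqn{R_{eq} = R_{max} C / (C + k_{off}/k_{on})}; dissociation decays
#' exponentially from the response at the end of association,
#' \eqn{R(t) = R(t_a) e^{-k_{off}(t - t_a)}}. No integration error.
#'
#' @param kon association rate constant, M^-1 s^-1 (> 0).
#' @param koff dissociation rate constant, s^-1 (> 0).
#' @param rmax maximal response, response units (> 0).
#' @param conc analyte concentration, molar (>= 0).
#' @param times numeric vector of time points, s.
#' @param t_assoc end of the association phase, s.
#' @return numeric vector of responses, one per time point.
#' @export
simulate_one_to_one <- function(kon, koff, rmax, conc, times, t_assoc) {
  if (any(c(kon, koff, rmax) <= 0)) stop("kon, koff and rmax must be > 0")
  if (conc < 0) stop("analyte concentration must be >= 0")
  kd <- koff / kon
  req <- rmax * conc / (conc + kd)
  kobs <- kon * conc + koff
  r <- ifelse(times <= t_assoc,
              req * (1 - exp(-kobs * times)),
              req * (1 - exp(-kobs * t_assoc)) * exp(-koff * (times - t_assoc)))
  as.double(r)
}

#' Supported kinetic model identifiers
#' @export
kinetic_models <- function() c("one_to_one", "heterogeneous_ligand", "bivalent_analyte")

.require_params <- function(params, keys, model) {
  missing <- setdiff(keys, names(params))
  if (length(missing))
    stop(sprintf("model '%s' requires parameter(s): %s",
                 model, paste(missing, collapse = ", ")))
}

#' Simulate a sensorgram trace under any supported binding scheme
#'
#' `one_to_one` uses the closed form of [simulate_one_to_one()].
#' `heterogeneous_ligand` (2:1) sums two independent 1:1 site classes with
#' parameters `kon1, koff1, rmax1, kon2, koff2, rmax2`.
#' `bivalent_analyte` (1:2) integrates the sequential two-site surface model
#' (`ka1` M^-1 s^-1, `kd1` s^-1, `ka2` RU^-1 s^-1, `kd2` s^-1, `rmax` RU):
#' \deqn{dR_1/dt = 2 k_{a1} C (R_{max} - R_1 - 2R_2) - k_{d1} R_1
#'       - k_{a2} R_1 (R_{max} - R_1 - 2R_2) + 2 k_{d2} R_2}
#' \deqn{dR_2/dt = k_{a2} R_1 (R_{max} - R_1 - 2R_2) - 2 k_{d2} R_2}
#' with signal \eqn{R_1 + R_2}, integrated by an adaptive Dormand-Prince 5(4)
#' scheme at relative tolerance 1e-10. The statistical factor 2 on the first
#' association step means the `ka2 = kd2 = 0` limit equals 1:1 kinetics with
#' `kon = 2*ka1`.
#'
#' @param model one of [kinetic_models()].
#' @param params named list/vector of model parameters (see Details).
#' @param conc analyte concentration, molar.
#' @param times time points, s.
#' @param t_assoc end of association phase, s.
#' @return numeric response vector.
#' @export
simulate_model <- function(model, params, conc, times, t_assoc) {
  params <- as.list(params)
  switch(model,
    one_to_one = {
      .require_params(params, c("kon", "koff", "rmax"), model)
      simulate_one_to_one(params$kon, params$koff, params$rmax,
                          conc, times, t_assoc)
    },
    heterogeneous_ligand = {
      .require_params(params, c("kon1", "koff1", "rmax1",
                                "kon2", "koff2", "rmax2"), model)
      r1 <- simulate_one_to_one(params$kon1, params$koff1, params$rmax1,
                                conc, times, t_assoc)
      r2 <- if (params$rmax2 > 0)
        simulate_one_to_one(params$kon2, params$koff2, params$rmax2,
                            conc, times, t_assoc)
      else rep(0, length(times))
      r1 + r2
    },
    bivalent_analyte = {
      .require_params(params, c("ka1", "kd1", "ka2", "kd2", "rmax"), model)
      if (conc < 0) stop("analyte concentration must be >= 0")
      if (params$ka1 <= 0 || params$kd1 <= 0 || params$rmax <= 0)
        stop("ka1, kd1 and rmax must be > 0")
      if (params$ka2 < 0 || params$kd2 < 0)
        stop("ka2 and kd2 must be >= 0")
      m <- .biv_ode_cpp(params$ka1, params$kd1, params$ka2, params$kd2,
                        params$rmax, conc, as.double(times), t_assoc,
                        1e-10, 1e-12)
      m[, 1] + m[, 2]
    },
    stop(sprintf("unknown kinetic model '%s'; supported: %s",
                 model, paste(kinetic_models(), collapse = ", ")))
  )
}

#' Bivalent-analyte species trajectories (singly and doubly bound)
#'
#' @inheritParams simulate_model
#' @return matrix with columns `R1` (AL) and `R2` (AL2).
#' @keywords internal
simulate_bivalent_species <- function(params, conc, times, t_assoc) {
  params <- as.list(params)
  m <- .biv_ode_cpp(params$ka1, params$kd1, params$ka2, params$kd2,
                    params$rmax, conc, as.double(times), t_assoc,
                    1e-10, 1e-12)
  colnames(m) <- c("R1", "R2")
  m
}
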