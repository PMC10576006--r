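#' Generate a synthetic 15N relaxation table from model-free parameters
#'
#' T1 = 1/R1, T2 = 1/R2 and hetNOE are computed from the Lipari-Szabo
#' forward model ([relaxation_rates()]) at the given field and overall
#' tumbling time, then perturbed by multiplicative Gaussian noise with
#' coefficient of variation `noise_cv` (applied independently to T1, T2 and
#' NOE). `noise_cv = 0` gives an exact forward table that round-trips through
#' [fit_model_free()].
#'
#' @param residues residue ids.
#' @param s2 order parameters, one per residue (or scalar), in `[0, 1]`.
#' @param tau_e_ps internal correlation times, ps (>= 0).
#' @param tau_c_ns overall correlation time, ns.
#' @param field 1H frequency, MHz (default 600).
#' @param noise_cv fractional multiplicative noise (default 0).
#' @param seed integer seed.
#' @return a [relaxation_table()].
#' @export
gen_relaxation_table <- function(residues, s2, tau_e_ps = 0, tau_c_ns,
                                 field = 600, noise_cv = 0, seed = 1L) {
  if (any(s2 < 0 | s2 > 1)) stop("S2 must lie in [0, 1]")
  if (any(tau_e_ps < 0)) stop("tau_e must be >= 0")
  if (field <= 0) stop("field must be > 0")
  n <- length(residues)
  s2 <- rep_len(s2, n)
  tau_e_ps <- rep_len(tau_e_ps, n)
  r <- relaxation_rates(s2, tau_c_ns, tau_e_ps, field)
  T1 <- 1 / r$R1
  T2 <- 1 / r$R2
  noe <- r$NOE
  if (noise_cv > 0) {
    set.seed(stream_seed(seed, noise_streams[["relaxation"]]))
    T1 <- T1 * (1 + stats::rnorm(n, 0, noise_cv))
    T2 <- T2 * (1 + stats::rnorm(n, 0, noise_cv))
    noe <- noe * (1 + stats::rnorm(n, 0, noise_cv))
  }
  relaxation_table(residues, T1, T2, noe, field)
}
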