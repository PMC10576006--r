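# Physical constants for the 15N amide relaxation forward model (SI units).
# rNH and the 15N CSA are the conventional values used in model-free work;
# they are parameters of relaxation_rates, not hard-wired truths.
.kB <- 1.380649e-23          # J/K
.hbar <- 1.054571817e-34     # J s
.gammaH <- 2.6752218744e8    # rad s^-1 T^-1
.gammaN <- -2.7116e7         # rad s^-1 T^-1 (negative)
.mu0_4pi <- 1e-7             # T^2 J^-1 m^3

#' Stokes-Einstein-Debye rotational correlation time
#'
#' \deqn{\tau_c = \frac{4\pi \eta r^3}{3 k_B T}} for a sphere of effective
#' hydrodynamic radius `r` in a solvent of viscosity `eta`. Scales linearly
#' in viscosity, as the cube of the radius and inversely with temperature.
#'
#' @param eta viscosity, mPa s (water at 25 C: 0.890).
#' @param temperature absolute temperature, K.
#' @param radius effective hydrodynamic radius, Angstrom. Vectorised.
#' @return correlation time tau_c in ns.
#' @export
sed_tau_c <- function(eta, temperature, radius) {
  if (any(c(eta, temperature, radius) <= 0))
    stop("eta, temperature and radius must be > 0")
  r_m <- radius * 1e-10
  tau_s <- 4 * pi * (eta * 1e-3) * r_m^3 / (3 * .kB * temperature)
  tau_s * 1e9
}

#' Lipari-Szabo model-free spectral density
#'
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2} +
#'   \frac{(1-S^2)\tau'}{1+(\omega\tau')^2}\right]},
#' \eqn{1/\tau' = 1/\tau_c + 1/\tau_e}: isotropic overall tumbling at
#' \eqn{\tau_c} with fast internal motion of amplitude \eqn{1-S^2} at
#' \eqn{\tau_e}.
#'
#' @param omega angular frequency, rad/s (vectorised).
#' @param s2 generalized order parameter in `[0, 1]`.
#' @param tau_c overall correlation time, s.
#' @param tau_e effective internal correlation time, s (>= 0; 0 collapses the
#'   internal term).
#' @return J(omega) in s/rad.
#' @export
spectral_density <- function(omega, s2, tau_c, tau_e = 0) {
  if (s2 < 0 || s2 > 1) stop("S2 must lie in [0, 1]")
  if (tau_c <= 0) stop("tau_c must be > 0")
  if (tau_e < 0) stop("tau_e must be >= 0")
  j <- s2 * tau_c / (1 + (omega * tau_c)^2)
  if (tau_e > 0 && s2 < 1) {
    tp <- 1 / (1 / tau_c + 1 / tau_e)
    j <- j + (1 - s2) * tp / (1 + (omega * tp)^2)
  }
  0.4 * j
}

#' 15N R1, R2 and heteronuclear NOE from model-free parameters
#'
#' Standard dipolar + CSA expressions for a backbone amide 15N at the given
#' 1H field, evaluated from [spectral_density()] at
#' \eqn{\{0, \omega_N, \omega_H - \omega_N, \omega_H, \omega_H + \omega_N\}}:
#' \deqn{R_1 = \tfrac{d^2}{4}[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = \tfrac{d^2}{8}[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H) + 6J(\omega_H+\omega_N)] + \tfrac{c^2}{6}[4J(0) +
#'   3J(\omega_N)] + R_{ex}}
#' \deqn{NOE = 1 + \tfrac{d^2}{4R_1}\tfrac{\gamma_H}{\gamma_N}
#'   [6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)]}
#' with \eqn{d = \mu_0 \hbar \gamma_H \gamma_N / (4\pi r_{NH}^3)} and
#' \eqn{c = \omega_N \Delta\sigma / \sqrt{3}}.
#'
#' @param s2,tau_c_ns,tau_e_ps model-free parameters (tau_c in ns, tau_e in
#'   ps); vectorised over residues when given equal-length vectors.
#' @param field 1H spectrometer frequency, MHz.
#' @param rex chemical-exchange contribution to R2, s^-1 (default 0).
#' @param rNH N-H bond length, Angstrom (default 1.02).
#' @param csa 15N CSA, ppm (default -160).
#' @return data.frame with columns `R1`, `R2`, `NOE` (s^-1, s^-1, unitless).
#' @export
relaxation_rates <- function(s2, tau_c_ns, tau_e_ps = 0, field = 600,
                             rex = 0, rNH = 1.02, csa = -160) {
  if (field <= 0) stop("field must be > 0")
  if (any(s2 < 0 | s2 > 1)) stop("S2 must lie in [0, 1]")
  r <- .rates_fast(s2, tau_c_ns, tau_e_ps, field, rex, rNH, csa)
  data.frame(R1 = r$R1, R2 = r$R2, NOE = r$NOE)
}

# Vectorised inner loop used by the fitters; no validation, plain lists.
.rates_fast <- function(s2, tau_c_ns, tau_e_ps, field, rex = 0,
                        rNH = 1.02, csa = -160) {
  n <- max(length(s2), length(tau_e_ps), length(rex), length(tau_c_ns))
  s2 <- rep_len(s2, n); tau_e_ps <- rep_len(tau_e_ps, n)
  rex <- rep_len(rex, n); tau_c <- rep_len(tau_c_ns, n) * 1e-9
  tau_e <- tau_e_ps * 1e-12
  wH <- 2 * pi * field * 1e6
  wN <- abs(wH * .gammaN / .gammaH)
  d <- .mu0_4pi * .hbar * .gammaH * .gammaN / (rNH * 1e-10)^3
  c2 <- (wN * csa * 1e-6)^2 / 3
  d2 <- d^2
  tp <- ifelse(tau_e > 0, tau_e * tau_c / (tau_e + tau_c), 0)
  Jv <- function(w) {
    j <- s2 * tau_c / (1 + (w * tau_c)^2)
    add <- ifelse(tp > 0, (1 - s2) * tp / (1 + (w * tp)^2), 0)
    0.4 * (j + add)
  }
  j0 <- Jv(0); jN <- Jv(wN); jHmN <- Jv(wH - wN); jH <- Jv(wH)
  jHpN <- Jv(wH + wN)
  R1 <- d2 / 4 * (jHmN + 3 * jN + 6 * jHpN) + c2 * jN
  R2 <- d2 / 8 * (4 * j0 + jHmN + 3 * jN + 6 * jH + 6 * jHpN) +
    c2 / 6 * (4 * j0 + 3 * jN) + rex
  NOE <- 1 + d2 / (4 * R1) * (.gammaH / .gammaN) * (6 * jHpN - jHmN)
  list(R1 = R1, R2 = R2, NOE = NOE)
}

#' Construct a per-residue relaxation table
#'
#' @param residue residue ids.
#' @param T1,T2 relaxation times, s (> 0).
#' @param hetNOE steady-state heteronuclear NOE values.
#' @param field 1H frequency, MHz.
#' @return data.frame of class `relaxation_table` with attribute `field`.
#' @export
relaxation_table <- function(residue, T1, T2, hetNOE, field = 600) {
  if (any(T1 <= 0) || any(T2 <= 0)) stop("T1 and T2 must be > 0")
  if (any(T2 > T1))
    warning("T2 > T1 for some residues: outside the slow-tumbling regime")
  out <- data.frame(residue = residue, T1 = as.double(T1), T2 = as.double(T2),
                    hetNOE = as.double(hetNOE))
  attr(out, "field") <- field
  class(out) <- c("relaxation_table", "data.frame")
  out
}

#' Write / read a relaxation table as CSV (columns residue, T1_s, T2_s, hetNOE)
#' @param x a `relaxation_table`.
#' @param path file path.
#' @param field 1H frequency (MHz) for `read_relaxation`.
#' @export
write_relaxation <- function(x, path) {
  utils::write.csv(data.frame(residue = x$residue, T1_s = x$T1, T2_s = x$T2,
                              hetNOE = x$hetNOE), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relaxation
#' @export
read_relaxation <- function(path, field = 600) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "T1_s", "T2_s", "hetNOE")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("relaxation CSV missing column(s): ", paste(missing, collapse = ", "))
  relaxation_table(df$residue, df$T1_s, df$T2_s, df$hetNOE, field)
}

#' Assign an oligomeric state by comparing a fitted tau_c with SED predictions
#'
#' Picks the candidate whose Stokes-Einstein-Debye correlation time is
#' closest to the fitted one in log space (multiplicative distance — natural
#' for a quantity that scales as r^3).
#'
#' @param tau_c_fit fitted overall correlation time, ns.
#' @param sed_predictions named numeric vector of theoretical tau_c (ns),
#'   e.g. `c(dimer = 14.2, tetramer = 38.8)`.
#' @return list with `state` (name), `tau_c_fit`, `predictions`,
#'   `log_distance`.
#' @export
assign_oligomer <- function(tau_c_fit, sed_predictions) {
  if (!length(sed_predictions) || is.null(names(sed_predictions)))
    stop("sed_predictions must be a named vector")
  d <- abs(log(tau_c_fit) - log(sed_predictions))
  list(state = names(which.min(d)), tau_c_fit = tau_c_fit,
       predictions = sed_predictions, log_distance = d)
}
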