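#' Rigid-limit tau_c estimate from the R2/R1 ratio
#'
#' For each residue passing the NOE cut, solves the rigid (S2 = 1, tau_e = 0)
#' R2/R1 ratio for tau_c by root finding, then takes a 10%-trimmed mean.
#' Residues with low NOE (flexible) or exchange-inflated R2 would bias the
#' ratio, hence the cut and the trimming. Used as the initializer for
#' [fit_model_free()].
#'
#' @param table a [relaxation_table()].
#' @param noe_cut minimum heteronuclear NOE (default 0.65).
#' @param trim trimming fraction for the mean (default 0.1).
#' @return tau_c estimate, ns.
#' @export
estimate_tau_c_r2r1 <- function(table, noe_cut = 0.65, trim = 0.1) {
  field <- attr(table, "field")
  keep <- table$hetNOE > noe_cut
  if (sum(keep) < 5)
    stop("fewer than 5 residues pass the NOE cut; cannot estimate tau_c")
  ratio_fun <- function(tc) {
    r <- relaxation_rates(1, tc, 0, field)
    r$R2 / r$R1
  }
  target <- table$T1[keep] / table$T2[keep]  # = R2/R1
  tcs <- vapply(target, function(tg) {
    f <- function(tc) ratio_fun(tc) - tg
    lo <- 0.3; hi <- 200
    if (f(lo) > 0) return(lo)
    if (f(hi) < 0) return(hi)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }, 0)
  mean(tcs, trim = trim)
}

# Per-residue (S2, tau_e) least squares at fixed tau_c. Relative residuals on
# R1/R2, absolute on NOE.
.residue_obj <- function(par, obs, tau_c, field) {
  r <- .rates_fast(par[1], tau_c, par[2], field)
  ((r$R1 - obs$R1) / obs$R1)^2 + ((r$R2 - obs$R2) / obs$R2)^2 +
    (r$NOE - obs$NOE)^2
}

# objective for all residues at once with parameter matrix p = (S2, tau_e)
.table_obj <- function(tau_c, p, obs, field) {
  r <- .rates_fast(p[, 1], tau_c, p[, 2], field)
  sum(((r$R1 - obs$R1) / obs$R1)^2 + ((r$R2 - obs$R2) / obs$R2)^2 +
        (r$NOE - obs$NOE)^2)
}

.fit_residue <- function(obs, tau_c, field, start = c(0.85, 50),
                         multi = TRUE) {
  best <- NULL
  starts <- if (multi) list(start, c(0.9, 20), c(0.7, 200), c(0.98, 5))
            else list(start)
  for (st in starts) {
    f <- tryCatch(
      stats::optim(st, .residue_obj, obs = obs, tau_c = tau_c, field = field,
                   method = "L-BFGS-B", lower = c(0, 0), upper = c(1, 5000),
                   control = list(factr = 1e3)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    if (!is.null(best) && best$value < 1e-16) break
  }
  best
}

#' Lipari-Szabo model-free fit of a relaxation table
#'
#' Alternating optimisation under isotropic overall tumbling: given the
#' global tau_c, per-residue (S2, tau_e) are fitted by bounded least squares
#' on (R1, R2, NOE); given the residue parameters, tau_c is refined by a 1-D
#' search. Iterates until the relative change in tau_c and in the objective
#' falls below `tol` (default 1e-6) or `max_iter` (default 100).
#'
#' @param table a [relaxation_table()].
#' @param field 1H frequency, MHz; defaults to the table's `field` attribute.
#' @param tol convergence tolerance on relative change.
#' @param max_iter iteration cap.
#' @return object of class `model_free_fit`: `tau_c_ns`, `residues`
#'   (data.frame residue, S2, tau_e_ps, rss), `converged`, `iterations`,
#'   `notes`.
#' @export
fit_model_free <- function(table, field = attr(table, "field"),
                           tol = 1e-6, max_iter = 100) {
  stopifnot(nrow(table) >= 1)
  obs <- data.frame(R1 = 1 / table$T1, R2 = 1 / table$T2, NOE = table$hetNOE)
  notes <- character(0)
  if (nrow(table) < 3)
    notes <- c(notes, "under-determined: too few residues to separate tau_c from S2")
  tau_c <- tryCatch(estimate_tau_c_r2r1(table, noe_cut = -Inf),
                    error = function(e) 10)
  pars <- matrix(c(rep(0.85, nrow(table)), rep(50, nrow(table))), ncol = 2)
  obj_old <- Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    for (k in seq_len(nrow(table))) {
      f <- .fit_residue(obs[k, ], tau_c, field, start = pars[k, ],
                        multi = iter <= 2)
      if (!is.null(f)) pars[k, ] <- f$par
    }
    op <- stats::optimize(.table_obj, c(tau_c / 1.5, tau_c * 1.5),
                          p = pars, obs = obs, field = field, tol = 1e-9)
    tau_new <- op$minimum
    obj_new <- op$objective
    dtau <- abs(tau_new - tau_c) / tau_c
    dobj <- abs(obj_new - obj_old) / max(obj_old, .Machine$double.eps)
    tau_c <- tau_new
    obj_old <- obj_new
    if (dtau < tol && dobj < tol) { converged <- TRUE; break }
  }
  if (!converged)
    notes <- c(notes, sprintf("not converged after %d iterations", iter))
  res <- data.frame(residue = table$residue, S2 = pars[, 1],
                    tau_e_ps = pars[, 2],
                    rss = vapply(seq_len(nrow(table)), function(k)
                      .residue_obj(pars[k, ], obs[k, ], tau_c, field), 0))
  structure(list(tau_c_ns = tau_c, residues = res, converged = converged,
                 iterations = iter, objective = obj_old, field = field,
                 notes = notes),
            class = "model_free_fit")
}

#' @export
print.model_free_fit <- function(x, ...) {
  cat(sprintf("<model_free_fit> tau_c = %.3f ns over %d residues (%s, %d iterations)\n",
              x$tau_c_ns, nrow(x$residues),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  S2: median %.3f [%.3f, %.3f]\n", stats::median(x$residues$S2),
              min(x$residues$S2), max(x$residues$S2)))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
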