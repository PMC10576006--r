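#' Global kinetic fit of a sensorgram set
#'
#' Minimises the plain (unweighted) residual sum of squares over all traces
#' and time points with rate constants and Rmax shared across concentrations.
#' Optimisation runs in log10 parameter space with `stats::optim`
#' (L-BFGS-B inside generous bounds, Nelder-Mead fallback) from a multi-start
#' grid — by default 4 x 4 log-spaced over kon in [1e2, 1e8] M^-1 s^-1 and
#' koff in [1e-5, 10] s^-1 — and keeps the best local optimum (ties broken by
#' lowest rss, then lowest koff). For the 2:1 heterogeneous-ligand and 1:2
#' bivalent-analyte models, additional starts are seeded from the 1:1
#' solution (second site/step near zero) so the nested-model rss inequality
#' holds by construction.
#'
#' @param data a [sensorgram_set()].
#' @param model one of [kinetic_models()].
#' @param init optional named list of starting parameter values; when given it
#'   is added to the start list.
#' @param n_starts grid resolution per axis for the 1:1 multi-start (default 4).
#' @param bounds optional named list `list(par = c(lo, hi))` overriding the
#'   default box (natural units).
#' @return object of class `kinetic_fit` with elements `model`, `params`
#'   (natural units), `kd_derived` (molar, per site class), `site_fractions`,
#'   `rmax`, `rss`, `residuals`, `converged`, `pinned`, `se` (standard errors
#'   from the local quadratic approximation, natural units), `notes`.
#' @export
fit_global <- function(data, model = "one_to_one", init = NULL, n_starts = 4,
                       bounds = NULL) {
  stopifnot(inherits(data, "sensorgram_set"))
  model <- match.arg(model, kinetic_models())
  for (tr in data$traces)
    if (anyNA(tr$response) || anyNA(tr$time_s))
      stop("NaN/NA in sensorgram data; clean the input first")
  notes <- character(0)
  if (length(data$traces) < 2)
    notes <- c(notes, "single trace: (kon, koff, rmax) weakly identifiable")

  obs <- lapply(data$traces, function(tr) tr$response)
  rmax_guess <- max(vapply(obs, max, 0))
  if (rmax_guess <= 0) rmax_guess <- 1

  pnames <- switch(model,
    one_to_one = c("kon", "koff", "rmax"),
    heterogeneous_ligand = c("kon1", "koff1", "rmax1", "kon2", "koff2", "rmax2"),
    bivalent_analyte = c("ka1", "kd1", "ka2", "kd2", "rmax"))

  default_box <- list(
    kon = c(1e2, 1e8), koff = c(1e-5, 10), rmax = c(1e-4 * rmax_guess, 100 * rmax_guess),
    kon1 = c(1e2, 1e8), koff1 = c(1e-5, 10), rmax1 = c(1e-6 * rmax_guess, 100 * rmax_guess),
    kon2 = c(1e2, 1e8), koff2 = c(1e-5, 10), rmax2 = c(1e-6 * rmax_guess, 100 * rmax_guess),
    ka1 = c(50, 5e7), kd1 = c(1e-5, 10),
    ka2 = c(1e-8 / rmax_guess, 1e4 / rmax_guess), kd2 = c(1e-6, 10))
  if (!is.null(bounds)) default_box[names(bounds)] <- bounds
  lo <- log10(vapply(pnames, function(p) default_box[[p]][1], 0))
  hi <- log10(vapply(pnames, function(p) default_box[[p]][2], 0))

  rss_fun <- function(lp) {
    pars <- as.list(10^lp)
    names(pars) <- pnames
    s <- 0
    for (i in seq_along(data$traces)) {
      pred <- tryCatch(
        simulate_model(model, pars, data$conc[i],
                       data$traces[[i]]$time_s, data$t_assoc),
        error = function(e) NULL)
      if (is.null(pred) || anyNA(pred) || any(!is.finite(pred))) return(1e30)
      s <- s + sum((obs[[i]] - pred)^2)
    }
    s
  }

  starts <- .fit_starts(model, data, n_starts, rmax_guess, pnames, init)
  koff_key <- grep("^(koff|kd1)", pnames)[1]
  best <- NULL
  for (st in starts) {
    lp0 <- pmin(pmax(log10(st[pnames]), lo + 1e-9), hi - 1e-9)
    fit <- tryCatch(
      stats::optim(lp0, rss_fun, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        stats::optim(lp0, rss_fun, method = "Nelder-Mead",
                     control = list(maxit = 1000, reltol = 1e-10)),
        error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    cand <- list(par = fit$par, value = fit$value,
                 koff = 10^fit$par[koff_key], conv = fit$convergence == 0)
    if (is.null(best) || cand$value < best$value * (1 - 1e-12) ||
        (abs(cand$value - best$value) <= 1e-12 * max(best$value, 1e-300) &&
         cand$koff < best$koff))
      best <- cand
  }
  # polish only the winning start to high precision
  if (!is.null(best)) {
    for (pass in 1:2) {
      pol <- tryCatch(
        stats::optim(best$par, rss_fun, method = "Nelder-Mead",
                     control = list(maxit = 3000, reltol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value)) {
        # Nelder-Mead is unconstrained: project back into the box
        pp <- pmin(pmax(pol$par, lo), hi)
        pv <- if (all(pp == pol$par)) pol$value else rss_fun(pp)
        if (is.finite(pv) && pv < best$value)
          best <- list(par = pp, value = pv, koff = 10^pp[koff_key],
                       conv = TRUE)
      }
      ref <- tryCatch(
        stats::optim(pmin(pmax(best$par, lo + 1e-9), hi - 1e-9), rss_fun,
                     method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(maxit = 300, factr = 1e3)),
        error = function(e) NULL)
      if (!is.null(ref) && is.finite(ref$value) && ref$value < best$value)
        best <- list(par = ref$par, value = ref$value,
                     koff = 10^ref$par[koff_key], conv = ref$convergence == 0)
    }
  }

  if (is.null(best)) {
    return(structure(list(model = model, params = NULL, kd_derived = NULL,
                          site_fractions = NULL, rss = NA_real_,
                          residuals = NULL, converged = FALSE, pinned = character(0),
                          se = NULL,
                          notes = c(notes, "no start converged")),
                     class = "kinetic_fit"))
  }

  lp <- best$par
  pars <- stats::setNames(as.list(10^lp), pnames)
  pinned <- pnames[lp <= lo + 1e-4 | lp >= hi - 1e-4]
  residuals <- unlist(lapply(seq_along(data$traces), function(i) {
    obs[[i]] - simulate_model(model, pars, data$conc[i],
                              data$traces[[i]]$time_s, data$t_assoc)
  }))
  rss <- sum(residuals^2)

  kd <- switch(model,
    one_to_one = c(site1 = pars$koff / pars$kon),
    heterogeneous_ligand = c(site1 = pars$koff1 / pars$kon1,
                             site2 = pars$koff2 / pars$kon2),
    bivalent_analyte = c(step1 = pars$kd1 / (2 * pars$ka1),
                         step2 = if (pars$ka2 > 0) 2 * pars$kd2 / pars$ka2 else NA_real_))
  fractions <- switch(model,
    heterogeneous_ligand = {
      tot <- pars$rmax1 + pars$rmax2
      c(site1 = pars$rmax1 / tot, site2 = pars$rmax2 / tot)
    },
    c(site1 = 1))
  rmax <- switch(model,
    one_to_one = c(site1 = pars$rmax),
    heterogeneous_ligand = c(site1 = pars$rmax1, site2 = pars$rmax2),
    bivalent_analyte = c(total = pars$rmax))

  se <- tryCatch(.fit_se(rss_fun, lp, pnames, rss,
                         length(residuals)), error = function(e) NULL)
  structure(list(model = model, params = pars, kd_derived = kd,
                 site_fractions = fractions, rmax = rmax, rss = rss,
                 residuals = residuals,
                 converged = best$conv && length(pinned) == 0,
                 pinned = pinned, se = se, notes = notes),
            class = "kinetic_fit")
}

# Multi-start grid; heterogeneous and bivalent starts are seeded from a 1:1
# pre-fit so nested models never fit worse than 1:1.
.fit_starts <- function(model, data, n_starts, rmax_guess, pnames, init) {
  kon_grid <- 10^seq(log10(1e2), log10(1e8), length.out = n_starts)
  koff_grid <- 10^seq(log10(1e-5), log10(10), length.out = n_starts)
  starts <- list()
  if (model == "one_to_one") {
    for (kon in kon_grid) for (koff in koff_grid)
      starts[[length(starts) + 1]] <- c(kon = kon, koff = koff, rmax = rmax_guess)
  } else {
    base <- fit_global(data, "one_to_one", n_starts = n_starts)
    p1 <- if (!is.null(base$params)) base$params else
      list(kon = 1e5, koff = 0.1, rmax = rmax_guess)
    small <- n_starts <= 2  # reduced start set for simulation sweeps
    if (model == "heterogeneous_ligand") {
      starts[[1]] <- c(kon1 = p1$kon, koff1 = p1$koff, rmax1 = p1$rmax * (1 - 1e-4),
                       kon2 = p1$kon, koff2 = p1$koff * 10, rmax2 = p1$rmax * 1e-4)
      for (fr in c(0.5, 0.2)) for (sep in if (small) 100 else c(10, 100))
        starts[[length(starts) + 1]] <-
          c(kon1 = p1$kon, koff1 = p1$koff, rmax1 = p1$rmax * (1 - fr),
            kon2 = p1$kon / sep, koff2 = p1$koff / sep, rmax2 = p1$rmax * fr)
      if (!small)
        starts[[length(starts) + 1]] <-
          c(kon1 = p1$kon, koff1 = p1$koff, rmax1 = p1$rmax * 0.5,
            kon2 = p1$kon * 10, koff2 = p1$koff * 10, rmax2 = p1$rmax * 0.5)
    } else { # bivalent_analyte
      starts[[1]] <- c(ka1 = p1$kon / 2, kd1 = p1$koff, ka2 = 1e-7 / rmax_guess,
                       kd2 = 1e-3, rmax = p1$rmax)
      for (ka2 in (if (small) c(1e-3, 10) else c(1e-3, 1e-1, 10)) / rmax_guess)
        for (kd2 in if (small) 0.01 else c(1e-3, 0.1))
          starts[[length(starts) + 1]] <-
            c(ka1 = p1$kon / 2, kd1 = p1$koff, ka2 = ka2, kd2 = kd2,
              rmax = p1$rmax)
    }
  }
  if (!is.null(init)) {
    v <- unlist(init)[pnames]
    if (!anyNA(v)) starts <- c(list(v), starts)
  }
  starts
}

# Standard errors from the local quadratic approximation of the RSS surface,
# propagated from log10 space to natural units.
.fit_se <- function(rss_fun, lp, pnames, rss, n_pts) {
  k <- length(lp)
  h <- pmax(abs(lp) * 1e-4, 1e-5)
  H <- matrix(0, k, k)
  f0 <- rss_fun(lp)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (rss_fun(lp + ei + ej) - rss_fun(lp + ei) - rss_fun(lp + ej) + f0) /
      (h[i] * h[j])
  }
  dof <- max(n_pts - k, 1)
  sigma2 <- rss / dof
  cov_lp <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
  if (is.null(cov_lp)) return(NULL)
  se_lp <- sqrt(pmax(diag(cov_lp), 0))
  stats::setNames(10^lp * log(10) * se_lp, pnames) # delta method
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> model = %s, converged = %s, rss = %s\n",
              x$model, x$converged,
              if (is.na(x$rss)) "NA" else format(signif(x$rss, 4))))
  if (!is.null(x$params)) {
    cat("  parameters:\n")
    for (nm in names(x$params))
      cat(sprintf("    %-6s = %s\n", nm, format(signif(x$params[[nm]], 4))))
    cat(sprintf("  KD (M): %s\n",
                paste(sprintf("%s=%s", names(x$kd_derived),
                              signif(x$kd_derived, 4)), collapse = ", ")))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Fit several kinetic models and rank them by residual sum of squares
#'
#' @param data a [sensorgram_set()].
#' @param models character vector of model ids (default: all three).
#' @param ... passed to [fit_global()].
#' @return object of class `model_comparison`: list of `kinetic_fit`s, a
#'   `ranking` (model ids, ascending rss, failed fits excluded) and `notes`.
#' @export
compare_models <- function(data, models = kinetic_models(), ...) {
  if (!length(models)) stop("at least one model id is required")
  fits <- lapply(models, function(m) fit_global(data, m, ...))
  names(fits) <- models
  ok <- vapply(fits, function(f) is.finite(f$rss), TRUE)
  ranking <- models[ok][order(vapply(fits[ok], `[[`, 0, "rss"))]
  notes <- unlist(lapply(models[!ok], function(m)
    sprintf("%s: fit failed (%s)", m, paste(fits[[m]]$notes, collapse = "; "))))
  structure(list(fits = fits, ranking = ranking,
                 rss = vapply(fits, `[[`, 0, "rss"),
                 notes = if (is.null(notes)) character(0) else notes),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  for (m in names(x$fits))
    cat(sprintf("  %-22s rss = %s%s\n", m,
                if (is.finite(x$rss[m])) format(signif(x$rss[m], 4)) else "failed",
                if (length(x$ranking) && m == x$ranking[1]) "  <- best" else ""))
  invisible(x)
}

#' Convert association rate constants between M^-1 s^-1 and M^-1 ms^-1
#'
#' Instrument reports often print kon in M^-1 ms^-1 (e.g. 137 M^-1 ms^-1
#' = 1.37e5 M^-1 s^-1). The round trip is exact.
#'
#' @param kon rate constant value.
#' @param to `"per_ms"` or `"per_s"`.
#' @return converted value.
#' @export
convert_kon <- function(kon, to = c("per_ms", "per_s")) {
  to <- match.arg(to)
  if (to == "per_ms") kon / 1e3 else kon * 1e3
}
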