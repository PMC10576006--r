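#' Construct a mass-photometry event list
#'
#' Per-landing-event molecular masses (kD). Events outside the instrument
#' range are filtered out, with the number removed recorded as an attribute.
#'
#' @param masses numeric masses, kD.
#' @param instrument_range detection window, kD (default `c(30, 5000)`).
#' @return object of class `event_list`.
#' @export
event_list <- function(masses, instrument_range = c(30, 5000)) {
  keep <- masses >= instrument_range[1] & masses <= instrument_range[2]
  structure(list(masses = as.double(masses[keep]),
                 instrument_range = as.double(instrument_range),
                 n_filtered = sum(!keep)),
            class = "event_list")
}

#' Write / read event lists as CSV (single column mass_kD)
#' @param x an `event_list`.
#' @param path file path.
#' @param instrument_range detection window for `read_events`.
#' @export
write_events <- function(x, path) {
  utils::write.csv(data.frame(mass_kD = x$masses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, instrument_range = c(30, 5000)) {
  df <- utils::read.csv(path)
  if (!"mass_kD" %in% names(df)) stop("events CSV must have a mass_kD column")
  event_list(df$mass_kD, instrument_range)
}

#' Histogram of event masses
#'
#' Left-closed right-open bins of width `bin_width` covering the instrument
#' range; total counts are preserved.
#'
#' @param events an [event_list()].
#' @param bin_width kD (default 2.5).
#' @return data.frame with `mid`, `lower`, `upper`, `count`.
#' @export
build_histogram <- function(events, bin_width = 2.5) {
  if (!length(events$masses)) stop("event list is empty")
  if (bin_width <= 0) stop("bin_width must be > 0")
  rng <- events$instrument_range
  if (!all(is.finite(rng)))  # unbounded range: cover the observed masses
    rng <- c(floor(min(events$masses)), ceiling(max(events$masses)))
  breaks <- seq(rng[1], rng[2] + bin_width, by = bin_width)
  idx <- findInterval(events$masses, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  data.frame(mid = breaks[-length(breaks)] + bin_width / 2,
             lower = breaks[-length(breaks)], upper = breaks[-1],
             count = counts)
}

# k-means++-style deterministic seeding for 1-D EM.
.gmm_init <- function(x, k, seed) {
  set.seed(seed)
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(x, function(v) min((v - centers[1:(j - 1)])^2), 0)
    centers[j] <- x[sample.int(length(x), 1, prob = d2 + 1e-12)]
  }
  sort(centers)
}

#' Maximum-likelihood Gaussian mixture fit of event masses
#'
#' Expectation-maximization on the raw event list with deterministic
#' k-means++-style seeding (fixed seed). The log-likelihood is asserted
#' non-decreasing at every iteration. A component collapsing to sd -> 0 is
#' re-initialized once, then flagged.
#'
#' @param events an [event_list()].
#' @param k number of components (>= 1; needs at least `10*k` events).
#' @param seed seed for the initialization.
#' @param max_iter,tol EM controls.
#' @return object of class `mass_components`: data.frame `components`
#'   (mean, sd, weight, sorted by mean), `loglik`, `converged`, `notes`.
#' @export
fit_mixture <- function(events, k = 1, seed = 1L, max_iter = 500, tol = 1e-8) {
  x <- events$masses
  if (k < 1) stop("k must be >= 1")
  if (length(x) < 10 * k) stop("need at least 10*k events")
  run_em <- function(init_seed) {
    mu <- .gmm_init(x, k, init_seed)
    sigma <- rep(stats::sd(x) / k + 1e-6, k)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j)
        w[j] * stats::dnorm(x, mu[j], sigma[j]), numeric(length(x)))
      dens <- matrix(dens, ncol = k)
      rowsum_d <- rowSums(dens) + 1e-300
      ll <- sum(log(rowsum_d))
      if (ll < ll_old - 1e-6 * abs(ll_old))
        stop("EM log-likelihood decreased - internal error")
      resp <- dens / rowsum_d
      nk <- colSums(resp)
      if (any(nk < 1e-8)) { degenerate <- TRUE; break }
      w <- nk / length(x)
      mu <- colSums(resp * x) / nk
      sigma <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
      if (any(sigma < 1e-6)) { degenerate <- TRUE; break }
      if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) {
        return(list(mu = mu, sigma = sigma, w = w, ll = ll,
                    converged = TRUE, degenerate = FALSE, iter = it))
      }
      ll_old <- ll
    }
    list(mu = mu, sigma = sigma, w = w, ll = ll_old,
         converged = FALSE, degenerate = degenerate, iter = max_iter)
  }
  base_seed <- stream_seed(seed, noise_streams[["massphot"]])
  fit <- run_em(base_seed)
  notes <- character(0)
  if (fit$degenerate) {
    fit <- run_em(base_seed + 1L)  # one re-initialization, then flag
    if (fit$degenerate) notes <- c(notes, "degenerate component (sd -> 0)")
  }
  ord <- order(fit$mu)
  structure(list(components = data.frame(mean = fit$mu[ord],
                                         sd = fit$sigma[ord],
                                         weight = fit$w[ord]),
                 loglik = fit$ll, converged = fit$converged,
                 iterations = fit$iter, k = k, n = length(x), notes = notes),
            class = "mass_components")
}

#' Least-squares Gaussian fit on the binned histogram (cross-check)
#'
#' Alternative to [fit_mixture()] fitting `k` Gaussian components to the
#' binned counts by nonlinear least squares, seeded from the EM solution.
#' Expected to agree with EM on component means within ~0.5 kD at default
#' binning.
#'
#' @inheritParams fit_mixture
#' @param bin_width histogram bin width, kD.
#' @return `mass_components` (weights renormalised to sum to 1).
#' @export
fit_mixture_binned <- function(events, k = 1, bin_width = 2.5, seed = 1L) {
  h <- build_histogram(events, bin_width)
  em <- fit_mixture(events, k, seed)
  n <- length(events$masses)
  par0 <- c(em$components$mean, log(em$components$sd),
            log(em$components$weight + 1e-12))
  obj <- function(p) {
    mu <- p[1:k]; sg <- exp(p[(k + 1):(2 * k)]); wt <- exp(p[(2 * k + 1):(3 * k)])
    pred <- rowSums(vapply(seq_len(k), function(j)
      n * wt[j] * bin_width * stats::dnorm(h$mid, mu[j], sg[j]),
      numeric(nrow(h))))
    sum((h$count - pred)^2)
  }
  fit <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  mu <- fit$par[1:k]; sg <- exp(fit$par[(k + 1):(2 * k)])
  wt <- exp(fit$par[(2 * k + 1):(3 * k)]); wt <- wt / sum(wt)
  ord <- order(mu)
  structure(list(components = data.frame(mean = mu[ord], sd = sg[ord],
                                         weight = wt[ord]),
                 loglik = NA_real_, converged = fit$convergence == 0,
                 iterations = NA_integer_, k = k, n = n,
                 notes = "binned least-squares cross-check"),
            class = "mass_components")
}

#' @export
print.mass_components <- function(x, ...) {
  cat(sprintf("<mass_components> k = %d on %d events, loglik = %s\n",
              x$k, x$n, format(signif(x$loglik, 6))))
  print(transform(x$components, mean = signif(mean, 4), sd = signif(sd, 3),
                  weight = signif(weight, 3)))
  invisible(x)
}

#' Theoretical oligomer mass ladder
#'
#' Builds species masses from subunit masses and stoichiometries, e.g.
#' KRas 19.898 kD + Rgl2 RA 10.952 kD in 1:1 and 2:2 compositions gives the
#' ~30.9 kD heterodimer and ~61.7 kD heterotetramer rungs.
#'
#' @param subunits named numeric vector of subunit masses, kD.
#' @param stoichiometries list of named integer vectors (subunit -> count);
#'   optionally named to set species labels, otherwise labels are generated
#'   from the composition.
#' @return object of class `oligomer_ladder` (named numeric vector of kD).
#' @export
mass_ladder <- function(subunits, stoichiometries) {
  if (any(subunits <= 0)) stop("subunit masses must be > 0")
  if (!length(stoichiometries))
    return(structure(stats::setNames(numeric(0), character(0)),
                     class = "oligomer_ladder"))
  masses <- vapply(stoichiometries, function(comp) {
    unknown <- setdiff(names(comp), names(subunits))
    if (length(unknown))
      stop("unknown subunit(s) in composition: ", paste(unknown, collapse = ", "))
    sum(comp * subunits[names(comp)])
  }, 0)
  labels <- names(stoichiometries)
  auto <- vapply(stoichiometries, function(comp)
    paste(sprintf("%s%d", names(comp), comp), collapse = "_"), "")
  if (is.null(labels)) labels <- auto
  labels[!nzchar(labels)] <- auto[!nzchar(labels)]
  if (anyDuplicated(labels)) stop("species labels must be unique")
  structure(stats::setNames(masses, labels), class = "oligomer_ladder")
}

#' Default subunit mass profile for the KRas4B:Rgl2 RA system
#'
#' KRas4B constructs including bound GTP weigh 19.856 (WT) / 19.898 (G12V)
#' kD; the Rgl2 RA-domain mass (10.952 kD) is derived from the 61.7 kD
#' 2:2 heterotetramer.
#'
#' @return named numeric vector, kD.
#' @export
default_subunits <- function() {
  c(kras_wt = 19.856, kras_g12v = 19.898, rgl2ra = 10.952)
}

#' Assign fitted mass components to ladder species
#'
#' Each component goes to the nearest ladder species by relative mass error
#' `|m - m_species| / m_species`; components whose best relative error
#' exceeds `rel_tol` stay unassigned. Order of ladder entries is irrelevant.
#'
#' @param components a `mass_components` (or numeric vector of masses, kD).
#' @param ladder an [mass_ladder()].
#' @param rel_tol relative mass tolerance (default 0.15).
#' @return data.frame with `component_mass`, `species`, `expected_mass`,
#'   `rel_error`, `assigned`.
#' @export
assign_components <- function(components, ladder, rel_tol = 0.15) {
  if (!length(ladder)) stop("ladder is empty")
  if (rel_tol <= 0) stop("rel_tol must be > 0")
  masses <- if (inherits(components, "mass_components"))
    components$components$mean else as.double(components)
  rows <- lapply(masses, function(m) {
    err <- abs(m - ladder) / ladder
    j <- which.min(err)
    ok <- err[j] <= rel_tol
    data.frame(component_mass = m,
               species = if (ok) names(ladder)[j] else NA_character_,
               expected_mass = if (ok) unname(ladder[j]) else NA_real_,
               rel_error = unname(err[j]), assigned = ok)
  })
  do.call(rbind, rows)
}
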