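#' Construct an HSQC titration series
#'
#' @param ratios ligand:protein molar ratios, strictly increasing from 0; the
#'   first entry must be 0 (the free-state reference).
#' @param peaklists list of [peak_list()]s, one per ratio.
#' @param protein_conc labelled-protein concentration, molar.
#' @return object of class `titration_series`.
#' @export
titration_series <- function(ratios, peaklists, protein_conc) {
  stopifnot(length(ratios) == length(peaklists))
  if (ratios[1] != 0) stop("first titration point must be the free state (ratio 0)")
  if (is.unsorted(ratios, strictly = TRUE)) stop("ratios must be strictly increasing")
  if (any(ratios < 0)) stop("ratios must be >= 0")
  structure(list(ratios = as.double(ratios), peaklists = peaklists,
                 protein_conc = as.double(protein_conc)),
            class = "titration_series")
}

#' Generate a synthetic fast-exchange HSQC titration
#'
#' In two-state fast exchange the observed peak position is the population
#' average of the free and bound states: at each titration point the shift is
#' `delta_free + f_b * delta_bound_change` with the fraction bound `f_b` from
#' the exact binding quadratic ([fraction_bound()]). Peak intensity decays
#' linearly with fraction bound, `I = I0 * (1 - intensity_decay * f_b)`
#' floored at 0 — a simple proxy for the line broadening that accompanies
#' complex formation. Shift noise is additive Gaussian (ppm, applied to both
#' nuclei); intensity noise is multiplicative at the same sd interpreted as a
#' fraction.
#'
#' @param free_shifts data.frame/`peak_list` with `residue`, `dH`, `dN` and
#'   optionally `intensity` for the free state.
#' @param bound_deltas data.frame with `residue`, `ddH`, `ddN`: the full
#'   free-to-bound shift changes (ppm).
#' @param kd dissociation constant, molar (> 0).
#' @param protein_conc labelled protein concentration, molar.
#' @param ratios ligand:protein ratios, strictly increasing from 0.
#' @param intensity_decay fractional intensity loss at full saturation.
#' @param noise a [noise_spec()]; sd in ppm for shifts.
#' @return a [titration_series()].
#' @export
gen_titration_peaklists <- function(free_shifts, bound_deltas, kd,
                                    protein_conc,
                                    ratios = c(0, 0.25, 0.5, 1, 1.5, 2, 3),
                                    intensity_decay = 0.6,
                                    noise = noise_spec(0)) {
  if (!nrow(free_shifts)) stop("free-state residue set is empty")
  if (kd <= 0) stop("kd must be > 0")
  if (ratios[1] != 0 || is.unsorted(ratios, strictly = TRUE))
    stop("ratios must be strictly increasing and start at 0")
  if (is.null(free_shifts$intensity)) free_shifts$intensity <- 1
  i <- match(free_shifts$residue, bound_deltas$residue)
  if (anyNA(i)) stop("bound_deltas must cover every residue in free_shifts")
  ddH <- bound_deltas$ddH[i]
  ddN <- bound_deltas$ddN[i]
  set.seed(stream_seed(noise$seed, noise_streams[["titration"]]))
  peaklists <- lapply(ratios, function(r) {
    fb <- fraction_bound(protein_conc, r * protein_conc, kd)
    dH <- free_shifts$dH + fb * ddH
    dN <- free_shifts$dN + fb * ddN
    inten <- pmax(0, free_shifts$intensity * (1 - intensity_decay * fb))
    if (noise$sd > 0 && r > 0) {
      n <- nrow(free_shifts)
      dH <- dH + stats::rnorm(n, 0, noise$sd)
      dN <- dN + stats::rnorm(n, 0, noise$sd)
      inten <- pmax(0, inten * (1 + stats::rnorm(n, 0, noise$sd)))
    }
    peak_list(free_shifts$residue, dH, dN, inten)
  })
  titration_series(ratios, peaklists, protein_conc)
}

#' Write / read a titration series as CSV
#'
#' Long format with columns `residue, dH_ppm, dN_ppm, intensity, ratio`.
#'
#' @param series a [titration_series()].
#' @param path file path.
#' @param protein_conc protein concentration (molar) for `read_titration`
#'   (not stored in the CSV).
#' @export
write_titration <- function(series, path) {
  rows <- lapply(seq_along(series$ratios), function(i) {
    pl <- series$peaklists[[i]]
    data.frame(residue = pl$residue, dH_ppm = pl$dH, dN_ppm = pl$dN,
               intensity = pl$intensity, ratio = series$ratios[i])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path, protein_conc) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "dH_ppm", "dN_ppm", "intensity", "ratio")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("titration CSV missing column(s): ", paste(missing, collapse = ", "))
  ratios <- sort(unique(df$ratio))
  pls <- lapply(ratios, function(r) {
    sub <- df[df$ratio == r, , drop = FALSE]
    peak_list(sub$residue, sub$dH_ppm, sub$dN_ppm, sub$intensity)
  })
  titration_series(ratios, pls, protein_conc)
}
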