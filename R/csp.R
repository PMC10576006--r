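#' Construct an HSQC peak list
#'
#' One row per assigned backbone amide: residue number (1-based UniProt
#' coordinates), amide proton and nitrogen chemical shifts (ppm) and peak
#' intensity (arbitrary units).
#'
#' @param residue integer residue numbers (unique).
#' @param dH,dN chemical shifts, ppm.
#' @param intensity peak intensities (>= 0); default 1.
#' @return data.frame of class `peak_list`.
#' @export
peak_list <- function(residue, dH, dN, intensity = rep(1, length(residue))) {
  if (anyDuplicated(residue)) stop("residue ids must be unique")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(data.frame(residue = as.integer(residue), dH = as.double(dH),
                       dN = as.double(dN), intensity = as.double(intensity)),
            class = c("peak_list", "data.frame"))
}

#' Combined amide chemical shift perturbation
#'
#' For each residue present in both peak lists, the mean shift difference is
#' \deqn{\Delta\delta_{ave} = \sqrt{(\Delta\delta_{H})^2 +
#'       (\alpha\,\Delta\delta_{N})^2}}
#' in ppm, with nitrogen scaling `alpha` (default 0.1, the conventional
#' 1H/15N chemical-shift-range ratio). Residues absent from `observed` are
#' flagged `missing` and excluded from summary statistics.
#'
#' @param reference free-state [peak_list()].
#' @param observed peak list at a titration point.
#' @param alpha nitrogen scaling factor (> 0 normally; 0 gives |ddH|).
#' @return data.frame of class `csp_profile` with columns `residue`, `ddH`,
#'   `ddN`, `csp`, `fold_change`, `missing`, `classes`.
#' @export
compute_csp <- function(reference, observed, alpha = 0.1) {
  if (alpha < 0) stop("alpha must be >= 0")
  shared <- intersect(reference$residue, observed$residue)
  if (!length(shared)) stop("peak lists share no residues")
  i <- match(reference$residue, observed$residue)
  ddH <- observed$dH[i] - reference$dH
  ddN <- observed$dN[i] - reference$dN
  csp <- sqrt(ddH^2 + (alpha * ddN)^2)
  fc <- ifelse(reference$intensity > 0,
               observed$intensity[i] / reference$intensity, NA_real_)
  out <- data.frame(residue = reference$residue, ddH = ddH, ddN = ddN,
                    csp = csp, fold_change = fc,
                    missing = is.na(i))
  out$classes <- rep(NA_character_, nrow(out))
  class(out) <- c("csp_profile", "data.frame")
  out
}

#' Per-residue intensity fold change between two peak lists
#'
#' `I_observed / I_reference` for shared residues. Residues with zero
#' reference intensity or absent from `observed` are flagged (`NA`), never
#' divided or imputed.
#'
#' @inheritParams compute_csp
#' @return data.frame with `residue`, `fold_change`, `missing`.
#' @export
intensity_fold_change <- function(reference, observed) {
  i <- match(reference$residue, observed$residue)
  fc <- ifelse(!is.na(i) & reference$intensity > 0,
               observed$intensity[i] / reference$intensity, NA_real_)
  data.frame(residue = reference$residue, fold_change = fc,
             missing = is.na(i) | reference$intensity <= 0)
}

#' Classify residues by shift perturbation and intensity fold change
#'
#' A residue is `attenuated` if fold change < `fold_low`, `enhanced` if
#' > `fold_high`, `shifted` if its combined CSP is at or above
#' `csp_threshold`, and `unperturbed` otherwise. Classes are not exclusive
#' (a residue can be both shifted and attenuated); the `classes` column
#' stores the set as a `+`-joined string. The default CSP threshold is the
#' mean + 1 SD of the profile over non-missing residues; the default
#' intensity guide lines are 0.5 and 1.5.
#'
#' @param csp a `csp_profile` from [compute_csp()].
#' @param csp_threshold ppm; `NULL` (default) uses mean + 1 SD.
#' @param fold_low,fold_high intensity fold-change guide lines
#'   (`fold_low < 1 < fold_high`).
#' @return the profile with `classes` filled.
#' @export
classify_residues <- function(csp, csp_threshold = NULL,
                              fold_low = 0.5, fold_high = 1.5) {
  if (!(fold_low < 1 && 1 < fold_high))
    stop("need fold_low < 1 < fold_high")
  ok <- !csp$missing
  if (is.null(csp_threshold)) {
    v <- csp$csp[ok]
    csp_threshold <- mean(v) + stats::sd(v)
    if (is.na(csp_threshold)) csp_threshold <- mean(v)
  }
  cls <- character(nrow(csp))
  for (k in seq_len(nrow(csp))) {
    if (csp$missing[k]) { cls[k] <- "missing"; next }
    s <- character(0)
    if (!is.na(csp$fold_change[k])) {
      if (csp$fold_change[k] < fold_low) s <- c(s, "attenuated")
      if (csp$fold_change[k] > fold_high) s <- c(s, "enhanced")
    }
    if (csp$csp[k] >= csp_threshold && csp$csp[k] > 0) s <- c(s, "shifted")
    cls[k] <- if (length(s)) paste(sort(s), collapse = "+") else "unperturbed"
  }
  csp$classes <- cls
  attr(csp, "csp_threshold") <- csp_threshold
  attr(csp, "fold_lines") <- c(fold_low, fold_high)
  csp
}

#' Residues carrying a given perturbation class
#'
#' @param csp classified `csp_profile`.
#' @param what classes counted as perturbed.
#' @return integer residue numbers.
#' @export
perturbed_residues <- function(csp,
                               what = c("shifted", "attenuated", "enhanced")) {
  hit <- vapply(strsplit(csp$classes, "+", fixed = TRUE),
                function(s) any(s %in% what), TRUE)
  csp$residue[hit & !is.na(csp$classes)]
}

#' Exact two-state fraction bound
#'
#' Solution of the binding quadratic for P + L <-> PL:
#' \deqn{f_b = \frac{(K_D + L + P) - \sqrt{(K_D + L + P)^2 - 4LP}}{2P}}
#' the fraction of protein P bound at total ligand L.
#'
#' @param protein_conc,ligand_conc total concentrations, molar (>= 0, P > 0).
#' @param kd dissociation constant, molar (> 0).
#' @return fraction in `[0, min(1, L/P)]`. Vectorised over `ligand_conc`.
#' @export
fraction_bound <- function(protein_conc, ligand_conc, kd) {
  if (protein_conc <= 0) stop("protein concentration must be > 0")
  if (any(ligand_conc < 0)) stop("ligand concentration must be >= 0")
  if (kd <= 0) stop("kd must be > 0")
  s <- kd + ligand_conc + protein_conc
  pmax(0, (s - sqrt(s^2 - 4 * ligand_conc * protein_conc)) / (2 * protein_conc))
}

#' Observed CSP trajectory vs predicted saturation over a titration
#'
#' For each titration ratio, reports the mean combined CSP over residues
#' shared with the free-state reference, and the fraction bound predicted by
#' the exact two-state solution at the supplied KD. The series is flagged
#' `saturated` when the observed mean trajectory changes by less than 5%
#' (relative) over the last two points.
#'
#' @param series a [titration_series()].
#' @param kd assumed dissociation constant, molar.
#' @param alpha nitrogen scaling for the CSP.
#' @return list with `table` (ratio, mean_csp, f_b_pred) and `saturated`.
#' @export
saturation_curve <- function(series, kd, alpha = 0.1) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$ratios) < 3) stop("need at least 3 titration points")
  ref <- series$peaklists[[1]]
  mean_csp <- vapply(seq_along(series$ratios), function(i) {
    prof <- compute_csp(ref, series$peaklists[[i]], alpha)
    mean(prof$csp[!prof$missing])
  }, 0)
  fb <- fraction_bound(series$protein_conc,
                       series$ratios * series$protein_conc, kd)
  n <- length(mean_csp)
  last_change <- abs(mean_csp[n] - mean_csp[n - 1]) /
    max(abs(mean_csp[n]), .Machine$double.eps)
  list(table = data.frame(ratio = series$ratios, mean_csp = mean_csp,
                          f_b_pred = fb),
       saturated = last_change < 0.05)
}

#' Write a CSP report as TSV
#'
#' Columns: residue, dH_ppm_delta, dN_ppm_delta, csp_ppm, fold_change,
#' classes.
#'
#' @param csp classified `csp_profile`.
#' @param path output file.
#' @export
write_csp_report <- function(csp, path) {
  out <- data.frame(residue = csp$residue, dH_ppm_delta = csp$ddH,
                    dN_ppm_delta = csp$ddN, csp_ppm = csp$csp,
                    fold_change = csp$fold_change, classes = csp$classes)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
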