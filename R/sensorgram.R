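#' Construct a multi-concentration sensorgram set
#'
#' The container for BLI data: one response trace per analyte concentration,
#' an association phase on `[0, t_assoc]` and a dissociation phase after it.
#'
#' @param traces list of data.frames with columns `time_s`, `response`.
#' @param conc numeric vector of analyte concentrations (molar), one per trace.
#' @param t_assoc end of the association phase, s (shared by all traces).
#' @param ligand_id,analyte_id free-text labels.
#' @return object of class `sensorgram_set`.
#' @export
sensorgram_set <- function(traces, conc, t_assoc,
                           ligand_id = "ligand", analyte_id = "analyte") {
  stopifnot(is.list(traces), length(traces) == length(conc))
  # zero-concentration (buffer-only) traces are allowed for referencing
  if (any(conc < 0)) stop("trace concentrations must be >= 0")
  for (tr in traces) {
    stopifnot(all(c("time_s", "response") %in% names(tr)))
    if (is.unsorted(tr$time_s, strictly = TRUE))
      stop("times must be strictly increasing within each trace")
  }
  structure(list(traces = traces, conc = as.double(conc),
                 t_assoc = as.double(t_assoc),
                 ligand_id = ligand_id, analyte_id = analyte_id),
            class = "sensorgram_set")
}

#' @export
print.sensorgram_set <- function(x, ...) {
  cat(sprintf("<sensorgram_set> %d traces, t_assoc = %g s, analyte '%s' on '%s'\n",
              length(x$traces), x$t_assoc, x$analyte_id, x$ligand_id))
  cat(sprintf("  concentrations (M): %s\n",
              paste(signif(x$conc, 3), collapse = ", ")))
  invisible(x)
}

#' Write / read a sensorgram set as CSV
#'
#' Long format with columns `time_s, response, conc_molar, phase, trace_id`
#' where `phase` is `assoc` or `dissoc`.
#'
#' @param x a `sensorgram_set`.
#' @param path file path.
#' @return `read_sensorgrams` returns a `sensorgram_set`.
#' @export
write_sensorgrams <- function(x, path) {
  stopifnot(inherits(x, "sensorgram_set"))
  rows <- lapply(seq_along(x$traces), function(i) {
    tr <- x$traces[[i]]
    data.frame(time_s = tr$time_s, response = tr$response,
               conc_molar = x$conc[i],
               phase = ifelse(tr$time_s <= x$t_assoc, "assoc", "dissoc"),
               trace_id = i)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensorgrams
#' @export
read_sensorgrams <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "response", "conc_molar", "phase", "trace_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sensorgram CSV missing column(s): ", paste(missing, collapse = ", "))
  ids <- unique(df$trace_id)
  traces <- lapply(ids, function(id) {
    sub <- df[df$trace_id == id, , drop = FALSE]
    sub[order(sub$time_s), c("time_s", "response")]
  })
  conc <- vapply(ids, function(id) df$conc_molar[df$trace_id == id][1], 0)
  t_assoc <- max(df$time_s[df$phase == "assoc"])
  sensorgram_set(traces, conc, t_assoc)
}

.interp_trace <- function(trace, times) {
  # rule 2: constant extrapolation covers half-interval grid offsets at the
  # phase edges; non-overlapping ranges are rejected by the caller
  stats::approx(trace$time_s, trace$response, xout = times, rule = 2)$y
}

#' Double referencing of BLI sensorgrams
#'
#' Subtracts the reference-sensor trace (unloaded sensor in analyte) and the
#' buffer-well trace (loaded sensor in buffer) from each sample trace:
#' `corrected = sample - reference_sensor - buffer_well`. Arithmetic is exact
#' on aligned grids; when grids differ, reference traces are aligned to the
#' sample grid by linear interpolation.
#'
#' @param sample `sensorgram_set` of sample wells.
#' @param reference_sensor `sensorgram_set` with a single trace (or one per
#'   sample trace) from the reference sensor.
#' @param buffer_well `sensorgram_set` with a single trace (or one per sample
#'   trace) from the buffer-only well.
#' @return corrected `sensorgram_set`.
#' @export
double_reference <- function(sample, reference_sensor, buffer_well) {
  stopifnot(inherits(sample, "sensorgram_set"))
  pick <- function(set, i) {
    if (is.null(set)) return(NULL)
    if (length(set$traces) == 1L) set$traces[[1]] else set$traces[[i]]
  }
  corrected <- lapply(seq_along(sample$traces), function(i) {
    tr <- sample$traces[[i]]
    resp <- tr$response
    for (ref in list(pick(reference_sensor, i), pick(buffer_well, i))) {
      if (is.null(ref)) next
      if (max(ref$time_s) < min(tr$time_s) || min(ref$time_s) > max(tr$time_s))
        stop("reference trace time range does not overlap the sample trace")
      resp <- resp - .interp_trace(ref, tr$time_s)
    }
    data.frame(time_s = tr$time_s, response = resp)
  })
  sensorgram_set(corrected, sample$conc, sample$t_assoc,
                 sample$ligand_id, sample$analyte_id)
}
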