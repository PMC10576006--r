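#' Parse PDB-format coordinate text
#'
#' Reads ATOM/HETATM records from fixed-width PDB text. Alternate locations
#' keep the highest-occupancy conformer (ties: first seen); insertion codes
#' are preserved; only the first MODEL is read by default. Malformed
#' fixed-width records are rejected with their line number.
#'
#' @param text character: either a file path or PDB-format lines.
#' @param model which MODEL to keep (default 1; files without MODEL records
#'   are treated as a single model).
#' @param allow_empty when `TRUE`, a file with zero ATOM records yields an
#'   empty coordinate set instead of an error.
#' @return object of class `coordinate_set`: data.frame `atoms` with columns
#'   `chain`, `residue_id`, `icode`, `residue_name`, `atom_name`, `altloc`,
#'   `element`, `x`, `y`, `z`, `occupancy`, plus `model_id`.
#' @export
parse_structure <- function(text, model = 1, allow_empty = FALSE) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text) else unlist(strsplit(text, "\n", fixed = TRUE))
  cur_model <- 1L
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    rec <- substr(line, 1, 6)
    if (startsWith(rec, "MODEL")) {
      cur_model <- suppressWarnings(as.integer(trimws(substr(line, 11, 14))))
      if (is.na(cur_model)) cur_model <- 1L
      next
    }
    if (!(rec %in% c("ATOM  ", "HETATM"))) next
    if (cur_model != model) next
    if (nchar(line) < 54)
      stop(sprintf("malformed ATOM record at line %d: too short", ln))
    x <- suppressWarnings(as.double(substr(line, 31, 38)))
    y <- suppressWarnings(as.double(substr(line, 39, 46)))
    z <- suppressWarnings(as.double(substr(line, 47, 54)))
    resid <- suppressWarnings(as.integer(trimws(substr(line, 23, 26))))
    if (anyNA(c(x, y, z)) || is.na(resid))
      stop(sprintf("malformed ATOM record at line %d: non-numeric field", ln))
    occ <- suppressWarnings(as.double(substr(line, 55, 60)))
    rows[[length(rows) + 1]] <- data.frame(
      chain = substr(line, 22, 22),
      residue_id = resid,
      icode = trimws(substr(line, 27, 27)),
      residue_name = trimws(substr(line, 18, 20)),
      atom_name = trimws(substr(line, 13, 16)),
      altloc = trimws(substr(line, 17, 17)),
      element = trimws(substr(line, 77, 78)),
      x = x, y = y, z = z,
      occupancy = if (is.na(occ)) 1 else occ)
  }
  if (!length(rows)) {
    if (!allow_empty) stop("no ATOM/HETATM records found")
    atoms <- data.frame(chain = character(0), residue_id = integer(0),
                        icode = character(0), residue_name = character(0),
                        atom_name = character(0), altloc = character(0),
                        element = character(0), x = double(0), y = double(0),
                        z = double(0), occupancy = double(0))
    return(structure(list(atoms = atoms, model_id = model),
                     class = "coordinate_set"))
  }
  atoms <- do.call(rbind, rows)
  atoms$element <- ifelse(nzchar(atoms$element), atoms$element,
                          substr(gsub("[0-9']", "", atoms$atom_name), 1, 1))
  # altloc: keep the highest-occupancy conformer per (chain, residue, atom)
  key <- paste(atoms$chain, atoms$residue_id, atoms$icode, atoms$atom_name)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    idx[which.max(atoms$occupancy[idx])]
  }), use.names = FALSE)
  atoms <- atoms[sort(keep), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = model), class = "coordinate_set")
}

#' Write a coordinate set as PDB-format text
#'
#' @param coords a `coordinate_set`.
#' @param path optional file path; when `NULL` the text is returned.
#' @return invisibly the path, or the text when `path` is `NULL`.
#' @export
write_pdb <- function(coords, path = NULL) {
  a <- coords$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    nm <- a$atom_name[i]
    # atom-name column convention: 1-letter elements start in column 14
    nm_fmt <- if (nchar(nm) < 4 && nchar(a$element[i]) == 1)
      sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, nm_fmt, ifelse(nzchar(a$altloc[i]), a$altloc[i], " "),
            a$residue_name[i], a$chain[i], a$residue_id[i],
            ifelse(nzchar(a$icode[i]), a$icode[i], " "),
            a$x[i], a$y[i], a$z[i], a$occupancy[i], 0, a$element[i])
  }, "")
  txt <- paste(c(lines, "END"), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.coordinate_set <- function(x, ...) {
  cat(sprintf("<coordinate_set> %d atoms, chains: %s (model %d)\n",
              nrow(x$atoms), paste(unique(x$atoms$chain), collapse = ", "),
              x$model_id))
  invisible(x)
}
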