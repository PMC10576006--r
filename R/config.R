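#' Read an INI-style run configuration
#'
#' Plain-text sections `[name]` with `key = value` lines; `#` and `;` start
#' comments. Duplicate sections or keys are rejected. Values stay character;
#' consumers coerce. Section order is preserved (it is the stage execution
#' order).
#'
#' @param path file path.
#' @return named list of named character vectors, class `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("[#;].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  cur <- NULL
  for (line in lines) {
    if (grepl("^\\[.+\\]$", line)) {
      cur <- sub("^\\[(.+)\\]$", "\\1", line)
      if (cur %in% names(cfg)) stop("duplicate config section: ", cur)
      cfg[[cur]] <- character(0)
    } else if (grepl("=", line, fixed = TRUE)) {
      if (is.null(cur)) stop("key outside any [section]: ", line)
      key <- trimws(sub("=.*$", "", line))
      val <- trimws(sub("^[^=]*=", "", line))
      if (key %in% names(cfg[[cur]]))
        stop(sprintf("duplicate key '%s' in section [%s]", key, cur))
      cfg[[cur]][key] <- val
    } else stop("unparseable config line: ", line)
  }
  structure(cfg, class = "run_config")
}

# strict key validation: every key must be known to the stage
.check_keys <- function(section, keys, known) {
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop(sprintf("unknown key(s) in [%s]: %s", section,
                 paste(unknown, collapse = ", ")))
}

.cfg_num <- function(block, key, default = NULL) {
  if (!key %in% names(block)) {
    if (is.null(default)) stop("missing required key: ", key)
    return(default)
  }
  as.double(block[[key]])
}

.cfg_nums <- function(block, key, default = NULL) {
  if (!key %in% names(block)) return(default)
  as.double(strsplit(block[[key]], ",")[[1]])
}

.cfg_chr <- function(block, key, default = NULL) {
  if (!key %in% names(block)) {
    if (is.null(default)) stop("missing required key: ", key)
    return(default)
  }
  block[[key]]
}

# "a=1,b=2" -> named numeric
.cfg_named_nums <- function(block, key, default = NULL) {
  if (!key %in% names(block)) return(default)
  parts <- strsplit(strsplit(block[[key]], ",")[[1]], "=")
  stats::setNames(vapply(parts, function(p) as.double(trimws(p[2])), 0),
                  vapply(parts, function(p) trimws(p[1]), ""))
}
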