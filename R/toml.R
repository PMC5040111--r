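# Minimal TOML-subset reader for pipeline configuration files. Supports
# [table] and [table.subtable] headers, `key = value` pairs with string,
# number, boolean and flat-array values, and # comments. Enough for the
# config dialect this package documents; not a general TOML parser.

toml_value <- function(txt, path, lineno) {
  txt <- trimws(txt)
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- trimws(substr(txt, 2, nchar(txt) - 1))
    if (inner == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, toml_value, path = path, lineno = lineno)))
  }
  if (grepl('^".*"$', txt)) return(substr(txt, 2, nchar(txt) - 1))
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(num)
  stop("cannot parse TOML value at ", path, ":", lineno, ": ", txt)
}

#' Read a TOML-subset configuration file
#'
#' @param path file path.
#' @return nested named list mirroring the TOML tables.
#' @export
read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- list()
  section <- character(0)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[[A-Za-z0-9_.-]+\\]$", line)) {
      section <- strsplit(substr(line, 2, nchar(line) - 1), ".",
                          fixed = TRUE)[[1]]
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3) stop("cannot parse TOML line at ", path, ":", i)
    keys <- c(section, m[2])
    out <- assign_nested(out, keys, toml_value(m[3], path, i))
  }
  out
}

assign_nested <- function(lst, keys, value) {
  if (length(keys) == 1) {
    lst[[keys]] <- value
    return(lst)
  }
  head_key <- keys[1]
  if (is.null(lst[[head_key]])) lst[[head_key]] <- list()
  lst[[head_key]] <- assign_nested(lst[[head_key]], keys[-1], value)
  lst
}
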