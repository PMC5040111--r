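# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Generators take an explicit seed and must
# not disturb global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("`seed` must be coercible to integer")
    genv <- globalenv()
    had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = genv) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = genv)
      } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    })
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s]", name, format(lower), format(upper)))
  }
  invisible(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' Write a data frame as a UTF-8 tab-delimited file
#'
#' Canonical TSV dialect used by all file interfaces of the package: header
#' row, tab separator, no quoting, no row names.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-delimited file written by [write_tsv()]
#'
#' @param path input file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}
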