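#' Paired-factorial warming x clipping design
#'
#' Describes the experimental layout: `n_blocks` paired plots, each containing
#' exactly one observation of the four treatment cells
#' UU (unclipped-unwarmed control), UW (unclipped-warmed), CU
#' (clipped-unwarmed) and CW (clipped-warmed).
#'
#' @param n_blocks number of blocks (paired plots); the field experiment the
#'   package emulates used 6.
#' @return An object of class `factorial_design`: a list with `n_blocks`,
#'   the treatment codes, and a `table` data frame with one row per
#'   block x treatment carrying binary `warmed`/`clipped` flags and a
#'   `sample_id` of the form `B<block>_<treatment>`.
#' @examples
#' design <- factorial_design(6)
#' head(design$table)
#' @export
factorial_design <- function(n_blocks = 6) {
  if (!is_count(n_blocks) || n_blocks < 2) {
    stop("`n_blocks` must be an integer >= 2")
  }
  n_blocks <- as.integer(n_blocks)
  treatments <- c("UU", "UW", "CU", "CW")
  tab <- expand.grid(treatment = treatments, block = seq_len(n_blocks),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- tab[, c("block", "treatment")]
  tab$warmed <- as.integer(tab$treatment %in% c("UW", "CW"))
  tab$clipped <- as.integer(tab$treatment %in% c("CU", "CW"))
  tab$sample_id <- sprintf("B%d_%s", tab$block, tab$treatment)
  structure(
    list(n_blocks = n_blocks, treatments = treatments, table = tab),
    class = "factorial_design"
  )
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("factorial_design: %d blocks x 4 treatments (%s)\n",
              x$n_blocks, paste(x$treatments, collapse = ", ")))
  invisible(x)
}

treatment_of <- function(warmed, clipped) {
  c("UU", "UW", "CU", "CW")[1L + warmed + 2L * clipped]
}
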