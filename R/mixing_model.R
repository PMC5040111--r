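# Two-source stable-isotope mixing model: fraction of soil carbon derived
# from C4 vegetation, from bulk-soil delta13C and C3/C4 plant end-members.

#' Fraction of soil carbon derived from C4 plants
#'
#' Two-compartment linear mixing model:
#' `f = (delta_soil - delta_c3) / (delta_c4 - delta_c3)`. The fraction is
#' affine in `delta_soil` and swapping the end-members maps `f` to `1 - f`.
#' Fractions outside \[0, 1\] indicate end-member misspecification; they are
#' returned unclamped with the `out_of_range` flag set rather than silently
#' truncated.
#'
#' @param delta_soil bulk soil delta13C (per mil); vectorized.
#' @param delta_c3 C3 plant tissue delta13C end-member (per mil).
#' @param delta_c4 C4 plant tissue delta13C end-member (per mil); must differ
#'   from `delta_c3`.
#' @return data frame with `delta_soil`, `fraction_c4` and logical
#'   `out_of_range`.
#' @examples
#' fraction_c4(c(-24, -18.5, -13), delta_c3 = -24, delta_c4 = -13)
#' @export
fraction_c4 <- function(delta_soil, delta_c3, delta_c4) {
  stopifnot_scalar_number(delta_c3, "delta_c3")
  stopifnot_scalar_number(delta_c4, "delta_c4")
  if (delta_c3 == delta_c4) {
    stop("end-members are equal: mixing fraction undefined")
  }
  if (!is.numeric(delta_soil) || any(!is.finite(delta_soil))) {
    stop("`delta_soil` must be finite numeric")
  }
  f <- (delta_soil - delta_c3) / (delta_c4 - delta_c3)
  data.frame(delta_soil = delta_soil, fraction_c4 = f,
             out_of_range = f < 0 | f > 1)
}
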