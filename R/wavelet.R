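# Coiflet-1 analysis filter pair (orthonormal quadrature-mirror filters).
# Standard published coefficients; the high-pass is the alternating-sign
# reversal of the low-pass.
coif1_dec_lo <- c(-0.015655728135791993, -0.072732619512526450,
                   0.384864846864857800,  0.852572020211600400,
                   0.337897662457481800, -0.072732619512526450)
coif1_dec_hi <- c( 0.072732619512526450,  0.337897662457481800,
                  -0.852572020211600400,  0.384864846864857800,
                   0.072732619512526450, -0.015655728135791993)

wavelet_subband_names <- function() {
  # expand.grid varies the first factor fastest, so with (z, y, x) the pasted
  # x/y/z strings come out in lexicographic L-before-H order: LLL, LLH, ..., HHH
  g <- expand.grid(z = c("L", "H"), y = c("L", "H"), x = c("L", "H"),
                   stringsAsFactors = FALSE)
  paste0(g$x, g$y, g$z)
}

#' Undecimated 3D wavelet decomposition
#'
#' Single-level stationary (undecimated) separable wavelet transform with
#' Coiflet-1 filters and symmetric boundary extension. Each axis is filtered
#' with either the low-pass (L) or high-pass (H) filter, giving the eight
#' subbands LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH (letters ordered x, y, z).
#' Because no downsampling is performed every subband has the same grid shape
#' as the input and the transform is shift-consistent.
#'
#' @param image An [image_volume()]; every axis must have length at least 2.
#' @return Named list of 8 [image_volume()] objects, in the fixed subband
#'   order above.
#' @export
wavelet_decompositions <- function(image) {
  stopifnot(is_image_volume(image))
  d <- dim(image$values)
  if (any(d < 2L)) stop("degenerate axis: all grid axes must have length >= 2")
  filters <- list(L = coif1_dec_lo, H = coif1_dec_hi)
  out <- list()
  for (nm in wavelet_subband_names()) {
    letters3 <- strsplit(nm, "")[[1]]
    v <- image$values
    for (axis in 1:3) {
      v <- conv_axis(v, filters[[letters3[axis]]], axis)
    }
    out[[nm]] <- image_volume(v, image$spacing_mm, image$sequence_label)
  }
  out
}
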