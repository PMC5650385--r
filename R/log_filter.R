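#' Discretized 2D Laplacian-of-Gaussian kernel
#'
#' Negated-LoG convention: the kernel is
#' \deqn{K(x, y) = -\frac{1}{\pi\sigma^4}\Big(1 - \frac{x^2+y^2}{2\sigma^2}\Big)
#'   e^{-(x^2+y^2)/(2\sigma^2)}}
#' sampled on an integer grid of radius `ceiling(3.5 sigma)` (at least 2) and
#' shifted by its mean so the discrete kernel sums exactly to zero, making the
#' filter a true band-pass (zero response on constants).
#'
#' @param sigma Positive filter width in pixels.
#' @return Square numeric matrix of odd side length.
#' @export
log_kernel <- function(sigma) {
  stopifnot(is.finite(sigma), sigma > 0)
  r <- max(2L, as.integer(ceiling(3.5 * sigma)))
  x <- seq(-r, r)
  ss <- outer(x^2, x^2, "+")
  k <- -(1 / (pi * sigma^4)) * (1 - ss / (2 * sigma^2)) * exp(-ss / (2 * sigma^2))
  k - mean(k)
}

#' Laplacian-of-Gaussian band-pass filtering
#'
#' Applies the 2D [log_kernel()] slice-wise in the axial (x, y) plane with
#' symmetric boundary extension. `sigma` tunes the texture scale emphasised:
#' small values respond to fine texture, large values to coarse texture.
#' `sigma = 0` means no filtration and returns the input unchanged.
#'
#' @param image An [image_volume()].
#' @param sigma Filter width in pixels, `>= 0`.
#' @return An [image_volume()] with the filter response (same grid, spacing
#'   and sequence label).
#' @export
apply_log_filter <- function(image, sigma) {
  stopifnot(is_image_volume(image))
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(image)
  k <- log_kernel(sigma)
  r <- (nrow(k) - 1L) %/% 2L
  v <- image$values
  d <- dim(v)
  ix <- symmetric_pad_index(d[1], r, r)
  iy <- symmetric_pad_index(d[2], r, r)
  vp <- v[ix, iy, , drop = FALSE]
  # direct shift-add 2D convolution over all slices at once; the kernel is
  # point-symmetric so correlation equals convolution
  out <- array(0, d)
  for (ki in seq_len(nrow(k))) {
    rows <- (ki - 1L) + seq_len(d[1])
    for (kj in seq_len(ncol(k))) {
      if (k[ki, kj] == 0) next
      out <- out + k[ki, kj] * vp[rows, (kj - 1L) + seq_len(d[2]), , drop = FALSE]
    }
  }
  image_volume(out, image$spacing_mm, image$sequence_label)
}
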