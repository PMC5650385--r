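# Internal separable filtering utilities shared by the Gaussian smoother,
# the LoG filter and the wavelet filter bank.

# Index vector implementing whole-sample symmetric extension
# (... x3 x2 x1 | x1 x2 ... xn | xn xn-1 ...).
symmetric_pad_index <- function(n, pad_left, pad_right) {
  if (max(pad_left, pad_right) > n) {
    stop("axis of length ", n, " is too short for a filter needing ",
         max(pad_left, pad_right), " samples of padding")
  }
  c(rev(seq_len(pad_left)), seq_len(n), n + 1L - seq_len(pad_right))
}

# "Same"-size 1D correlation of a 3D array along one axis with symmetric
# boundary extension. Convention: out[i] = sum_k kernel[k] * ext[i - pl + k - 1]
# with pl = floor(L/2); for symmetric kernels this equals centred convolution.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  stopifnot(length(d) == 3L, axis %in% 1:3)
  n <- d[axis]
  L <- length(kernel)
  if (n < 2L) stop("degenerate axis of length 1 cannot be filtered")
  pl <- L %/% 2L
  pr <- L - 1L - pl
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dim(m) <- c(n, prod(d[perm[2:3]]))
  mp <- m[symmetric_pad_index(n, pl, pr), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (k in seq_len(L)) {
    out <- out + kernel[k] * mp[(k - 1L) + seq_len(n), , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing; sigma_vox is per-axis, in voxels (0 skips axis).
gaussian_smooth_3d <- function(a, sigma_vox) {
  stopifnot(length(sigma_vox) == 3L, all(sigma_vox >= 0))
  for (axis in 1:3) {
    if (sigma_vox[axis] > 0) {
      a <- conv_axis(a, gaussian_kernel_1d(sigma_vox[axis]), axis)
    }
  }
  a
}
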