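firstorder_feature_names <- function() {
  c("mean", "median", "minimum", "maximum", "range", "variance", "std",
    "skewness", "kurtosis", "energy", "total_energy", "entropy", "uniformity",
    "rms", "mad", "robust_mad", "p10", "p90", "iqr")
}

#' First-order intensity features
#'
#' The 19-feature first-order set of the catalog, computed over in-mask
#' voxels. Moments use the population (1/N) convention; kurtosis is
#' non-excess (a Gaussian scores 3); entropy and uniformity are computed on
#' an equal-width `n_bins` histogram of the in-mask range (base-2 entropy);
#' `total_energy` scales energy by the voxel volume in mm^3. `robust_mad` is
#' the mean absolute deviation of the values between the 10th and 90th
#' percentiles. Degenerate convention: skewness and kurtosis of a constant
#' region are 0.
#'
#' @param image An [image_volume()].
#' @param mask An aligned [roi_mask()].
#' @param n_bins Histogram bins for entropy/uniformity (default 32).
#' @return Named numeric vector of length 19.
#' @export
firstorder_features <- function(image, mask, n_bins = 32L) {
  stopifnot(is_image_volume(image), is_roi_mask(mask))
  check_aligned(image, mask)
  x <- image$values[mask$values]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  inner <- x[x >= q[1] & x <= q[4]]
  rng <- range(x)
  if (rng[2] > rng[1]) {
    b <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1, n_bins)
    p <- tabulate(b, n_bins) / n
  } else {
    p <- 1
  }
  voxvol <- prod(image$spacing_mm)
  c(mean = mu,
    median = stats::median(x),
    minimum = rng[1],
    maximum = rng[2],
    range = rng[2] - rng[1],
    variance = m2,
    std = sqrt(m2),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    energy = sum(x^2),
    total_energy = voxvol * sum(x^2),
    entropy = entropy2(p),
    uniformity = sum(p^2),
    rms = sqrt(mean(x^2)),
    mad = mean(abs(x - mu)),
    robust_mad = mean(abs(inner - mean(inner))),
    p10 = q[1],
    p90 = q[4],
    iqr = q[3] - q[2])
}
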