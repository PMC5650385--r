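#' Build the indexed set of image variants for feature extraction
#'
#' Produces the deterministic ordered list of filtered image variants from
#' which texture features are computed: the original image (index 1), one
#' LoG-filtered image per sigma in ascending order (fine to coarse texture),
#' and the eight undecimated wavelet subbands in LLL..HHH order. With the
#' default sigmas this yields 13 variants per image.
#'
#' @param image An [image_volume()].
#' @param log_sigmas LoG filter widths in pixels; must be distinct. The
#'   default `c(1, 1.5, 2, 2.5)` spans fine (1.0), medium (1.5, 2.0) and
#'   coarse (2.5) texture.
#' @return List of variants; each element is a list with `image`
#'   ([image_volume()]), integer `variant_index` and a `descriptor` string
#'   (`"original"`, `"LoG(s)"` or `"wavelet(SSS)"`).
#' @export
build_variant_set <- function(image, log_sigmas = c(1, 1.5, 2, 2.5)) {
  stopifnot(is_image_volume(image))
  if (anyDuplicated(log_sigmas)) stop("'log_sigmas' must be distinct")
  if (length(log_sigmas)) {
    stopifnot(all(is.finite(log_sigmas)), all(log_sigmas > 0))
    log_sigmas <- sort(log_sigmas)
  }
  variants <- list(list(image = image, descriptor = "original"))
  for (s in log_sigmas) {
    variants[[length(variants) + 1L]] <-
      list(image = apply_log_filter(image, s),
           descriptor = sprintf("LoG(%g)", s))
  }
  wl <- wavelet_decompositions(image)
  for (nm in names(wl)) {
    variants[[length(variants) + 1L]] <-
      list(image = wl[[nm]], descriptor = sprintf("wavelet(%s)", nm))
  }
  for (i in seq_along(variants)) variants[[i]]$variant_index <- i
  variants
}

#' Discretize in-mask intensities to gray levels
#'
#' Equal-width binning of the in-mask intensity range into `n_bins` gray
#' levels 1..Ng (level 0 outside the mask), the standard preprocessing step
#' for co-occurrence and run-length matrices. A constant in-mask region maps
#' entirely to level 1.
#'
#' @param image An [image_volume()].
#' @param mask An aligned [roi_mask()].
#' @param n_bins Number of gray levels, `>= 2` (default 32).
#' @return Object of class `discretized_roi`: list with integer array
#'   `levels` (0 outside the mask) and `n_levels = n_bins`.
#' @export
discretize_roi <- function(image, mask, n_bins = 32L) {
  stopifnot(is_image_volume(image), is_roi_mask(mask), n_bins >= 2L)
  check_aligned(image, mask)
  inmask <- image$values[mask$values]
  if (!all(is.finite(inmask))) stop("non-finite in-mask intensities")
  lo <- min(inmask)
  hi <- max(inmask)
  lv <- array(0L, dim(image$values))
  if (hi > lo) {
    b <- pmin(as.integer(floor((inmask - lo) / (hi - lo) * n_bins)) + 1L,
              as.integer(n_bins))
    lv[mask$values] <- b
  } else {
    lv[mask$values] <- 1L
  }
  structure(list(levels = lv, n_levels = as.integer(n_bins)),
            class = "discretized_roi")
}
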