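#' 3D image volume
#'
#' Container for one scalar MRI-like volume: a 3D numeric grid with voxel
#' spacing in millimetres and a sequence label. All feature extraction in the
#' package operates on this type together with an aligned [roi_mask()].
#'
#' @param values 3D numeric array of finite voxel intensities.
#' @param spacing_mm Numeric length-3 vector of positive voxel spacings (mm).
#' @param sequence_label Sequence the volume represents, `"T2w"` or `"CET1w"`.
#' @return An object of class `image_volume`: a list with elements `values`,
#'   `spacing_mm` and `sequence_label`.
#' @examples
#' vol <- image_volume(array(rnorm(64), c(4, 4, 4)), c(1, 1, 4), "T2w")
#' dim(vol$values)
#' @export
image_volume <- function(values, spacing_mm = c(1, 1, 1),
                         sequence_label = c("T2w", "CET1w")) {
  sequence_label <- match.arg(sequence_label)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array")
  }
  if (!all(is.finite(values))) stop("'values' must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop("'spacing_mm' must be 3 positive numbers")
  }
  structure(list(values = values, spacing_mm = spacing_mm,
                 sequence_label = sequence_label),
            class = "image_volume")
}

is_image_volume <- function(x) inherits(x, "image_volume")

#' Binary region-of-interest mask
#'
#' Tumor segmentation mask aligned voxel-for-voxel with an [image_volume()].
#'
#' @param values 3D array coercible to logical; `TRUE`/1 marks tumor voxels.
#'   At least one voxel must be positive.
#' @return An object of class `roi_mask` with a logical 3D `values` array.
#' @export
roi_mask <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array")
  }
  v <- array(as.logical(values), dim(values))
  if (anyNA(v)) stop("mask values must be 0/1 or logical")
  if (!any(v)) stop("mask must contain at least one positive voxel")
  structure(list(values = v), class = "roi_mask")
}

is_roi_mask <- function(x) inherits(x, "roi_mask")

check_aligned <- function(image, mask) {
  if (!identical(dim(image$values), dim(mask$values))) {
    stop("image and mask grids are not aligned: ",
         paste(dim(image$values), collapse = "x"), " vs ",
         paste(dim(mask$values), collapse = "x"))
  }
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers over the RNifti reader/writer that carry the voxel spacing
#' and (on write) store the array as-is. Masks are written as 0/1 volumes.
#'
#' @param x An [image_volume()] or [roi_mask()].
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @param sequence_label Label to attach on read.
#' @return `write_volume_nifti` returns `path` invisibly; `read_volume_nifti`
#'   returns an [image_volume()].
#' @export
write_volume_nifti <- function(x, path) {
  v <- if (is_roi_mask(x)) x$values + 0 else x$values
  img <- RNifti::asNifti(v)
  if (is_image_volume(x)) RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, sequence_label = "T2w") {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim(img)[1:3]),
               spacing_mm = RNifti::pixdim(img)[1:3],
               sequence_label = sequence_label)
}
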