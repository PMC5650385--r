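shape_feature_names <- function() {
  c("volume_mm3", "surface_area_mm2", "surface_to_volume_ratio", "sphericity",
    "compactness1", "compactness2", "spherical_disproportion",
    "max_3d_diameter_mm", "major_axis_length_mm", "minor_axis_length_mm",
    "least_axis_length_mm")
}

# Surface area via the coarea formula: smooth the binary indicator with a
# small Gaussian and integrate the gradient magnitude. Averages away the
# voxel staircase so digitized smooth shapes get close-to-analytic areas.
mask_surface_area <- function(mask_values, spacing_mm, sigma_mm = 0.55) {
  f <- gaussian_smooth_3d(mask_values + 0, pmax(sigma_mm / spacing_mm, 0.35))
  d <- dim(f)
  grad2 <- array(0, d)
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2L) next
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    idx_p <- idx_m <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_p[[axis]] <- ip
    idx_m[[axis]] <- im
    h <- (ip - im) * spacing_mm[axis]
    g <- (f[idx_p[[1]], idx_p[[2]], idx_p[[3]], drop = FALSE] -
          f[idx_m[[1]], idx_m[[2]], idx_m[[3]], drop = FALSE])
    # divide by the per-position step (2h interior, h at the edges)
    g <- sweep(g, axis, h, "/")
    grad2 <- grad2 + g^2
  }
  sum(sqrt(grad2)) * prod(spacing_mm)
}

#' Shape and size features of a tumor mask
#'
#' The 11-feature shape set of the catalog. Volume is voxel count times
#' voxel volume. Surface area uses a smoothed-indicator (coarea) estimator
#' that compensates the voxel staircase. Sphericity is
#' \eqn{\pi^{1/3} (6V)^{2/3} / A}; compactness1 \eqn{V / (\sqrt{\pi}
#' A^{3/2})}; compactness2 \eqn{36 \pi V^2 / A^3}; spherical disproportion
#' is the reciprocal of sphericity. The maximum 3D diameter is the largest
#' distance between boundary voxel centres; axis lengths are
#' \eqn{4\sqrt{\lambda}} for the eigenvalues of the voxel-coordinate
#' covariance (in mm).
#'
#' @param mask An [roi_mask()].
#' @param spacing_mm Voxel spacing in mm (length 3).
#' @return Named numeric vector of length 11.
#' @export
shape_features <- function(mask, spacing_mm = c(1, 1, 1)) {
  stopifnot(is_roi_mask(mask))
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  mv <- mask$values
  nvox <- sum(mv)
  vol <- nvox * prod(spacing_mm)
  area <- mask_surface_area(mv, spacing_mm)

  # boundary voxels: in-mask with at least one 6-neighbour outside (or on
  # the grid edge)
  d <- dim(mv)
  interior <- array(TRUE, d)
  for (axis in 1:3) {
    n <- d[axis]
    for (shift in c(-1L, 1L)) {
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[axis]] <- pmin(pmax(seq_len(n) + shift, 1L), n)
      nb <- mv[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      edge_pos <- (seq_len(n) + shift < 1L) | (seq_len(n) + shift > n)
      if (any(edge_pos)) {
        sel <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        sel[[axis]] <- which(edge_pos)
        nb[sel[[1]], sel[[2]], sel[[3]]] <- FALSE
      }
      interior <- interior & nb
    }
  }
  boundary <- mv & !interior
  coord <- which(mv, arr.ind = TRUE)
  coord_mm <- sweep(coord, 2, spacing_mm, "*")
  bcoord <- which(boundary, arr.ind = TRUE)
  bcoord_mm <- sweep(bcoord, 2, spacing_mm, "*")

  maxdiam <- 0
  if (nrow(bcoord_mm) > 1L) {
    sq <- rowSums(bcoord_mm^2)
    g <- bcoord_mm %*% t(bcoord_mm)
    maxdiam <- sqrt(max(outer(sq, sq, "+") - 2 * g))
  }

  axes <- c(0, 0, 0)
  if (nvox > 1L) {
    cv <- stats::cov(coord_mm) * (nvox - 1) / nvox
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    axes <- 4 * sqrt(pmax(ev, 0))
  }

  sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  c(volume_mm3 = vol,
    surface_area_mm2 = area,
    surface_to_volume_ratio = area / vol,
    sphericity = sph,
    compactness1 = vol / (sqrt(pi) * area^1.5),
    compactness2 = 36 * pi * vol^2 / area^3,
    spherical_disproportion = 1 / sph,
    max_3d_diameter_mm = maxdiam,
    major_axis_length_mm = axes[1],
    minor_axis_length_mm = axes[2],
    least_axis_length_mm = axes[3])
}
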