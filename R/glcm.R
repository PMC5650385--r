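#' The 13 unique 3D neighbour directions
#'
#' Offsets covering every 26-connected neighbour pair once (opposite offsets
#' are equivalent after symmetrization).
#'
#' @return Integer 13 x 3 matrix of (dx, dy, dz) offsets.
#' @export
texture_directions_3d <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0),
    c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(m) <- "integer"
  m
}

#' Gray-level co-occurrence matrix
#'
#' Accumulates co-occurrences of gray-level pairs at a fixed voxel distance
#' over the given 3D directions (all 13 unique directions by default, merged
#' into a single matrix), restricted to pairs where both voxels lie inside
#' the mask. The matrix is symmetrized and normalized to sum 1.
#'
#' @param d A `discretized_roi` from [discretize_roi()].
#' @param directions Integer matrix of offsets (rows), as
#'   [texture_directions_3d()].
#' @param distance Co-occurrence distance in voxels (default 1).
#' @return Object of class `glcm`: list with probability matrix `p`
#'   (`Ng x Ng`) and `Ng`.
#' @export
compute_glcm <- function(d, directions = texture_directions_3d(), distance = 1L) {
  stopifnot(inherits(d, "discretized_roi"), distance >= 1L)
  if (is.null(dim(directions)) || nrow(directions) < 1L) {
    stop("'directions' must be a non-empty offset matrix")
  }
  lv <- d$levels
  Ng <- d$n_levels
  dd <- dim(lv)
  counts <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(directions))) {
    off <- directions[r, ] * as.integer(distance)
    src <- vector("list", 3)
    for (a in 1:3) {
      src[[a]] <- if (off[a] >= 0) seq_len(dd[a] - off[a]) else seq(1 - off[a], dd[a])
      if (length(src[[a]]) == 0L) break
    }
    if (any(lengths(src) == 0L)) next
    l1 <- lv[src[[1]], src[[2]], src[[3]], drop = FALSE]
    l2 <- lv[src[[1]] + off[1], src[[2]] + off[2], src[[3]] + off[3], drop = FALSE]
    keep <- l1 > 0L & l2 > 0L
    if (!any(keep)) next
    code <- (l1[keep] - 1L) * Ng + l2[keep]
    tab <- tabulate(code, nbins = Ng * Ng)
    counts <- counts + matrix(tab, Ng, Ng, byrow = TRUE)
  }
  counts <- counts + t(counts)
  total <- sum(counts)
  if (total == 0) stop("no co-occurring in-mask voxel pairs at this distance")
  structure(list(p = counts / total, Ng = Ng), class = "glcm")
}

glcm_feature_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade",
    "cluster_tendency", "contrast", "correlation", "difference_average",
    "difference_entropy", "difference_variance", "dissimilarity", "energy",
    "entropy", "homogeneity1", "homogeneity2", "IMC1", "IMC2", "IDMN", "IDN",
    "inverse_variance", "maximum_probability", "sum_average", "sum_entropy",
    "sum_variance", "variance")
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Haralick-type features of a co-occurrence matrix
#'
#' Computes the 24-feature GLCM set of the catalog. Entropies are base 2.
#' Degenerate conventions: when a marginal standard deviation is zero,
#' `correlation` is 1; when `max(HX, HY)` is zero, `IMC1` is 0.
#'
#' @param m A `glcm` from [compute_glcm()].
#' @return Named numeric vector of length 24.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "glcm"))
  p <- m$p
  Ng <- m$Ng
  i <- row(p)
  j <- col(p)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(seq_len(Ng) * px)
  mu_y <- sum(seq_len(Ng) * py)
  sd_x <- sqrt(sum((seq_len(Ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(Ng) - mu_y)^2 * py))

  # diagonal (difference) and cross-diagonal (sum) distributions
  pdiff <- as.numeric(tapply(p, abs(i - j), sum))        # k = 0 .. Ng-1
  kdiff <- sort(unique(as.vector(abs(i - j))))
  psum <- as.numeric(tapply(p, i + j, sum))              # k = 2 .. 2Ng
  ksum <- sort(unique(as.vector(i + j)))

  da <- sum(kdiff * pdiff)
  sa <- sum(ksum * psum)

  hxy <- entropy2(p)
  hx <- entropy2(px)
  hy <- entropy2(py)
  pxy_prod <- px[i] * py[j]
  pos <- p > 0 & pxy_prod > 0
  hxy1 <- -sum(p[pos] * log2(pxy_prod[pos]))
  posm <- pxy_prod > 0
  hxy2 <- -sum(pxy_prod[posm] * log2(pxy_prod[posm]))

  corr <- if (sd_x * sd_y > 0) {
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  off <- i != j
  c(autocorrelation = sum(i * j * p),
    cluster_prominence = sum((i + j - mu_x - mu_y)^4 * p),
    cluster_shade = sum((i + j - mu_x - mu_y)^3 * p),
    cluster_tendency = sum((i + j - mu_x - mu_y)^2 * p),
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = entropy2(pdiff),
    difference_variance = sum((kdiff - da)^2 * pdiff),
    dissimilarity = sum(abs(i - j) * p),
    energy = sum(p^2),
    entropy = hxy,
    homogeneity1 = sum(p / (1 + abs(i - j))),
    homogeneity2 = sum(p / (1 + (i - j)^2)),
    IMC1 = imc1,
    IMC2 = imc2,
    IDMN = sum(p / (1 + (i - j)^2 / Ng^2)),
    IDN = sum(p / (1 + abs(i - j) / Ng)),
    inverse_variance = sum(p[off] / (i[off] - j[off])^2),
    maximum_probability = max(p),
    sum_average = sa,
    sum_entropy = entropy2(psum),
    sum_variance = sum((ksum - sa)^2 * psum),
    variance = sum((i - mu_x)^2 * p))
}
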