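#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along each direction, restricted
#' to in-mask voxels (out-of-mask voxels break runs), and sums the per-
#' direction matrices over all given directions (the 13 unique 3D directions
#' by default).
#'
#' @param d A `discretized_roi` from [discretize_roi()].
#' @param directions Integer offset matrix, as [texture_directions_3d()].
#' @return Object of class `glrlm`: list with run-count matrix `r`
#'   (`Ng x Rmax`), total run count `Nr`, in-mask voxel count `n_voxels` and
#'   `n_directions`.
#' @export
compute_glrlm <- function(d, directions = texture_directions_3d()) {
  stopifnot(inherits(d, "discretized_roi"))
  if (is.null(dim(directions)) || nrow(directions) < 1L) {
    stop("'directions' must be a non-empty offset matrix")
  }
  lv <- d$levels
  Ng <- d$n_levels
  dd <- dim(lv)
  np <- sum(lv > 0L)
  if (np == 0L) stop("empty mask: no in-mask voxels")
  rmax <- max(dd)
  xv <- as.vector(slice.index(lv, 1))
  yv <- as.vector(slice.index(lv, 2))
  zv <- as.vector(slice.index(lv, 3))
  lvv <- as.vector(lv)
  S <- max(dd) + 1L
  counts <- numeric(Ng * rmax)
  for (k in seq_len(nrow(directions))) {
    o <- directions[k, ]
    first <- which(o != 0L)[1]
    tv <- switch(first, xv, yv, zv)
    # line id: project each voxel back along the direction to its line origin
    bx <- xv - tv * o[1] + S
    by <- yv - tv * o[2] + S
    bz <- zv - tv * o[3] + S
    id <- bx + 3 * S * (by + 3 * S * bz)
    ord <- order(id, tv)
    lvo <- lvv[ord]
    ido <- id[ord]
    grp <- cumsum(c(TRUE, ido[-1] != ido[-length(ido)]))
    runs <- rle(grp * (Ng + 1) + lvo)
    lev <- lvo[cumsum(runs$lengths)]
    len <- runs$lengths
    keep <- lev > 0L
    if (any(keep)) {
      counts <- counts + tabulate(lev[keep] + (len[keep] - 1L) * Ng,
                                  nbins = Ng * rmax)
    }
  }
  r <- matrix(counts, Ng, rmax)
  structure(list(r = r, Nr = sum(r), n_voxels = np,
                 n_directions = nrow(directions)),
            class = "glrlm")
}

glrlm_feature_names <- function() {
  c("SRE", "LRE", "GLN", "RLN", "RP",
    "LGRE", "HGRE", "SRLGLE", "SRHGLE", "LRLGLE", "LRHGLE")
}

#' Run-length features of a run-length matrix
#'
#' The 11-feature GLRLM set of the catalog: short/long-run emphasis (SRE,
#' LRE), gray-level and run-length non-uniformity (GLN, RLN), run percentage
#' (RP, runs per in-mask voxel and direction), low/high gray-level run
#' emphasis (LGRE, HGRE) and the four joint emphases, including
#' SRLGLE = sum r(i,j) / (i^2 j^2) / Nr.
#'
#' @param m A `glrlm` from [compute_glrlm()].
#' @return Named numeric vector of length 11.
#' @export
glrlm_features <- function(m) {
  stopifnot(inherits(m, "glrlm"))
  if (m$Nr <= 0) stop("run-length matrix has no runs")
  r <- m$r
  nr <- m$Nr
  i <- row(r)   # gray level
  j <- col(r)   # run length
  ri <- rowSums(r)
  rj <- colSums(r)
  c(SRE = sum(r / j^2) / nr,
    LRE = sum(r * j^2) / nr,
    GLN = sum(ri^2) / nr,
    RLN = sum(rj^2) / nr,
    RP = nr / (m$n_voxels * m$n_directions),
    LGRE = sum(r / i^2) / nr,
    HGRE = sum(r * i^2) / nr,
    SRLGLE = sum(r / (i^2 * j^2)) / nr,
    SRHGLE = sum(r * i^2 / j^2) / nr,
    LRLGLE = sum(r * j^2 / i^2) / nr,
    LRHGLE = sum(r * i^2 * j^2) / nr)
}
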