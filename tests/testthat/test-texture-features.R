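make_glcm <- function(p) structure(list(p = p, Ng = nrow(p)), class = "glcm")
make_glrlm <- function(r, n_voxels, n_directions = 1L) {
  structure(list(r = r, Nr = sum(r), n_voxels = n_voxels,
                 n_directions = n_directions), class = "glrlm")
}

test_that("GLCM accumulation is symmetric, normalized and matches exhaustive enumeration", {
  # single in-mask pair along z: half the mass at (1,2), half at (2,1)
  vals <- array(c(0, 1), c(1, 1, 2))
  d <- discretize_roi(image_volume(vals), roi_mask(array(TRUE, c(1, 1, 2))), 2)
  g <- compute_glcm(d)
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # uniform single-level ROI: all mass at (1,1)
  du <- discretize_roi(image_volume(array(5, c(3, 3, 3))),
                       roi_mask(array(TRUE, c(3, 3, 3))), 4)
  expect_equal(compute_glcm(du)$p[1, 1], 1)

  # random 4x4x4 against the brute-force pair-count oracle
  fx <- random_discretized_roi(c(4, 4, 4), 4, seed = 31)
  g4 <- compute_glcm(fx$d)
  expect_equal(sum(g4$p), 1, tolerance = 1e-9)
  expect_equal(g4$p, t(g4$p))
  expect_equal(g4$p,
               oracle_glcm(fx$d$levels, 4, texture_directions_3d()),
               tolerance = 1e-12)

  # distance > 1 also matches the oracle
  fx2 <- random_discretized_roi(c(5, 5, 5), 3, seed = 77)
  expect_equal(compute_glcm(fx2$d, distance = 2)$p,
               oracle_glcm(fx2$d$levels, 3, texture_directions_3d(), 2),
               tolerance = 1e-12)
})

test_that("GLCM features obey hand-computed values and degenerate conventions", {
  # uniform diagonal matrix: homogeneity1 = 1
  diag4 <- make_glcm(diag(4) / 4)
  f <- glcm_features(diag4)
  expect_equal(unname(f["homogeneity1"]), 1)
  expect_equal(unname(f["contrast"]), 0)

  # independence (outer product of marginals): IMC1 = 0
  px <- c(0.2, 0.3, 0.5)
  ind <- make_glcm(outer(px, px))
  expect_equal(unname(glcm_features(ind)["IMC1"]), 0, tolerance = 1e-12)

  # hand evaluation on the flat 2-level matrix
  flat <- make_glcm(matrix(0.25, 2, 2))
  ff <- glcm_features(flat)
  expect_equal(unname(ff["correlation"]), 0)
  expect_equal(unname(ff["inverse_variance"]), 0.5)
  expect_equal(unname(ff["energy"]), 0.25)
  expect_equal(unname(ff["entropy"]), 2)

  # degenerate marginals: all mass at one level
  degen <- make_glcm(matrix(c(1, 0, 0, 0), 2, 2))
  fd <- glcm_features(degen)
  expect_equal(unname(fd["correlation"]), 1)
  expect_equal(unname(fd["IMC1"]), 0)

  expect_length(f, 24)
  expect_named(f, radprog:::glcm_feature_names())
})

test_that("GLRLM counts maximal in-mask runs and matches exhaustive enumeration", {
  # a single 3-voxel run along the scan direction
  vals <- array(1, c(1, 1, 3))
  d <- discretize_roi(image_volume(vals), roi_mask(array(TRUE, c(1, 1, 3))), 2)
  g <- compute_glrlm(d, directions = rbind(c(0L, 0L, 1L)))
  expect_equal(g$r[1, 3], 1)
  expect_equal(g$Nr, 1)

  # checkerboard slice: along axis directions every run has length 1
  cb <- array(0, c(4, 4, 1))
  cb[, , 1] <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  dcb <- discretize_roi(image_volume(cb), roi_mask(array(TRUE, c(4, 4, 1))), 2)
  gcb <- compute_glrlm(dcb, directions = rbind(c(1L, 0L, 0L), c(0L, 1L, 0L)))
  expect_equal(sum(gcb$r[, 1]), 32)       # 16 voxels x 2 directions
  expect_equal(sum(gcb$r[, -1]), 0)

  # random 4x4x4 with mask holes against the brute-force scan oracle
  fx <- random_discretized_roi(c(4, 4, 4), 3, seed = 13, p_mask = 0.75)
  got <- compute_glrlm(fx$d)
  ref <- oracle_glrlm(fx$d$levels, 3, texture_directions_3d())
  expect_equal(got$r, ref)
  expect_equal(got$Nr, sum(ref))
})

test_that("GLRLM features match their defining sums", {
  # single run, level 1, length 1: SRLGLE = 1
  r1 <- matrix(0, 2, 3); r1[1, 1] <- 1
  expect_equal(unname(glrlm_features(make_glrlm(r1, 1))["SRLGLE"]), 1)

  # single run, level 2, length 2: SRLGLE = 1/16
  r2 <- matrix(0, 2, 3); r2[2, 2] <- 1
  expect_equal(unname(glrlm_features(make_glrlm(r2, 2))["SRLGLE"]), 1 / 16)

  # random small matrix against direct summation
  set.seed(4)
  rr <- matrix(rpois(12, 3), 3, 4)
  rr[1, 1] <- rr[1, 1] + 1
  m <- make_glrlm(rr, n_voxels = sum(rr * col(rr)), n_directions = 2L)
  f <- glrlm_features(m)
  nr <- sum(rr)
  i <- row(rr); j <- col(rr)
  expect_equal(unname(f["SRE"]), sum(rr / j^2) / nr)
  expect_equal(unname(f["LRHGLE"]), sum(rr * i^2 * j^2) / nr)
  expect_equal(unname(f["GLN"]), sum(rowSums(rr)^2) / nr)
  expect_equal(unname(f["RP"]), nr / (m$n_voxels * 2))
  expect_length(f, 11)
})

test_that("first-order features match direct summation and handle constants", {
  cvol <- image_volume(array(3.5, c(3, 3, 3)))
  cmask <- roi_mask(array(TRUE, c(3, 3, 3)))
  fc <- firstorder_features(cvol, cmask)
  expect_equal(unname(fc[c("mean", "median", "minimum", "maximum")]),
               rep(3.5, 4))
  expect_equal(unname(fc["variance"]), 0)
  expect_equal(unname(fc[c("skewness", "kurtosis")]), c(0, 0))
  expect_equal(unname(fc["entropy"]), 0)
  expect_equal(unname(fc["uniformity"]), 1)

  vals <- array(0, c(4, 1, 1)); vals[, 1, 1] <- 1:4
  f4 <- firstorder_features(image_volume(vals),
                            roi_mask(array(TRUE, c(4, 1, 1))))
  expect_equal(unname(f4["mean"]), 2.5)
  expect_equal(unname(f4["range"]), 3)

  set.seed(88)
  rv <- array(rnorm(200, 50, 12), c(10, 5, 4))
  rm <- array(runif(200) < 0.6, c(10, 5, 4)); rm[1] <- TRUE
  vol <- image_volume(rv, c(0.9, 0.9, 4))
  f <- firstorder_features(vol, roi_mask(rm))
  ref <- oracle_firstorder(rv[rm], prod(c(0.9, 0.9, 4)))
  expect_equal(f, ref, tolerance = 1e-12)
  expect_length(f, 19)
})

test_that("shape features: voxel volumes are exact and a digitized ball is near-spherical", {
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  s1 <- shape_features(roi_mask(m1), c(1, 1, 1))
  expect_equal(unname(s1["volume_mm3"]), 1)

  m8 <- array(FALSE, c(4, 4, 4)); m8[2:3, 2:3, 2:3] <- TRUE
  s8 <- shape_features(roi_mask(m8), c(1, 1, 1))
  expect_equal(unname(s8["volume_mm3"]), 8)
  expect_equal(unname(s8["max_3d_diameter_mm"]), sqrt(3))

  # anisotropic spacing scales the volume
  s8a <- shape_features(roi_mask(m8), c(1, 1, 4))
  expect_equal(unname(s8a["volume_mm3"]), 32)

  xs <- (1:25) - 13
  ball <- array(outer(outer(xs^2, xs^2, "+"), xs^2, "+") <= 100, c(25, 25, 25))
  sb <- shape_features(roi_mask(ball), c(1, 1, 1))
  expect_gte(unname(sb["sphericity"]), 0.9)
  expect_lte(unname(sb["sphericity"]), 1.0)
  expect_equal(unname(sb["spherical_disproportion"]),
               1 / unname(sb["sphericity"]), tolerance = 1e-12)
  # axis lengths of a ball approximate its diameter and are ordered
  expect_true(all(diff(unname(sb[c("major_axis_length_mm",
                                   "minor_axis_length_mm",
                                   "least_axis_length_mm")])) <= 0))
})

test_that("the catalog enumerates 485 features per sequence with unique stable keys", {
  cat1 <- feature_catalog()
  expect_equal(nrow(cat1), 970)
  expect_equal(as.integer(table(cat1$sequence)), c(485L, 485L))
  expect_false(anyDuplicated(cat1$key) > 0)
  expect_identical(cat1$key, feature_catalog()$key)
  # per-family arithmetic: 11 shape + 19 first-order + 13 x (24 + 11)
  t2 <- cat1[cat1$sequence == "T2w", ]
  expect_equal(as.integer(table(t2$family)[c("shape", "firstorder", "GLCM", "GLRLM")]),
               c(11L, 19L, 24L * 13L, 11L * 13L))
  # the published signature keys exist in the catalog
  expect_true(all(published_radscore_model()$terms$key %in% cat1$key))
})

test_that("full extraction returns 970 finite values, honours catalog order and subsets", {
  pair <- generate_tumor_pair(small_cohort_config(), 0.5, seed = 2024)
  v <- extract_all(pair$volume_t2, pair$volume_cet1, pair$mask)
  expect_length(v, 970)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), feature_catalog()$key)

  cat_t2 <- feature_catalog(sequences = "T2w")
  v_t2 <- extract_all(pair$volume_t2, NULL, pair$mask, cat_t2)
  expect_length(v_t2, 485)
  expect_equal(v_t2, v[names(v_t2)])

  expect_error(extract_all(pair$volume_t2, NULL, pair$mask),
               "missing sequence.*CET1w")

  # permuting the catalog permutes the output identically
  cat_perm <- feature_catalog()
  set.seed(1); ord <- sample.int(nrow(cat_perm))
  cat_perm2 <- cat_perm[ord, ]
  attr(cat_perm2, "log_sigmas") <- attr(cat_perm, "log_sigmas")
  v_perm <- extract_all(pair$volume_t2, pair$volume_cet1, pair$mask, cat_perm2)
  expect_identical(names(v_perm), names(v)[ord])
  expect_equal(unname(v_perm), unname(v[ord]))
})

test_that("unfiltered-variant features depend only on in-mask voxels", {
  pair <- generate_tumor_pair(small_cohort_config(), 0.4, seed = 99)
  keys <- c("T2w_1_GLCM_contrast", "T2w_1_GLRLM_SRE",
            "T2w_1_firstorder_mean", "T2w_1_shape_volume_mm3",
            "CET1w_1_GLCM_homogeneity1")
  base <- radprog:::extract_feature_subset(pair$volume_t2, pair$volume_cet1,
                                           pair$mask, keys)
  t2 <- pair$volume_t2
  t2$values[!pair$mask$values] <- t2$values[!pair$mask$values] + 500
  ce <- pair$volume_cet1
  ce$values[!pair$mask$values] <- 0
  mod <- radprog:::extract_feature_subset(t2, ce, pair$mask, keys)
  expect_equal(mod, base, tolerance = 1e-12)
})

test_that("z-score normalization centres the discovery set and freezes statistics for validation", {
  set.seed(6)
  disc <- as.data.frame(matrix(rnorm(40 * 6, 10, 3), 40, 6))
  names(disc) <- paste0("T2w_1_GLCM_f", 1:6)
  disc[[6]] <- 2                      # zero-variance column
  out <- zscore_normalize(disc)
  z <- as.matrix(out$table)
  expect_lt(max(abs(colMeans(z[, 1:5]))), 1e-9)
  expect_equal(unname(apply(z[, 1:5], 2, sd)), rep(1, 5), tolerance = 1e-9)
  expect_true(out$stats$zero_variance[6])
  expect_true(all(z[, 6] == 0))

  val <- as.data.frame(matrix(rnorm(15 * 6, 14, 3), 15, 6))
  names(val) <- names(disc)
  zv <- as.matrix(zscore_normalize(val, stats = out$stats)$table)
  expect_gt(max(abs(colMeans(zv[, 1:5]))), 0.1)  # frozen stats, shifted data

  # documented sample-sd convention
  single <- data.frame(T2w_1_GLCM_x = c(2, 4, 6))
  zs <- zscore_normalize(single)$table[[1]]
  expect_equal(zs, c(-1, 0, 1))
})

test_that("volume correlation audit applies the published strength categories", {
  set.seed(12)
  n <- 200
  vol <- runif(n, 10, 50)
  # a permutation with Spearman rho exactly 0.55 on 9 points:
  # rho = 1 - 6*S/(n(n^2-1)) with S = sum of squared rank differences
  target_s <- round(0.075 * 9 * 80)   # 54
  perm <- NULL
  for (i in 1:20000) {
    cand <- sample(9)
    if (sum((cand - 1:9)^2) == target_s) { perm <- cand; break }
  }
  expect_false(is.null(perm))
  tab <- data.frame(
    T2w_1_GLCM_a = vol,
    T2w_1_GLCM_b = -vol,
    T2w_1_GLCM_c = rnorm(n),
    CET1w_1_GLCM_d = rep(1, n))
  audit <- volume_correlation_audit(tab, vol)
  pf <- audit$per_feature
  expect_equal(pf$rho[1], 1)
  expect_equal(pf$category[1], "very high")
  expect_equal(pf$category[2], "very high")   # category uses |rho|
  expect_equal(pf$category[3], "little if any")
  expect_true(pf$flagged[4])
  expect_equal(pf$category[4], "little if any")
  expect_equal(unname(audit$counts["T2w", "very high"]), 2L)

  aud9 <- volume_correlation_audit(
    data.frame(T2w_1_GLCM_m = as.numeric(perm),
               T2w_1_GLCM_n = as.numeric(9:1)), as.numeric(1:9))
  expect_equal(aud9$per_feature$rho[1], 0.55)
  expect_equal(aud9$per_feature$category[1], "moderate")
  expect_equal(aud9$per_feature$rho[2], -1)
})
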