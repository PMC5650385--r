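#' The deterministic feature catalog
#'
#' Enumerates, in a fixed order, every feature the extractor computes: per
#' sequence, 11 shape features and 19 first-order features on the original
#' image (variant 1), then 24 GLCM and 11 GLRLM features on each of the 13
#' image variants (original, 4 LoG scales, 8 wavelet subbands), giving
#' 11 + 19 + 35 x 13 = 485 features per sequence and 970 per patient. The
#' canonical key is `"{sequence}_{variant}_{family}_{name}"`, e.g.
#' `"T2w_3_GLCM_homogeneity1"`. The counts are asserted at build time.
#'
#' @param log_sigmas LoG widths defining variants 2..(1+k); default
#'   `c(1, 1.5, 2, 2.5)`.
#' @param sequences Sequence labels, default `c("T2w", "CET1w")`.
#' @return Data frame with columns `sequence`, `variant_index`, `family`,
#'   `feature_name`, `key`; attribute `log_sigmas` records the variant
#'   definition.
#' @export
feature_catalog <- function(log_sigmas = c(1, 1.5, 2, 2.5),
                            sequences = c("T2w", "CET1w")) {
  if (anyDuplicated(log_sigmas)) stop("'log_sigmas' must be distinct")
  log_sigmas <- sort(log_sigmas)
  n_var <- 1L + length(log_sigmas) + 8L
  rows <- list()
  for (seq_lab in sequences) {
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = seq_lab, variant_index = 1L, family = "shape",
      feature_name = shape_feature_names(), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = seq_lab, variant_index = 1L, family = "firstorder",
      feature_name = firstorder_feature_names(), stringsAsFactors = FALSE)
    for (v in seq_len(n_var)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seq_lab, variant_index = v, family = "GLCM",
        feature_name = glcm_feature_names(), stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seq_lab, variant_index = v, family = "GLRLM",
        feature_name = glrlm_feature_names(), stringsAsFactors = FALSE)
    }
  }
  cat_df <- do.call(rbind, rows)
  cat_df$key <- paste(cat_df$sequence, cat_df$variant_index, cat_df$family,
                      cat_df$feature_name, sep = "_")
  if (anyDuplicated(cat_df$key)) stop("catalog keys are not unique")
  per_seq <- table(cat_df$sequence)
  expected <- 11L + 19L + 35L * n_var
  if (length(log_sigmas) == 4L) {
    stopifnot(expected == 485L, all(per_seq == 485L),
              nrow(cat_df) == 485L * length(sequences))
  } else {
    stopifnot(all(per_seq == expected))
  }
  attr(cat_df, "log_sigmas") <- log_sigmas
  cat_df
}

#' Extract every catalog feature for one patient
#'
#' Runs the full pipeline for one patient: builds the 13 image variants per
#' sequence, discretizes each within the tumor mask, and computes shape,
#' first-order, GLCM and GLRLM features in catalog order. With both
#' sequences and the default catalog this yields exactly 970 named values
#' (485 per sequence).
#'
#' @param volume_t2,volume_cet1 The two [image_volume()] sequences; pass
#'   `NULL` to extract a single sequence (the catalog must then list only
#'   the present one).
#' @param mask An [roi_mask()] aligned with both volumes.
#' @param catalog A [feature_catalog()].
#' @param n_bins Gray levels for discretization (default 32).
#' @param distance GLCM co-occurrence distance in voxels (default 1).
#' @return Named numeric vector ordered exactly as `catalog$key`.
#' @export
extract_all <- function(volume_t2, volume_cet1, mask,
                        catalog = feature_catalog(), n_bins = 32L,
                        distance = 1L) {
  stopifnot(is_roi_mask(mask))
  vols <- list(T2w = volume_t2, CET1w = volume_cet1)
  need <- unique(catalog$sequence)
  missing_seq <- need[vapply(vols[need], is.null, logical(1))]
  if (length(missing_seq)) {
    stop("missing sequence volume(s): ", paste(missing_seq, collapse = ", "))
  }
  sigmas <- attr(catalog, "log_sigmas")
  out <- stats::setNames(rep(NA_real_, nrow(catalog)), catalog$key)
  for (seq_lab in need) {
    vol <- vols[[seq_lab]]
    stopifnot(is_image_volume(vol))
    check_aligned(vol, mask)
    variants <- build_variant_set(vol, sigmas)
    sub <- catalog[catalog$sequence == seq_lab, ]
    sh <- shape_features(mask, vol$spacing_mm)
    fo <- firstorder_features(vol, mask, n_bins)
    for (v in unique(sub$variant_index[sub$family %in% c("GLCM", "GLRLM")])) {
      dz <- discretize_roi(variants[[v]]$image, mask, n_bins)
      gl <- glcm_features(compute_glcm(dz, distance = distance))
      rl <- glrlm_features(compute_glrlm(dz))
      out[paste(seq_lab, v, "GLCM", names(gl), sep = "_")] <- gl
      out[paste(seq_lab, v, "GLRLM", names(rl), sep = "_")] <- rl
    }
    out[paste(seq_lab, 1L, "shape", names(sh), sep = "_")] <- sh
    out[paste(seq_lab, 1L, "firstorder", names(fo), sep = "_")] <- fo
  }
  if (anyNA(out)) stop("internal error: catalog entries left uncomputed")
  out
}

#' Extract the feature table for a whole cohort
#'
#' @param cohort A `radprog_cohort` from [generate_cohort()].
#' @param catalog A [feature_catalog()].
#' @param n_bins,distance Passed to [extract_all()].
#' @param verbose Print a progress line per patient.
#' @return Data frame: `patient_id` column plus one column per catalog key.
#' @export
extract_cohort_features <- function(cohort, catalog = feature_catalog(),
                                    n_bins = 32L, distance = 1L,
                                    verbose = FALSE) {
  stopifnot(inherits(cohort, "radprog_cohort"))
  rows <- lapply(cohort$patients, function(p) {
    if (verbose) message("extracting ", p$patient_id)
    extract_all(p$volume_t2, p$volume_cet1, p$mask, catalog,
                n_bins = n_bins, distance = distance)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(patient_id = vapply(cohort$patients, `[[`, "", "patient_id"),
             tab, check.names = FALSE, stringsAsFactors = FALSE)
}
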