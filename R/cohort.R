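default_clinical_ranges <- function() {
  list(age = list(mean = 44, sd = 9, min = 18, max = 80),
       p_male = 0.76,
       p_stage_iv = 0.33,
       hemoglobin = list(mean = 170, sd = 28, min = 60),
       platelets = list(mean = 150, sd = 40, min = 40))
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size and
#' 70/30 discovery/validation split, grid geometry, the planted prognostic
#' texture features with their per-SD log-hazard effects, the exponential
#' baseline hazard and censoring window, and the marginal clinical
#' distributions.
#'
#' @param n_patients Cohort size (default 100, >= 4).
#' @param discovery_fraction Fraction allocated to the discovery set,
#'   in (0, 1); default 0.7.
#' @param seed Integer master seed; every generator output is a pure
#'   function of the configuration including this seed.
#' @param grid_shape Voxel counts per axis.
#' @param voxel_spacing_mm Positive voxel spacings (mm); the default
#'   represents an axial acquisition with thick slices.
#' @param planted_features Catalog keys of the five planted prognostic
#'   features. The defaults are texture descriptors with distinct
#'   functional forms (co-occurrence asymmetry, intensity kurtosis,
#'   co-occurrence mode probability) chosen so that no other catalog
#'   feature nearly duplicates them, which makes the planted signal
#'   statistically attributable to these exact columns.
#' @param effect_sizes Log-hazard per SD of each planted feature (same
#'   length as `planted_features`); the default signs make the combined
#'   linear predictor increase with tumor heterogeneity (the maximum-
#'   probability features fall as heterogeneity rises, hence their
#'   negative effects).
#' @param baseline_hazard Exponential baseline hazard, events/month.
#' @param censor_window_months Maximum follow-up; dropout occurs uniformly
#'   in the upper three quarters of the window.
#' @param clinical_ranges Per-covariate marginal distributions (see
#'   `default_clinical_ranges`).
#' @param n_bins,log_sigmas Discretization and variant options used when
#'   computing the planted features.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          discovery_fraction = 0.7,
                          seed = 101L,
                          grid_shape = c(28L, 28L, 14L),
                          voxel_spacing_mm = c(1, 1, 4),
                          planted_features = c("T2w_8_GLCM_cluster_shade",
                                               "CET1w_11_GLCM_cluster_shade",
                                               "T2w_1_firstorder_kurtosis",
                                               "CET1w_6_GLCM_maximum_probability",
                                               "T2w_4_GLCM_maximum_probability"),
                          effect_sizes = c(1, 1, 1, -1, -1),
                          baseline_hazard = 0.012,
                          censor_window_months = 80,
                          clinical_ranges = default_clinical_ranges(),
                          n_bins = 32L,
                          log_sigmas = c(1, 1.5, 2, 2.5)) {
  stopifnot(n_patients >= 4L,
            discovery_fraction > 0, discovery_fraction < 1,
            length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0),
            length(effect_sizes) == length(planted_features),
            baseline_hazard > 0, censor_window_months > 0)
  structure(list(n_patients = as.integer(n_patients),
                 discovery_fraction = discovery_fraction,
                 seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 n_planted_features = length(planted_features),
                 planted_features = planted_features,
                 effect_sizes = as.numeric(effect_sizes),
                 baseline_hazard = baseline_hazard,
                 censor_window_months = censor_window_months,
                 clinical_ranges = clinical_ranges,
                 n_bins = as.integer(n_bins),
                 log_sigmas = log_sigmas),
            class = "cohort_config")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate one synthetic tumor pair
#'
#' Builds one ellipsoidal tumor mask and two aligned intensity volumes
#' (T2w-like and CET1w-like). Intratumoral texture is a Gaussian random
#' field whose correlation length shrinks, and whose contrast grows, with
#' `latent_heterogeneity`, so co-occurrence features such as GLCM
#' homogeneity respond monotonically to the latent: homogeneous tumors
#' (latent near 0) have smooth, strongly correlated texture, heterogeneous
#' tumors (latent near 1) fine-grained high-contrast texture.
#'
#' @param config A [cohort_config()].
#' @param latent_heterogeneity Value in [0, 1].
#' @param seed Optional integer; when given the output is a pure function
#'   of (config, latent_heterogeneity, seed).
#' @return List with `volume_t2`, `volume_cet1` ([image_volume()]) and
#'   `mask` ([roi_mask()]).
#' @export
generate_tumor_pair <- function(config, latent_heterogeneity, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"),
            is.finite(latent_heterogeneity),
            latent_heterogeneity >= 0, latent_heterogeneity <= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- config$grid_shape
  h <- latent_heterogeneity

  # ellipsoid mask with jittered centre and semi-axes ~1/3 of the grid;
  # reject grids that cannot contain the largest possible ellipsoid
  semi_max <- c(0.36, 0.36, 0.34) * d
  if (any((d + 1) / 2 + 1 + semi_max > d - 0.5)) {
    stop("grid too small to contain the tumor ellipsoid; enlarge 'grid_shape'")
  }
  centre <- (d + 1) / 2 + stats::runif(3, -1, 1)
  semi <- c(stats::runif(2, 0.26, 0.36) * d[1:2], stats::runif(1, 0.24, 0.34) * d[3])
  xs <- (seq_len(d[1]) - centre[1]) / semi[1]
  ys <- (seq_len(d[2]) - centre[2]) / semi[2]
  zs <- (seq_len(d[3]) - centre[3]) / semi[3]
  rr <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  mask <- roi_mask(rr <= 1)

  # Texture model: a shared heterogeneity-driven band (correlation length
  # shrinks and contrast grows with the latent) mixed with independent
  # per-sequence fine and coarse band amplitudes. The shared band makes
  # co-occurrence features respond monotonically to the latent; the
  # independent band amplitudes give the two sequences and the different
  # filter scales partially independent texture variation, so distinct
  # catalog features carry distinct signal components.
  make_volume <- function(label, base) {
    ell <- 2.6 - 2.1 * h                       # shared correlation length (voxels)
    u_fine <- stats::runif(1, 0.5, 1.5)        # independent band amplitudes
    u_coarse <- stats::runif(1, 0.5, 1.5)
    grf <- function(sig) {
      f <- gaussian_smooth_3d(array(stats::rnorm(prod(d)), d),
                              c(sig, sig, sig / 2))
      f / stats::sd(f)
    }
    field <- (1 + 1.4 * h) * grf(ell) +
      0.55 * u_fine * grf(0.7) +
      0.65 * u_coarse * grf(3.2)
    field <- field / stats::sd(field)
    amp <- base * (0.07 + 0.18 * h)            # overall texture contrast
    v <- base + amp * field + stats::rnorm(prod(d), 0, base * 0.008)
    image_volume(array(v, d), config$voxel_spacing_mm, label)
  }
  list(volume_t2 = make_volume("T2w", 300),
       volume_cet1 = make_volume("CET1w", 420),
       mask = mask)
}

#' Simulate right-censored progression-free survival
#'
#' Proportional-hazards generator: event times are exponential with rate
#' `baseline_hazard * exp(linear_predictor)` (inverse-transform sampling);
#' follow-up ends at a dropout time drawn uniformly from the upper three
#' quarters of the censoring window, censoring the record if progression
#' has not occurred by then.
#'
#' @param linear_predictor Finite log-hazard offset(s); vectorized.
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return Data frame with `time_months` (> 0) and `event` (1 progression,
#'   0 censored), one row per element of `linear_predictor`.
#' @export
simulate_survival <- function(linear_predictor, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!all(is.finite(linear_predictor))) {
    stop("non-finite linear predictor")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(linear_predictor)
  rate <- config$baseline_hazard * exp(linear_predictor)
  t_event <- stats::rexp(n) / rate
  dropout <- stats::runif(n, 0.25, 1) * config$censor_window_months
  data.frame(time_months = pmin(t_event, dropout),
             event = as.integer(t_event <= dropout))
}

parse_catalog_key <- function(keys) {
  m <- regmatches(keys,
    regexec("^(T2w|CET1w)_([0-9]+)_(GLCM|GLRLM|shape|firstorder)_(.+)$", keys))
  bad <- lengths(m) != 5L
  if (any(bad)) stop("malformed catalog key(s): ", paste(keys[bad], collapse = ", "))
  data.frame(key = keys,
             sequence = vapply(m, `[`, "", 2),
             variant_index = as.integer(vapply(m, `[`, "", 3)),
             family = vapply(m, `[`, "", 4),
             feature_name = vapply(m, `[`, "", 5),
             stringsAsFactors = FALSE)
}

# Compute only the features named by 'keys' (used for the planted signal;
# avoids a full 970-feature extraction per patient at generation time).
extract_feature_subset <- function(volume_t2, volume_cet1, mask, keys,
                                   log_sigmas = c(1, 1.5, 2, 2.5),
                                   n_bins = 32L, distance = 1L) {
  info <- parse_catalog_key(keys)
  vols <- list(T2w = volume_t2, CET1w = volume_cet1)
  out <- stats::setNames(rep(NA_real_, length(keys)), keys)
  for (seq_lab in unique(info$sequence)) {
    vol <- vols[[seq_lab]]
    sub <- info[info$sequence == seq_lab, ]
    variants <- NULL
    for (v in unique(sub$variant_index[sub$family %in% c("GLCM", "GLRLM")])) {
      if (is.null(variants)) variants <- build_variant_set(vol, log_sigmas)
      dz <- discretize_roi(variants[[v]]$image, mask, n_bins)
      fams <- unique(sub$family[sub$variant_index == v])
      if ("GLCM" %in% fams) {
        gl <- glcm_features(compute_glcm(dz, distance = distance))
        sel <- sub$family == "GLCM" & sub$variant_index == v
        out[sub$key[sel]] <- gl[sub$feature_name[sel]]
      }
      if ("GLRLM" %in% fams) {
        rl <- glrlm_features(compute_glrlm(dz))
        sel <- sub$family == "GLRLM" & sub$variant_index == v
        out[sub$key[sel]] <- rl[sub$feature_name[sel]]
      }
    }
    if (any(sub$family == "shape")) {
      sh <- shape_features(mask, vol$spacing_mm)
      sel <- sub$family == "shape"
      out[sub$key[sel]] <- sh[sub$feature_name[sel]]
    }
    if (any(sub$family == "firstorder")) {
      fo <- firstorder_features(vol, mask, n_bins)
      sel <- sub$family == "firstorder"
      out[sub$key[sel]] <- fo[sub$feature_name[sel]]
    }
  }
  out
}

draw_clinical <- function(n, ranges) {
  rtrunc_norm <- function(n, spec, lo = spec$min, hi = Inf) {
    x <- stats::rnorm(n, spec$mean, spec$sd)
    pmin(pmax(x, lo), hi)
  }
  data.frame(
    age = round(rtrunc_norm(n, ranges$age, ranges$age$min, ranges$age$max)),
    sex = ifelse(stats::runif(n) < ranges$p_male, "male", "female"),
    stage = ifelse(stats::runif(n) < ranges$p_stage_iv, "IV", "III"),
    hemoglobin = round(rtrunc_norm(n, ranges$hemoglobin), 1),
    platelets = round(rtrunc_norm(n, ranges$platelets), 1),
    stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Generates `n_patients` synthetic patients: tumor image pairs with a
#' per-patient latent heterogeneity drawn uniformly on [0, 1], clinical
#' covariates drawn independently of the hazard (the reference conditions
#' treat the clinical factors as non-prognostic), progression-free survival
#' whose log-hazard is the sum of the z-scored planted texture features
#' weighted by `effect_sizes`, and a seeded random discovery/validation
#' split with `round(n * discovery_fraction)` discovery patients
#' (round half up).
#'
#' @param config A [cohort_config()].
#' @return Object of class `radprog_cohort`: list with `config`, `patients`
#'   (each holding `patient_id`, volumes, `mask`, `latent_heterogeneity`),
#'   `clinical` (data frame including `pfs_months`, `event`, `split`),
#'   `planted` (n x k matrix of raw planted feature values) and
#'   `linear_predictor`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  set.seed(config$seed)
  latent <- stats::runif(n)
  patient_seeds <- sample.int(2^30, n + 2L)
  clinical <- draw_clinical(n, config$clinical_ranges)

  patients <- vector("list", n)
  planted <- matrix(NA_real_, n, config$n_planted_features,
                    dimnames = list(NULL, config$planted_features))
  for (i in seq_len(n)) {
    pair <- generate_tumor_pair(config, latent[i], seed = patient_seeds[i])
    planted[i, ] <- extract_feature_subset(
      pair$volume_t2, pair$volume_cet1, pair$mask, config$planted_features,
      log_sigmas = config$log_sigmas, n_bins = config$n_bins)
    patients[[i]] <- list(patient_id = sprintf("P%03d", i),
                          volume_t2 = pair$volume_t2,
                          volume_cet1 = pair$volume_cet1,
                          mask = pair$mask,
                          latent_heterogeneity = latent[i])
  }
  z <- scale(planted)
  lp <- as.numeric(z %*% config$effect_sizes)
  surv <- simulate_survival(lp, config, seed = patient_seeds[n + 1L])

  set.seed(patient_seeds[n + 2L])
  n_disc <- as.integer(floor(n * config$discovery_fraction + 0.5))
  split <- rep("validation", n)
  split[sample.int(n)[seq_len(n_disc)]] <- "discovery"

  clinical <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                         clinical,
                         pfs_months = surv$time_months,
                         event = surv$event,
                         split = split,
                         stringsAsFactors = FALSE)
  structure(list(config = config, patients = patients, clinical = clinical,
                 planted = planted, linear_predictor = lp),
            class = "radprog_cohort")
}

#' @export
print.radprog_cohort <- function(x, ...) {
  cat("Synthetic radiomics cohort:", length(x$patients), "patients (",
      sum(x$clinical$split == "discovery"), "discovery /",
      sum(x$clinical$split == "validation"), "validation ),",
      sum(x$clinical$event), "progression events\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes per-patient NIfTI volume and mask files, one clinical CSV and a
#' JSON manifest under `dir`.
#'
#' @param cohort A `radprog_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "radprog_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (p in cohort$patients) {
    base <- file.path(dir, p$patient_id)
    write_volume_nifti(p$volume_t2, paste0(base, "_T2w.nii.gz"))
    write_volume_nifti(p$volume_cet1, paste0(base, "_CET1w.nii.gz"))
    write_volume_nifti(p$mask, paste0(base, "_mask.nii.gz"))
    files[[p$patient_id]] <- paste0(p$patient_id,
                                    c("_T2w.nii.gz", "_CET1w.nii.gz", "_mask.nii.gz"))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  manifest <- list(n_patients = length(cohort$patients),
                   seed = cohort$config$seed,
                   grid_shape = cohort$config$grid_shape,
                   voxel_spacing_mm = cohort$config$voxel_spacing_mm,
                   files = files,
                   clinical = "clinical.csv")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
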