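# Shared fixtures. The reference cohort (the generator's default
# conditions) is expensive to build, so it is computed once per test run
# and shared across test files.

.fixture_env <- new.env(parent = emptyenv())

# a small, fast cohort configuration used by smoke/determinism tests
small_cohort_config <- function(n = 10L, seed = 404L, ...) {
  cohort_config(n_patients = n, seed = seed,
                grid_shape = c(18L, 18L, 14L), ...)
}

reference_fit <- function() {
  if (is.null(.fixture_env$ref)) {
    cfg <- cohort_config()
    cohort <- generate_cohort(cfg)
    features <- extract_cohort_features(cohort)
    disc <- cohort$clinical$split == "discovery"
    nz <- zscore_normalize(features[disc, ])
    model <- fit_lasso_cox(nz$table,
                           time = cohort$clinical$pfs_months[disc],
                           event = cohort$clinical$event[disc],
                           seed = 1L,
                           exclude = nz$stats$key[nz$stats$zero_variance])
    nzv <- zscore_normalize(features[!disc, ], stats = nz$stats)
    clin <- cohort$clinical
    z_all <- as.matrix(features[, -1])
    z_all[disc, ] <- as.matrix(nz$table[, -1])
    z_all[!disc, ] <- as.matrix(nzv$table[, -1])
    clin$radscore <- compute_radscore(z_all, model)
    .fixture_env$ref <- list(config = cfg, cohort = cohort,
                             features = features, model = model,
                             clinical = clin, disc = disc)
  }
  .fixture_env$ref
}

random_discretized_roi <- function(dims, n_bins, seed, p_mask = 0.8) {
  set.seed(seed)
  vals <- array(rnorm(prod(dims)), dims)
  mask <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(mask)) mask[1] <- TRUE
  list(vol = image_volume(vals), mask = roi_mask(mask),
       d = discretize_roi(image_volume(vals), roi_mask(mask), n_bins))
}
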