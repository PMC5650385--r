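#' Pipeline configuration
#'
#' Bundles the per-stage options of the end-to-end run: the synthetic
#' cohort configuration (or paths to pre-existing feature/clinical CSVs),
#' catalog options, selection options, and validation options.
#'
#' @param cohort A [cohort_config()] (ignored when `features_csv` is given).
#' @param features_csv,clinical_csv Optional paths to a pre-extracted
#'   feature table and clinical table; when given, the simulate/extract
#'   stages are skipped.
#' @param n_bins,log_sigmas Catalog options.
#' @param nfolds,lambda_rule,selection_seed Lasso-Cox options.
#' @param dichotomize Enter the Rad-score in model 2 as the risk group
#'   rather than the continuous score.
#' @param stepdown Backward AIC step-down in the Cox models.
#' @param out Optional output directory for the run report and tables.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            features_csv = NULL, clinical_csv = NULL,
                            n_bins = 32L, log_sigmas = c(1, 1.5, 2, 2.5),
                            nfolds = 10L, lambda_rule = "lambda.min",
                            selection_seed = 1L,
                            dichotomize = FALSE, stepdown = FALSE,
                            out = NULL) {
  structure(list(cohort = cohort, features_csv = features_csv,
                 clinical_csv = clinical_csv, n_bins = as.integer(n_bins),
                 log_sigmas = log_sigmas, nfolds = as.integer(nfolds),
                 lambda_rule = lambda_rule,
                 selection_seed = as.integer(selection_seed),
                 dichotomize = isTRUE(dichotomize),
                 stepdown = isTRUE(stepdown), out = out),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [pipeline_config()]
#'   and [cohort_config()] (under `cohort:`).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("[stage:config] config file not found: ", path)
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort
  cohort <- if (is.null(cohort_args)) cohort_config() else {
    do.call(cohort_config, cohort_args)
  }
  args <- y[setdiff(names(y), "cohort")]
  do.call(pipeline_config, c(list(cohort = cohort), args))
}

stage_stop <- function(stage, ...) stop("[stage:", stage, "] ", ...,
                                        call. = FALSE)

#' Run the full prognostic pipeline
#'
#' Orchestrates simulate, extract, normalize, fit-signature, score and
#' validate with one configuration. All statistics that must not leak
#' (normalization means/SDs, the signature, the risk cutoff) are estimated
#' on the discovery set only and applied frozen to the validation set;
#' validation outcomes are read only after the model is frozen. Cox models
#' 1 (clinical covariates only) and 2 (plus Rad-score) are refit separately
#' on the discovery and validation sets, and the stratified subgroup
#' analysis runs on the whole cohort.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr.
#' @return Object of class `radprog_report`: list with the configuration
#'   echo, catalog checksum, feature counts, selected terms, cutoff, the
#'   per-set model 1 / model 2 Cox tables, the subgroup table, Rad-scores
#'   and the stage log. Written as JSON (plus CSV tables) under
#'   `config$out` when set.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stages <- character()
  log_stage <- function(s) {
    stages <<- c(stages, s)
    if (verbose) message("[", format(Sys.time(), "%H:%M:%S"), "] stage: ", s)
  }
  catalog <- feature_catalog(config$log_sigmas)

  if (is.null(config$features_csv)) {
    log_stage("simulate")
    cohort <- generate_cohort(config$cohort)
    clinical <- cohort$clinical
    log_stage("extract")
    features <- extract_cohort_features(cohort, catalog,
                                        n_bins = config$n_bins,
                                        verbose = verbose)
  } else {
    log_stage("load")
    if (!file.exists(config$features_csv)) {
      stage_stop("load", "features CSV not found: ", config$features_csv)
    }
    if (is.null(config$clinical_csv) || !file.exists(config$clinical_csv)) {
      stage_stop("load", "clinical CSV not found: ",
                 if (is.null(config$clinical_csv)) "(not given)"
                 else config$clinical_csv)
    }
    features <- utils::read.csv(config$features_csv, check.names = FALSE)
    clinical <- utils::read.csv(config$clinical_csv, stringsAsFactors = FALSE)
  }
  if (!all(catalog$key %in% names(features))) {
    stage_stop("extract", "feature table does not cover the catalog")
  }

  disc <- clinical$split == "discovery"
  feat_mat <- features[, catalog$key]

  log_stage("normalize")
  norm_disc <- zscore_normalize(feat_mat[disc, ])
  norm_val <- zscore_normalize(feat_mat[!disc, , drop = FALSE],
                               stats = norm_disc$stats)

  log_stage("fit-signature")
  model <- fit_lasso_cox(norm_disc$table,
                         time = clinical$pfs_months[disc],
                         event = clinical$event[disc],
                         nfolds = config$nfolds,
                         lambda_rule = config$lambda_rule,
                         seed = config$selection_seed,
                         exclude = norm_disc$stats$key[norm_disc$stats$zero_variance])

  log_stage("score")
  z_all <- feat_mat
  z_all[disc, ] <- as.matrix(norm_disc$table)
  z_all[!disc, ] <- as.matrix(norm_val$table)
  clinical$radscore <- compute_radscore(z_all, model)
  clinical$risk_group <- as.character(assign_risk_group(clinical$radscore,
                                                        model))

  log_stage("validate")
  cox_tables <- list()
  fit_notes <- character()
  for (set_name in c("discovery", "validation")) {
    d <- clinical[clinical$split == set_name, ]
    for (with_rs in c(FALSE, TRUE)) {
      label <- paste0(set_name, "_", if (with_rs) "model2" else "model1")
      # a small validation set can make the full covariate model inestimable
      # (monotone separation); record the diagnostic and keep the other
      # model tables rather than aborting the run
      tab <- tryCatch(
        fit_cox_multivariate(d, include_radscore = with_rs,
                             dichotomize = config$dichotomize,
                             cutoff = model$cutoff,
                             stepdown = config$stepdown),
        error = function(e) {
          fit_notes <<- c(fit_notes,
                          paste0(label, ": ", conditionMessage(e)))
          NULL
        })
      if (is.null(tab)) next
      tab$set <- set_name
      attr(tab, "fit") <- NULL
      cox_tables[[label]] <- tab
    }
  }
  if (length(fit_notes)) {
    warning("some Cox models could not be fitted: ",
            paste(fit_notes, collapse = "; "))
  }
  subgroups <- stratified_km_analysis(clinical, model)

  checksum <- catalog_checksum(catalog)
  report <- structure(list(
    seed = config$cohort$seed,
    config = config,
    catalog_checksum = checksum,
    n_patients = nrow(clinical),
    n_features = nrow(catalog),
    n_features_per_sequence = nrow(catalog) / 2L,
    n_zero_variance = sum(norm_disc$stats$zero_variance),
    selected_terms = model$terms,
    intercept = model$intercept,
    cutoff = model$cutoff,
    cox = do.call(rbind, cox_tables),
    cox_fit_notes = fit_notes,
    subgroup_tests = subgroups$tests,
    radscores = clinical[, c("patient_id", "split", "radscore", "risk_group")],
    stages = stages,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "radprog_report")

  if (!is.null(config$out)) write_report(report, config$out)
  report
}

catalog_checksum <- function(catalog) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(catalog$key, f)
  unname(tools::md5sum(f))
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cox, file.path(dir, "cox_models.csv"),
                   row.names = FALSE)
  utils::write.csv(report$subgroup_tests, file.path(dir, "subgroup_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(report$radscores, file.path(dir, "radscores.csv"),
                   row.names = FALSE)
  json <- report
  json$config <- NULL
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' @export
print.radprog_report <- function(x, ...) {
  cat("radprog run report\n")
  cat("  patients:", x$n_patients, " features:", x$n_features, "\n")
  cat("  selected terms:", nrow(x$selected_terms),
      " cutoff:", format(x$cutoff), "\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}
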