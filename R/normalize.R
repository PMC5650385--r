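#' Z-score normalization with frozen statistics
#'
#' Transforms each feature column to mean 0 and standard deviation 1. When
#' `stats` is `NULL` the means and standard deviations are estimated on the
#' input (the discovery set) and returned so they can be applied frozen to a
#' validation set. Standard deviations use the sample (n-1) convention.
#' Zero-variance features are flagged in the returned statistics and their
#' normalized values set to 0; they are kept in the table so downstream code
#' can exclude them from selection explicitly.
#'
#' @param table Numeric matrix or data frame (rows = patients, columns =
#'   features; a `patient_id` column is carried through untouched).
#' @param stats Optional frozen statistics from a previous call.
#' @return List with `table` (normalized, same shape) and `stats` (data
#'   frame: `key`, `mean`, `sd`, `zero_variance`).
#' @export
zscore_normalize <- function(table, stats = NULL) {
  id <- NULL
  if (is.data.frame(table) && "patient_id" %in% names(table)) {
    id <- table$patient_id
    table <- table[, setdiff(names(table), "patient_id"), drop = FALSE]
  }
  x <- as.matrix(table)
  if (is.null(stats)) {
    if (nrow(x) < 2L) stop("need at least 2 rows to estimate statistics")
    mu <- colMeans(x)
    sd <- apply(x, 2, stats::sd)
    stats <- data.frame(key = colnames(x), mean = mu, sd = sd,
                        zero_variance = sd == 0, row.names = NULL,
                        stringsAsFactors = FALSE)
  } else {
    if (!all(colnames(x) %in% stats$key)) {
      stop("frozen statistics do not cover all features")
    }
    stats <- stats[match(colnames(x), stats$key), ]
  }
  sd_safe <- ifelse(stats$zero_variance, 1, stats$sd)
  z <- sweep(sweep(x, 2, stats$mean, "-"), 2, sd_safe, "/")
  z[, stats$zero_variance] <- 0
  out <- as.data.frame(z, check.names = FALSE)
  if (!is.null(id)) out <- data.frame(patient_id = id, out,
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE)
  list(table = out, stats = stats)
}

#' Correlation of features with tumor volume
#'
#' Spearman correlation of every feature against tumor volume, with the
#' strength categories little if any (|rho| 0-0.25), low (0.26-0.49),
#' moderate (0.50-0.69), high (0.70-0.89) and very high (0.90-1.0), plus
#' per-sequence category counts. Constant features have undefined rho and
#' are flagged and categorized as "little if any".
#'
#' @param table Feature table (matrix or data frame; optional `patient_id`
#'   column ignored), one row per patient.
#' @param volumes Numeric tumor volumes, one per patient.
#' @return List with `per_feature` (data frame: `key`, `rho`, `category`,
#'   `flagged`) and `counts` (sequence x category table).
#' @export
volume_correlation_audit <- function(table, volumes) {
  if (is.data.frame(table) && "patient_id" %in% names(table)) {
    table <- table[, setdiff(names(table), "patient_id"), drop = FALSE]
  }
  x <- as.matrix(table)
  if (nrow(x) < 3L) stop("need at least 3 patients")
  stopifnot(length(volumes) == nrow(x))
  rho <- suppressWarnings(
    as.numeric(stats::cor(x, volumes, method = "spearman")))
  flagged <- !is.finite(rho)
  cat_of <- function(a) {
    cut(a, breaks = c(-1e-9, 0.25, 0.495, 0.695, 0.895, 1 + 1e-9),
        labels = c("little if any", "low", "moderate", "high", "very high"))
  }
  category <- cat_of(abs(ifelse(flagged, 0, rho)))
  seq_lab <- sub("_.*$", "", colnames(x))
  per_feature <- data.frame(key = colnames(x), rho = rho,
                            category = as.character(category),
                            flagged = flagged, row.names = NULL,
                            stringsAsFactors = FALSE)
  counts <- base::table(sequence = seq_lab,
                        category = factor(per_feature$category,
                                          levels = levels(category)))
  list(per_feature = per_feature, counts = counts)
}
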