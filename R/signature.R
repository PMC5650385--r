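#' Rad-score model container
#'
#' A linear prognostic signature: selected catalog features with their
#' coefficients, a centering intercept, and the risk cutoff used to
#' dichotomize patients.
#'
#' @param terms Data frame with columns `key` (unique catalog keys) and
#'   `coefficient`.
#' @param intercept Finite centering constant.
#' @param cutoff Finite risk cutoff (high risk when score >= cutoff).
#' @param lambda Optional penalty at which the model was selected.
#' @return Object of class `radscore_model`.
#' @export
radscore_model <- function(terms, intercept, cutoff, lambda = NA_real_) {
  stopifnot(is.data.frame(terms), all(c("key", "coefficient") %in% names(terms)),
            !anyDuplicated(terms$key),
            is.finite(intercept), is.finite(cutoff))
  structure(list(terms = terms[, c("key", "coefficient")],
                 intercept = intercept, cutoff = cutoff, lambda = lambda),
            class = "radscore_model")
}

#' @export
print.radscore_model <- function(x, ...) {
  cat("Rad-score model:", nrow(x$terms), "terms, intercept",
      format(x$intercept), ", cutoff", format(x$cutoff), "\n")
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' The published five-feature Rad-score signature
#'
#' The reference signature shipped as a constant: five GLCM/GLRLM texture
#' features with their reported lasso-Cox coefficients, the reported
#' centering constant (-7.995) and the reported median risk cutoff
#' (-6.863). Scores at or above the cutoff are high risk.
#'
#' @return A [radscore_model()].
#' @examples
#' m <- published_radscore_model()
#' compute_radscore(setNames(numeric(5), m$terms$key), m)  # the intercept
#' @export
published_radscore_model <- function() {
  radscore_model(
    terms = data.frame(
      key = c("T2w_3_GLCM_homogeneity1",
              "CET1w_6_GLCM_IMC1",
              "CET1w_5_GLCM_correlation",
              "T2w_1_GLCM_inverse_variance",
              "T2w_1_GLRLM_SRLGLE"),
      coefficient = c(2.495, 1.474, -1.203, -0.809, -3.839),
      stringsAsFactors = FALSE),
    intercept = -7.995,
    cutoff = -6.863)
}

#' Fit a sparse prognostic signature by lasso-Cox regression
#'
#' L1-penalized Cox partial-likelihood regression on z-scored features with
#' the penalty chosen by seeded k-fold cross-validated partial-likelihood
#' deviance. Only features with non-zero coefficients enter the model. A
#' Cox model has no native intercept; the returned intercept centres the
#' linear predictor so the mean Rad-score on the fitting set equals
#' `offset`. The risk cutoff is the median Rad-score on the fitting set.
#'
#' @param x Numeric matrix or data frame of z-scored features (rows =
#'   patients); an optional `patient_id` column is ignored.
#' @param time,event Survival outcome (time > 0; event 1 = progression).
#' @param nfolds Cross-validation folds (default 10; reduced with a warning
#'   when there are fewer rows than folds).
#' @param lambda_rule `"lambda.min"` (default) or `"lambda.1se"`.
#' @param lambda_fixed Optional fixed penalty; when given, cross-validation
#'   is skipped and the model is extracted at this penalty.
#' @param seed Integer seed controlling the fold assignment.
#' @param offset Target mean Rad-score on the fitting set (default 0).
#' @param exclude Feature keys to exclude from selection (e.g. flagged
#'   zero-variance features).
#' @return A [radscore_model()] with attribute `"scores"` holding the
#'   fitting-set Rad-scores.
#' @export
fit_lasso_cox <- function(x, time, event, nfolds = 10L,
                          lambda_rule = c("lambda.min", "lambda.1se"),
                          lambda_fixed = NULL,
                          seed = 1L, offset = 0, exclude = character()) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.data.frame(x) && "patient_id" %in% names(x)) {
    x <- x[, setdiff(names(x), "patient_id"), drop = FALSE]
  }
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(time), length(time) == length(event))
  if (sum(event) < 2L) stop("need at least 2 events to fit a Cox model")
  keep <- setdiff(colnames(x), exclude)
  xs <- x[, keep, drop = FALSE]
  if (nrow(xs) < nfolds) {
    warning("fewer rows than folds; reducing nfolds to ", nrow(xs))
    nfolds <- nrow(xs)
  }
  y <- survival::Surv(time, event)
  set.seed(seed)
  if (is.null(lambda_fixed)) {
    cv <- glmnet::cv.glmnet(xs, y, family = "cox", nfolds = nfolds)
    lambda_used <- cv[[lambda_rule]]
    beta <- as.matrix(stats::coef(cv, s = lambda_rule))
  } else {
    fit <- glmnet::glmnet(xs, y, family = "cox")
    lambda_used <- lambda_fixed
    beta <- as.matrix(stats::coef(fit, s = lambda_fixed, exact = TRUE,
                                  x = xs, y = y))
  }
  nz <- which(beta[, 1] != 0)
  terms <- data.frame(key = rownames(beta)[nz], coefficient = beta[nz, 1],
                      row.names = NULL, stringsAsFactors = FALSE)
  lp <- if (nrow(terms)) {
    as.numeric(xs[, terms$key, drop = FALSE] %*% terms$coefficient)
  } else rep(0, nrow(xs))
  intercept <- offset - mean(lp)
  scores <- intercept + lp
  model <- radscore_model(terms, intercept, stats::median(scores),
                          lambda = lambda_used)
  attr(model, "scores") <- scores
  model
}

#' Compute the Rad-score
#'
#' The linear signature value: intercept plus the sum of each model
#' coefficient times the (normalized) feature value.
#'
#' @param features Named numeric vector for one patient, or a matrix/data
#'   frame (rows = patients) whose columns include every model term key.
#' @param model A [radscore_model()].
#' @return Numeric score(s).
#' @export
compute_radscore <- function(features, model) {
  stopifnot(inherits(model, "radscore_model"))
  if (is.data.frame(features)) {
    if ("patient_id" %in% names(features)) {
      features <- features[, setdiff(names(features), "patient_id"),
                           drop = FALSE]
    }
    features <- as.matrix(features)
  }
  if (is.null(dim(features))) features <- matrix(features, 1,
    dimnames = list(NULL, names(features)))
  missing_keys <- setdiff(model$terms$key, colnames(features))
  if (length(missing_keys)) {
    stop("feature vector is missing model term(s): ",
         paste(missing_keys, collapse = ", "))
  }
  as.numeric(model$intercept +
             features[, model$terms$key, drop = FALSE] %*% model$terms$coefficient)
}

#' Assign the risk group
#'
#' High risk when the Rad-score is greater than or equal to the model
#' cutoff, low risk otherwise.
#'
#' @param score Finite Rad-score(s).
#' @param model A [radscore_model()].
#' @return Factor with levels `low`, `high`.
#' @export
assign_risk_group <- function(score, model) {
  stopifnot(inherits(model, "radscore_model"), all(is.finite(score)))
  factor(ifelse(score >= model$cutoff, "high", "low"),
         levels = c("low", "high"))
}

#' Rank signature terms by coefficient magnitude
#'
#' @param model A [radscore_model()] with at least one term.
#' @return Data frame (`key`, `coefficient`, `abs_coefficient`) sorted by
#'   decreasing absolute coefficient.
#' @export
coefficient_magnitude_report <- function(model) {
  stopifnot(inherits(model, "radscore_model"), nrow(model$terms) >= 1L)
  out <- model$terms
  out$abs_coefficient <- abs(out$coefficient)
  out[order(-out$abs_coefficient), , drop = FALSE]
}

#' Serialize / read a Rad-score model as JSON
#'
#' @param model A [radscore_model()].
#' @param path Output JSON path.
#' @param stats Optional normalization statistics data frame to embed.
#' @return `path` (write) or a [radscore_model()] with attribute
#'   `"normalization"` (read).
#' @export
write_radscore_model <- function(model, path, stats = NULL) {
  obj <- list(terms = model$terms, intercept = model$intercept,
              cutoff = model$cutoff, lambda = model$lambda)
  if (!is.null(stats)) obj$normalization <- stats
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_radscore_model
#' @export
read_radscore_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- radscore_model(obj$terms, obj$intercept, obj$cutoff,
                      lambda = if (is.null(obj$lambda)) NA_real_ else obj$lambda)
  if (!is.null(obj$normalization)) attr(m, "normalization") <- obj$normalization
  m
}
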