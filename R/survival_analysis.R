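#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function; censored times reduce
#' the risk set without introducing steps.
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicators (1 progression, 0 censored).
#' @return Object of class `km_curve`: data frame with `time`, `n_risk`,
#'   `n_event`, `n_censor` and `survival` at the observed times.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event),
            all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test
#'
#' Chi-square comparison of survival distributions across k groups with
#' k - 1 degrees of freedom.
#'
#' @param time,event Survival outcome.
#' @param group Group labels; at least 2 non-empty groups.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
log_rank_test <- function(time, event, group) {
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) stop("need at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox proportional hazards model (model 1 / model 2)
#'
#' Fits the clinical covariates alone (model 1) or together with the
#' Rad-score (model 2) against progression-free survival, with Efron tie
#' handling, Wald 95% confidence intervals and p-values, and optional
#' backward elimination by the Akaike information criterion. The Rad-score
#' enters as the continuous score by default or dichotomized at the model
#' cutoff via `dichotomize`.
#'
#' @param data Data frame with columns `pfs_months`, `event`, the clinical
#'   covariates and (for model 2) `radscore`.
#' @param covariates Clinical covariate column names.
#' @param include_radscore Add the Rad-score term (model 2)?
#' @param dichotomize Use the risk group instead of the continuous score
#'   (requires `cutoff`).
#' @param cutoff Risk cutoff used when `dichotomize = TRUE`.
#' @param stepdown Backward AIC step-down (default off, so every covariate
#'   is reported).
#' @param ties Tie handling for the partial likelihood, `"efron"` (default,
#'   lower bias) or `"breslow"`.
#' @return Object of class `cox_result`: data frame with `model_label`,
#'   `covariate`, `HR`, `ci_low`, `ci_high`, `p_value`; the fitted `coxph`
#'   object is kept in attribute `"fit"`.
#' @export
fit_cox_multivariate <- function(data,
                                 covariates = c("age", "sex", "stage",
                                                "hemoglobin", "platelets"),
                                 include_radscore = FALSE,
                                 dichotomize = FALSE, cutoff = NULL,
                                 stepdown = FALSE,
                                 ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("pfs_months", "event") %in% names(data)))
  if (sum(data$event) < 2L) stop("need at least 2 events")
  df <- data
  terms <- covariates
  if (include_radscore) {
    stopifnot("radscore" %in% names(df))
    if (dichotomize) {
      if (is.null(cutoff)) stop("'cutoff' required when dichotomize = TRUE")
      df$risk_group <- factor(ifelse(df$radscore >= cutoff, "high", "low"),
                              levels = c("low", "high"))
      terms <- c(terms, "risk_group")
    } else {
      terms <- c(terms, "radscore")
    }
  }
  # drop zero-variance covariates
  keep <- vapply(terms, function(v) length(unique(df[[v]])) > 1L, logical(1))
  if (any(!keep)) {
    warning("dropping zero-variance covariate(s): ",
            paste(terms[!keep], collapse = ", "))
    terms <- terms[keep]
  }
  if (!length(terms)) stop("no usable covariates")
  fml <- stats::as.formula(paste("survival::Surv(pfs_months, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  if (stepdown) {
    fit <- stats::step(fit, direction = "backward", trace = 0)
  }
  cf <- stats::coef(fit)
  if (length(cf) == 0L) {
    res <- data.frame(model_label = character(), covariate = character(),
                      HR = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p_value = numeric())
  } else {
    if (any(!is.finite(cf)) || any(abs(cf) > 15)) {
      stop("Cox fit did not converge (separation suspected); coefficients: ",
           paste(round(cf, 2), collapse = ", "))
    }
    ci <- exp(stats::confint(fit))
    sm <- summary(fit)$coefficients
    res <- data.frame(
      model_label = if (include_radscore) "model2" else "model1",
      covariate = names(cf),
      HR = exp(cf),
      ci_low = ci[, 1],
      ci_high = ci[, 2],
      p_value = sm[, "Pr(>|z|)"],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  class(res) <- c("cox_result", "data.frame")
  attr(res, "fit") <- fit
  res
}

default_stratification_scheme <- function() {
  list(
    age = function(d) cut(d$age, c(-Inf, 40, 50, Inf),
                          labels = c("<=40", "40-50", ">50")),
    sex = function(d) factor(d$sex, levels = c("female", "male")),
    stage = function(d) factor(d$stage, levels = c("III", "IV")),
    hemoglobin = function(d) cut(d$hemoglobin, c(-Inf, 156, Inf),
                                 labels = c("<=156", ">156")),
    platelets = function(d) cut(d$platelets, c(-Inf, 158, Inf),
                                labels = c("<=158", ">158")))
}

#' Stratified Kaplan-Meier subgroup analysis
#'
#' For each clinical stratification variable (age <=40 / 40-50 / >50 years,
#' sex, overall stage III/IV, hemoglobin <=156 / >156 g/L, platelets
#' <=158 / >158 x 10^9/L): a log-rank test across its levels, then a
#' low-vs-high Rad-score log-rank test within each level, plus the overall
#' Rad-score split. Returns a long-format results table and the KM curves.
#'
#' @param data Data frame with `pfs_months`, `event`, the clinical columns
#'   and `radscore`.
#' @param model A [radscore_model()] providing the risk cutoff.
#' @param scheme Named list of functions mapping `data` to a factor; the
#'   default implements the reference subgroup thresholds.
#' @return List with `tests` (data frame: `stratum_variable`,
#'   `stratum_level`, `comparison`, `n`, `n_events`, `statistic`, `df`,
#'   `p_value`) and `curves` (named list of [km_estimate()] results per
#'   stratum level and risk group).
#' @export
stratified_km_analysis <- function(data, model,
                                   scheme = default_stratification_scheme()) {
  stopifnot(inherits(model, "radscore_model"),
            all(c("pfs_months", "event", "radscore") %in% names(data)))
  risk <- assign_risk_group(data$radscore, model)
  rows <- list()
  curves <- list()
  add_row <- function(var, level, comparison, idx, lr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stratum_variable = var, stratum_level = level, comparison = comparison,
      n = length(idx), n_events = sum(data$event[idx]),
      statistic = lr$statistic, df = lr$df, p_value = lr$p_value,
      stringsAsFactors = FALSE)
  }
  test_if_possible <- function(time, event, group) {
    g <- droplevels(as.factor(group))
    if (nlevels(g) < 2L) return(NULL)
    log_rank_test(time, event, g)
  }
  for (var in names(scheme)) {
    bins <- scheme[[var]](data)
    stopifnot(length(bins) == nrow(data), !anyNA(bins))
    lr <- test_if_possible(data$pfs_months, data$event, bins)
    if (!is.null(lr)) add_row(var, "(all)", "between_levels",
                              seq_len(nrow(data)), lr)
    for (lev in levels(droplevels(bins))) {
      idx <- which(bins == lev)
      lr2 <- test_if_possible(data$pfs_months[idx], data$event[idx], risk[idx])
      if (!is.null(lr2)) add_row(var, lev, "radscore_within_level", idx, lr2)
      for (rg in levels(risk)) {
        sel <- idx[risk[idx] == rg]
        if (length(sel)) {
          curves[[paste(var, lev, rg, sep = "|")]] <-
            km_estimate(data$pfs_months[sel], data$event[sel])
        }
      }
    }
  }
  lr_all <- test_if_possible(data$pfs_months, data$event, risk)
  if (!is.null(lr_all)) add_row("radscore", "(all)", "between_levels",
                                seq_len(nrow(data)), lr_all)
  list(tests = do.call(rbind, rows), curves = curves)
}
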