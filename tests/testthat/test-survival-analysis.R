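test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  all_cens <- km_estimate(c(2, 4, 6, 8), rep(0, 4))
  expect_true(all(all_cens$survival == 1))

  n <- 7
  one_event <- km_estimate(c(3, seq(4, length.out = n - 1)),
                           c(1, rep(0, n - 1)))
  expect_equal(one_event$survival[one_event$time == 3], 1 - 1 / n)

  # censoring reduces risk sets without steps; compare with the oracle
  time <- c(1, 2, 2.5, 3, 4.5, 5, 6.2, 7)
  event <- c(1, 0, 1, 1, 0, 1, 0, 1)
  km2 <- km_estimate(time, event)
  ref <- oracle_km(time, event)
  got <- km2[km2$n_event > 0, c("time", "survival")]
  expect_equal(got$time, ref$time)
  expect_equal(got$survival, ref$survival, tolerance = 1e-12)
  expect_true(all(diff(km2$survival) <= 1e-12))

  # with no censoring the estimator is 1 - ECDF
  t3 <- c(2, 5, 9, 11)
  km3 <- km_estimate(t3, rep(1, 4))
  expect_equal(km3$survival, 1 - ecdf(t3)(t3))
})

test_that("log-rank test matches hand computation and is null for identical groups", {
  time <- c(1, 2, 3, 1, 2, 3)
  event <- c(1, 1, 0, 1, 0, 1)
  same <- log_rank_test(c(time, time), c(event, event),
                        rep(c("a", "b"), each = 6))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  t6 <- c(1, 3, 5, 2, 4, 6)
  e6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- rep(c("A", "B"), each = 3)
  got <- log_rank_test(t6, e6, g6)
  ref <- oracle_logrank2(t6, e6, g6)
  expect_equal(got$statistic, ref$statistic, tolerance = 1e-9)
  expect_equal(got$p_value, ref$p_value, tolerance = 1e-9)
  expect_equal(got$df, 1)

  expect_error(log_rank_test(t6, e6, rep("A", 6)), "2 non-empty groups")
})

test_that("multivariate Cox models keep the model1/model2 covariate contract", {
  set.seed(77)
  n <- 160
  cfg <- cohort_config()
  clin <- radprog:::draw_clinical(n, radprog:::default_clinical_ranges())
  clin$radscore <- rnorm(n)
  surv <- simulate_survival(0.8 * clin$radscore, cfg, seed = 8)
  d <- data.frame(clin, pfs_months = surv$time_months, event = surv$event)

  m1 <- fit_cox_multivariate(d, include_radscore = FALSE)
  m2 <- fit_cox_multivariate(d, include_radscore = TRUE)
  expect_equal(m1$model_label[1], "model1")
  expect_equal(m2$model_label[1], "model2")
  expect_identical(setdiff(m2$covariate, m1$covariate), "radscore")
  expect_identical(setdiff(m1$covariate, m2$covariate), character(0))
  expect_true(all(m1$ci_low <= m1$HR & m1$HR <= m1$ci_high))

  # dichotomized mode replaces the continuous term by the risk group
  m2d <- fit_cox_multivariate(d, include_radscore = TRUE, dichotomize = TRUE,
                              cutoff = median(d$radscore))
  expect_true("risk_grouphigh" %in% m2d$covariate)
  expect_false("radscore" %in% m2d$covariate)

  # backward AIC step-down returns a subset of the full model terms
  m2s <- fit_cox_multivariate(d, include_radscore = TRUE, stepdown = TRUE)
  expect_true(all(m2s$covariate %in% m2$covariate))
  expect_true("radscore" %in% m2s$covariate)   # the true signal survives AIC

  # zero-variance covariate is dropped with a warning
  d$stage <- "III"
  expect_warning(fit_cox_multivariate(d), "zero-variance")

  expect_error(fit_cox_multivariate(d[d$event == 0, ]), "events")
})

test_that("partial-likelihood estimates are invariant to case duplication on tie-free data", {
  set.seed(15)
  n <- 80
  cfg <- cohort_config()
  clin <- radprog:::draw_clinical(n, radprog:::default_clinical_ranges())
  clin$radscore <- rnorm(n)
  surv <- simulate_survival(clin$radscore, cfg, seed = 16)
  d <- data.frame(clin, pfs_months = surv$time_months, event = surv$event)
  stopifnot(!anyDuplicated(d$pfs_months[d$event == 1]))  # tie-free source
  d2 <- rbind(d, d)

  # duplication creates within-pair ties, which only the tie approximation
  # sees: Breslow is exactly invariant, Efron nearly so
  f1b <- fit_cox_multivariate(d, covariates = "radscore", ties = "breslow")
  f2b <- fit_cox_multivariate(d2, covariates = "radscore", ties = "breslow")
  expect_equal(f2b$HR, f1b$HR, tolerance = 1e-8)

  f1e <- fit_cox_multivariate(d, covariates = "radscore")
  f2e <- fit_cox_multivariate(d2, covariates = "radscore")
  expect_equal(f2e$HR, f1e$HR, tolerance = 0.05)
})

test_that("stratified analysis partitions every patient and tests within subgroups", {
  ref <- reference_fit()
  res <- stratified_km_analysis(ref$clinical, ref$model)
  tests <- res$tests

  # age bins partition all patients
  age_rows <- tests[tests$stratum_variable == "age" &
                    tests$comparison == "radscore_within_level", ]
  expect_equal(sum(age_rows$n), nrow(ref$clinical))

  # every scheme variable produced a between-level test
  expect_setequal(
    unique(tests$stratum_variable),
    c("age", "sex", "stage", "hemoglobin", "platelets", "radscore"))

  # planted signal: the overall Rad-score split separates survival
  overall <- tests[tests$stratum_variable == "radscore" &
                   tests$stratum_level == "(all)", ]
  expect_lt(overall$p_value, 0.05)

  # KM curves exist and start at or below 1
  expect_gt(length(res$curves), 0)
  expect_true(all(vapply(res$curves, function(k) all(k$survival <= 1 + 1e-12),
                         TRUE)))
})

test_that("clinical subgroup log-rank p-values are uniform when covariates carry no signal", {
  set.seed(606)
  cfg <- cohort_config()
  dummy_model <- radscore_model(data.frame(key = "x", coefficient = 1), 0, 0)
  pvals <- numeric(0)
  for (r in 1:200) {
    clin <- radprog:::draw_clinical(100, radprog:::default_clinical_ranges())
    surv <- simulate_survival(rep(0, 100), cfg)
    clin$pfs_months <- surv$time_months
    clin$event <- surv$event
    clin$radscore <- rnorm(100)
    res <- stratified_km_analysis(clin, dummy_model)
    sel <- res$tests$comparison == "between_levels" &
      res$tests$stratum_variable != "radscore"
    pvals <- c(pvals, res$tests$p_value[sel])
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
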