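test_that("AUC equals the Mann-Whitney pair count", {
  r <- roc_with_cutoff(c(90, 80, 70, 60), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  r <- roc_with_cutoff(c(90, 60, 80, 70), c(1, 0, 1, 0))
  expect_equal(r$auc, pair_count_auc(c(90, 60, 80, 70), c(1, 0, 1, 0)))

  # all scores tied
  r <- roc_with_cutoff(rep(50, 8), c(1, 1, 1, 0, 0, 0, 0, 1))
  expect_equal(r$auc, 0.5)

  set.seed(51)
  for (i in 1:20) {
    sc <- sample(0:100, 30, replace = TRUE)
    st <- rbinom(30, 1, 0.4)
    if (length(unique(st)) < 2) next
    expect_equal(roc_with_cutoff(sc, st)$auc, pair_count_auc(sc, st))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(52)
  sc <- round(runif(40, 0, 100), 1)
  st <- rbinom(40, 1, 0.5)
  r <- roc_with_cutoff(sc, st)
  ref <- pROC::roc(st, sc, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
})

test_that("rank AUC equals the trapezoidal area under the empirical curve", {
  set.seed(53)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    sc <- sample(seq(0, 100, by = 2.5), n, replace = TRUE)
    st <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(st)) < 2) next
    r <- roc_with_cutoff(sc, st)
    cur <- r$curve[order(r$curve$fpr, r$curve$tpr), ]
    trap <- sum(diff(cur$fpr) * (head(cur$tpr, -1) + tail(cur$tpr, -1)) / 2)
    expect_equal(r$auc, trap)
    # complement symmetry with tie correction
    r_rev <- roc_with_cutoff(100 - sc, st)
    expect_equal(r$auc + r_rev$auc, 1)
  }
})

test_that("the Youden cutoff is reproduced by dichotomize", {
  set.seed(54)
  for (i in 1:20) {
    sc <- sample(seq(0, 100, by = 5), 30, replace = TRUE)
    st <- as.logical(rbinom(30, 1, 0.5))
    if (length(unique(st)) < 2) next
    r <- roc_with_cutoff(sc, st)
    g <- dichotomize(sc, r$cutoff)
    sens <- mean(g[st] == "low_bap1")
    spec <- mean(g[!st] == "high_bap1")
    expect_identical(sens, r$sensitivity)
    expect_identical(spec, r$specificity)
  }
})

test_that("dichotomize boundary is inclusive on the low-BAP-1 side", {
  expect_identical(as.character(dichotomize(68, 68)), "low_bap1")
  expect_identical(as.character(dichotomize(0, 46)), "high_bap1")
  expect_identical(as.character(dichotomize(c(95, 10), 46)),
                   c("low_bap1", "high_bap1"))
  expect_error(roc_with_cutoff(c(10, 20), c(1, 1)),
               class = "bap1_validation_error")  # single class
})

test_that("Kaplan-Meier product-limit estimates match the hand calculation", {
  km <- km_logrank(groups = rep(c("a", "b"), c(4, 4)),
                   follow_up_months = c(1, 2, 3, 4, 1, 2, 3, 4),
                   events = c(1, 1, 0, 1, 0, 0, 0, 0))
  s <- summary(km$fit)
  grp_a <- s$surv[s$strata == "group=a"]
  expect_equal(grp_a, c(0.75, 0.50, 0.0))  # steps at t = 1, 2, 4; censored at 3
  expect_true(km$p_value >= 0 && km$p_value <= 1)
})

test_that("log-rank with no events warns and reports p = 1", {
  expect_warning(
    km <- km_logrank(rep(c("a", "b"), each = 5), rexp(10, 0.1), rep(0, 10)),
    "no events")
  expect_equal(km$p_value, 1)
  expect_true(all(summary(km$fit)$surv == 1))
  expect_error(km_logrank(rep("a", 6), rexp(6, 0.1), rbinom(6, 1, 0.5)),
               class = "bap1_validation_error")
})

test_that("log-rank detects a strong simulated hazard ratio", {
  set.seed(55)
  hits <- 0L
  for (i in 1:50) {
    g <- rep(c(0, 1), each = 20)
    t <- rexp(40, 0.01 * ifelse(g == 1, 10, 1))
    ev <- t <= 120; t <- pmin(t, 120)
    km <- km_logrank(factor(g), t, ev)
    hits <- hits + (km$p_value < 0.01)
  }
  expect_gte(hits, 47L)  # >= ~95% power at HR 10
})

test_that("tiny Cox fits match the 1-D Newton oracle", {
  # the two-subject configuration (event in group 1 at t=1, in group 0 at
  # t=2) has a monotone partial likelihood e^b/(e^b+1): no finite
  # maximizer exists, and the fit must say so
  fit2 <- cox_univariate(c(1, 0), c(1, 2), c(1, 1))
  expect_true(fit2$unstable)

  # smallest configuration with a finite maximizer: opposing events
  x <- c(1, 0, 1, 0); time <- c(1, 2, 3, 4); event <- c(1, 1, 0, 1)
  fit <- cox_univariate(x, time, event)
  b_oracle <- newton_cox(x, time, event)
  expect_equal(fit$b, b_oracle, tolerance = 1e-8)
  # invariants of the result object
  expect_equal(fit$hr, exp(fit$b))
  expect_equal(fit$ci_low, exp(fit$b - qnorm(0.975) * fit$se))
  expect_equal(fit$ci_high, exp(fit$b + qnorm(0.975) * fit$se))
})

test_that("larger Cox fits match the Newton oracle and flag instability", {
  set.seed(56)
  x <- rbinom(30, 1, 0.5)
  t <- rexp(30, 0.02 * exp(0.8 * x))
  ev <- as.integer(t <= 60); t <- pmin(t, 60)
  if (sum(ev) > 2 && length(unique(x)) == 2) {
    fit <- cox_univariate(x, t, ev)
    expect_equal(fit$b, newton_cox(x, t, ev), tolerance = 1e-6)
  }
  expect_error(cox_univariate(rep(1, 10), rexp(10), rbinom(10, 1, 0.5)),
               class = "bap1_validation_error")
  # one group event-free -> monotone likelihood flagged
  fit <- cox_univariate(rep(c(0, 1), each = 10),
                        c(rexp(10, 0.5), rep(50, 10)),
                        c(rep(1, 10), rep(0, 10)))
  expect_true(fit$unstable)
})

test_that("LR chi-square change behaves at the degenerate ends", {
  set.seed(57)
  t <- rexp(30, 0.05); ev <- as.integer(t <= 30); t <- pmin(t, 30)
  r <- lr_chisq_change(NULL, rep(3, 30), t, ev)
  expect_equal(r$lr_chi2, 0)
  expect_equal(r$p_value, 1)

  x <- rbinom(30, 1, 0.5)
  base <- data.frame(x = x)
  expect_error(lr_chisq_change(base, x, t, ev, added_name = "x"),
               class = "bap1_validation_error")  # not nested
})

test_that("LR chi-square is invariant to affine rescaling of the covariate", {
  set.seed(58)
  z <- rnorm(40)
  base <- data.frame(grp = rbinom(40, 1, 0.5))
  t <- rexp(40, 0.03 * exp(0.5 * z)); ev <- as.integer(t <= 60)
  t <- pmin(t, 60)
  a <- lr_chisq_change(base, z, t, ev)
  b <- lr_chisq_change(base, 100 + 7 * z, t, ev)
  expect_equal(a$lr_chi2, b$lr_chi2, tolerance = 1e-6)
  expect_equal(a$df, b$df)
})

test_that("LR chi-square equals twice the log-likelihood gap from survival", {
  set.seed(59)
  n <- 50
  grp <- rbinom(n, 1, 0.5); z <- rnorm(n)
  t <- rexp(n, 0.04 * exp(0.6 * grp + 0.4 * z)); ev <- as.integer(t <= 60)
  t <- pmin(t, 60)
  r <- lr_chisq_change(data.frame(grp = grp), z, t, ev, added_name = "z")
  f0 <- survival::coxph(survival::Surv(t, ev) ~ grp, ties = "breslow")
  f1 <- survival::coxph(survival::Surv(t, ev) ~ grp + z, ties = "breslow")
  expect_equal(r$lr_chi2, 2 * (f1$loglik[2] - f0$loglik[2]), tolerance = 1e-10)
  expect_equal(r$df, 1L)
})

test_that("compartment_comparison emits the full report schema", {
  set.seed(60)
  sim <- generate_cohort(cohort_spec(n_patients = 40, seed = 60))
  co <- sim$cohort
  meas <- co[, c("patient_id", "full_pct", "hot_pct", "cold_pct",
                 "scleral_pct")]
  rep <- compartment_comparison(meas, co)
  expect_s3_class(rep, "bap1_report")
  expect_identical(rep$roc_metastasis$area,
                   c("full", "hot", "cold", "scleral"))
  expect_identical(names(rep$roc_metastasis),
                   c("area", "auc", "se", "p", "ci_low", "ci_high", "cutoff",
                     "sensitivity", "specificity"))
  expect_identical(names(rep$cox_table),
                   c("area", "b", "se", "wald", "p", "hr", "ci_low",
                     "ci_high", "logrank_p", "unstable"))
  expect_equal(nrow(rep$lr_region), 12L)  # ordered pairs of 4 compartments
  expect_identical(names(rep$lr_region), c("base", "added", "lr_chi2", "df", "p"))
  expect_equal(nrow(rep$lr_tcategory), 4L)
  expect_true(rep$estimable)
  expect_output(print(rep), "ROC vs metastasis")
})

test_that("a cohort with no metastases is flagged not estimable", {
  set.seed(61)
  sim <- generate_cohort(cohort_spec(n_patients = 20, horizon_months = 0,
                                     seed = 61))
  co <- sim$cohort
  expect_true(all(!co$metastasis_event))
  meas <- co[, c("patient_id", "full_pct", "hot_pct", "cold_pct",
                 "scleral_pct")]
  rep <- compartment_comparison(meas, co)
  expect_false(rep$estimable)
  expect_true(all(is.na(rep$roc_metastasis$auc)))
  expect_true(all(is.na(rep$cox_table$hr)))
  expect_null(rep$lr_region)
})
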