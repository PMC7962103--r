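# Cutoff calibration on the proportion of BAP-1 NEGATIVE cells and the
# downstream survival machinery: Kaplan-Meier / log-rank, univariate Cox,
# and likelihood-ratio chi-square change between nested models.
#
# Scores throughout this module are percent BAP-1 negative cells (loss of
# nuclear BAP-1 marks metastatic risk), so a higher score means higher
# risk and all cutoffs live on that scale.

#' ROC analysis with Youden-index cutoff
#'
#' Nonparametric ROC of a percent-negative-cells score against a binary
#' state (metastasis, or gene expression class 2). The AUC is the
#' Mann-Whitney probability that a state-positive tumor scores higher than
#' a state-negative one (ties count one half); its standard error is the
#' Hanley-McNeil estimate with an asymptotic-normal 95% CI, and the
#' p-value tests AUC = 0.5 by the corresponding z statistic. The reported
#' cutoff maximizes Youden's J = sensitivity + specificity - 1 (equal
#' emphasis on sensitivity and specificity); among ties the cutoff with
#' higher specificity, then the lower cutoff, wins. The classification
#' rule is score >= cutoff => predicted state-positive.
#'
#' @param scores percent negative cells per tumor, in \[0, 100\].
#' @param state logical (or 0/1) state per tumor; both classes required.
#' @param state_variable label stored on the result (`"metastasis"` or
#'   `"gep_class_2"`).
#' @return a `bap1_roc`: `auc`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `cutoff`, `sensitivity`, `specificity`, counts, and the empirical
#'   `curve` (`threshold`, `fpr`, `tpr`).
#' @export
roc_with_cutoff <- function(scores, state, state_variable = "metastasis") {
  state <- as.logical(state)
  if (length(scores) != length(state)) abort_validation("length mismatch")
  keep <- is.finite(scores) & !is.na(state)
  scores <- scores[keep]; state <- state[keep]
  if (any(scores < 0 | scores > 100))
    abort_validation("scores must lie in [0, 100]")
  n1 <- sum(state); n0 <- sum(!state)
  if (n1 == 0L || n0 == 0L)
    abort_validation("both state classes must be present")

  r <- rank(scores)
  auc <- (sum(r[state]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
              (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- if (se > 0) (auc - 0.5) / se else Inf * sign(auc - 0.5)
  p <- if (is.finite(z)) 2 * pnorm(-abs(z)) else if (auc == 0.5) 1 else 0

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(c) mean(scores[state] >= c), numeric(1L))
  fpr <- vapply(thr, function(c) mean(scores[!state] >= c), numeric(1L))
  sens <- tpr
  # computed directly (not as 1 - fpr) so dichotomize() reproduces it bit-exactly
  spec <- vapply(thr, function(c) mean(scores[!state] < c), numeric(1L))
  j <- sens + spec - 1
  best <- order(-j, -spec, thr)[1L]

  structure(list(auc = auc, se = se,
                 ci_low = max(0, auc - stats::qnorm(0.975) * se),
                 ci_high = min(1, auc + stats::qnorm(0.975) * se),
                 p_value = p, cutoff = thr[best],
                 sensitivity = sens[best], specificity = spec[best],
                 youden_j = j[best], n_state = n1, n_control = n0,
                 state_variable = state_variable,
                 curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "bap1_roc")
}

#' @export
print.bap1_roc <- function(x, ...) {
  cat(sprintf(paste0(
    "ROC (%s, %d vs %d): AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f, p = %.2g)\n",
    "  Youden cutoff %.4g%% negative cells: sensitivity %.0f%%, specificity %.0f%%\n"),
    x$state_variable, x$n_state, x$n_control, x$auc, x$se, x$ci_low,
    x$ci_high, x$p_value, x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' @export
plot.bap1_roc <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  lines(c(0, 1), c(0, 1), lty = 2)
  invisible(x)
}

#' Dichotomize tumors at a percent-negative cutoff
#'
#' Tumors whose percent-negative score is at or above the cutoff fall in
#' the BAP-1 low (high metastatic risk) group; below it, BAP-1 high. The
#' boundary is inclusive on the low-BAP-1 side so that the sensitivity and
#' specificity quoted by [roc_with_cutoff()] are reproduced exactly.
#'
#' @param scores percent negative cells.
#' @param cutoff cutoff in \[0, 100\].
#' @return factor with levels `high_bap1`, `low_bap1`.
#' @export
dichotomize <- function(scores, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      (is.finite(cutoff) && (cutoff < 0 || cutoff > 100)))
    abort_validation("cutoff must be a single value in [0, 100]")
  factor(ifelse(scores >= cutoff, "low_bap1", "high_bap1"),
         levels = c("high_bap1", "low_bap1"))
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit metastasis-free survival per group with a two-sided
#' log-rank comparison. With no events anywhere the log-rank statistic is
#' undefined; the p-value is reported as 1 with a warning.
#'
#' @param groups factor-like group per subject (all groups non-empty).
#' @param follow_up_months nonnegative follow-up times.
#' @param events logical/0-1 event indicators.
#' @return a `bap1_km`: the `survfit` object, `p_value`, `chisq`, `df` and
#'   a per-group summary table.
#' @export
km_logrank <- function(groups, follow_up_months, events) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    abort_validation("need at least two non-empty groups")
  if (any(follow_up_months < 0)) abort_validation("negative follow-up time")
  events <- as.integer(as.logical(events))
  d <- data.frame(time = follow_up_months, event = events, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (sum(events) == 0L) {
    warning("no events in any group; log-rank test undefined, p set to 1")
    chisq <- 0; df <- nlevels(groups) - 1L; p <- 1
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    chisq <- sd$chisq
    df <- length(sd$n) - 1L
    p <- pchisq(chisq, df, lower.tail = FALSE)
  }
  structure(list(fit = fit, p_value = p, chisq = chisq, df = df,
                 table = data.frame(group = levels(groups),
                                    n = as.integer(table(groups)),
                                    events = as.integer(tapply(events, groups, sum)))),
            class = "bap1_km")
}

#' @export
print.bap1_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier metastasis-free survival, log-rank p = %.3g (chi2 %.2f, %d df)\n",
              x$p_value, x$chisq, x$df))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.bap1_km <- function(x, ...) {
  ng <- nrow(x$table)
  plot(x$fit, col = seq_len(ng), xlab = "months",
       ylab = "metastasis-free survival", ...)
  legend("bottomleft", legend = x$table$group, col = seq_len(ng), lty = 1,
         bty = "n")
  invisible(x)
}

.as_indicator <- function(group) {
  if (is.factor(group) || is.character(group)) {
    group <- droplevels(factor(group))
    if (nlevels(group) != 2L)
      abort_validation("group must have exactly two levels")
    as.integer(group == levels(group)[2L])
  } else as.numeric(group)
}

#' Univariate Cox regression
#'
#' Proportional-hazards fit of a single (typically dichotomized BAP-1
#' status) covariate on metastasis-free survival, with Breslow handling of
#' tied event times by default. When one group is event-free the partial
#' likelihood is monotone and the estimate diverges; the result is then
#' flagged `unstable`.
#'
#' @param group_indicator two-level factor or numeric covariate (for a
#'   factor, the second level is the exposed group).
#' @param follow_up_months nonnegative times.
#' @param events logical/0-1 event indicators.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return a `bap1_cox`: `b`, `se`, `wald`, `p_value`, `hr`, `ci_low`,
#'   `ci_high`, `unstable`, `n`, `n_events`.
#' @export
cox_univariate <- function(group_indicator, follow_up_months, events,
                           ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  xi <- .as_indicator(group_indicator)
  if (length(unique(xi)) < 2L)
    abort_validation("group indicator is constant; no contrast to estimate")
  if (any(follow_up_months < 0)) abort_validation("negative follow-up time")
  ev <- as.integer(as.logical(events))
  # monotone likelihood when the covariate is binary and a group is event-free
  unstable <- length(unique(xi)) == 2L &&
    any(tapply(ev, xi, sum) == 0L)
  d <- data.frame(time = follow_up_months, event = ev, x = xi)
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ x, data = d, ties = ties))
  b <- unname(fit$coefficients[1L])
  se <- sqrt(fit$var[1L, 1L])
  # a diverging estimate also signals a monotone partial likelihood
  if (!is.finite(b) || abs(b) > 15) unstable <- TRUE
  z <- stats::qnorm(0.975)
  structure(list(b = b, se = se, wald = (b / se)^2,
                 p_value = pchisq((b / se)^2, 1L, lower.tail = FALSE),
                 hr = exp(b), ci_low = exp(b - z * se),
                 ci_high = exp(b + z * se), ties = ties,
                 unstable = unstable, n = nrow(d), n_events = sum(ev),
                 fit = fit),
            class = "bap1_cox")
}

#' @export
print.bap1_cox <- function(x, ...) {
  cat(sprintf(
    "Cox univariate (%s ties, n = %d, %d events)%s\n  B %.3f (SE %.3f), Wald %.2f, p = %.3g, HR %.2f (95%% CI %.2f-%.2f)\n",
    x$ties, x$n, x$n_events, if (x$unstable) " [UNSTABLE: monotone likelihood]" else "",
    x$b, x$se, x$wald, x$p_value, x$hr, x$ci_low, x$ci_high))
  invisible(x)
}

.cox_fit <- function(d, covars, ties) {
  if (length(covars) == 0L) return(NULL)
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(sprintf("`%s`", covars), collapse = " + ")))
  suppressWarnings(survival::coxph(f, data = d, ties = ties))
}

#' Likelihood-ratio chi-square change between nested Cox models
#'
#' Fits the base Cox model and the base plus one added covariate and
#' reports twice the log partial-likelihood difference, with a chi-square
#' p-value on the number of parameters added. This measures the prognostic
#' information the added covariate contributes beyond the base model.
#'
#' @param base_covariates `data.frame` of base-model covariates (or `NULL`
#'   for the null model).
#' @param added_covariate vector: the covariate whose added value is
#'   tested (numeric, or factor contributing `nlevels - 1` parameters).
#' @param follow_up_months nonnegative times.
#' @param events logical/0-1 event indicators.
#' @param added_name name used in the report.
#' @param ties `"breslow"` or `"efron"`.
#' @return a `bap1_lrchange`: `base_model`, `added`, `lr_chi2`, `df`,
#'   `p_value`.
#' @export
lr_chisq_change <- function(base_covariates, added_covariate,
                            follow_up_months, events, added_name = "added",
                            ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  ev <- as.integer(as.logical(events))
  n <- length(follow_up_months)
  if (!is.null(base_covariates)) {
    base_covariates <- as.data.frame(base_covariates)
    if (nrow(base_covariates) != n) abort_validation("length mismatch")
    if (added_name %in% names(base_covariates))
      abort_validation("added covariate is already part of the base model (not nested)")
  }
  if (length(added_covariate) != n) abort_validation("length mismatch")

  d <- data.frame(time = follow_up_months, event = ev)
  base_names <- character(0L)
  if (!is.null(base_covariates)) {
    for (nm in names(base_covariates)) d[[nm]] <- base_covariates[[nm]]
    base_names <- names(base_covariates)
  }
  d[[added_name]] <- added_covariate

  base_fit <- .cox_fit(d, base_names, ties)
  ll_of <- function(fit) if (is.null(fit)) NA_real_ else fit$loglik[2L]
  ncoef <- function(fit) if (is.null(fit)) 0L else sum(!is.na(fit$coefficients))

  varies <- length(unique(added_covariate[!is.na(added_covariate)])) > 1L
  if (!varies) {
    lr <- 0; df <- 0L
  } else {
    full_fit <- .cox_fit(d, c(base_names, added_name), ties)
    ll_base <- if (is.null(base_fit)) full_fit$loglik[1L] else ll_of(base_fit)
    df <- ncoef(full_fit) - ncoef(base_fit)
    lr <- max(0, 2 * (ll_of(full_fit) - ll_base))
    if (df == 0L) lr <- 0
  }
  structure(list(base_model = if (length(base_names)) base_names else "(null)",
                 added = added_name, lr_chi2 = lr, df = df,
                 p_value = if (df == 0L) 1 else
                   pchisq(lr, df, lower.tail = FALSE)),
            class = "bap1_lrchange")
}

#' @export
print.bap1_lrchange <- function(x, ...) {
  cat(sprintf("LR chi-square change: + %s over [%s]: %.2f on %d df, p = %.3g\n",
              x$added, paste(x$base_model, collapse = ", "), x$lr_chi2, x$df,
              x$p_value))
  invisible(x)
}

COMPARTMENTS <- c(full = "full_pct", hot = "hot_pct", cold = "cold_pct",
                  scleral = "scleral_pct")

.na_roc_row <- function(area) data.frame(
  area = area, auc = NA_real_, se = NA_real_, p = NA_real_,
  ci_low = NA_real_, ci_high = NA_real_, cutoff = NA_real_,
  sensitivity = NA_real_, specificity = NA_real_)

.roc_row <- function(area, r) data.frame(
  area = area, auc = r$auc, se = r$se, p = r$p_value, ci_low = r$ci_low,
  ci_high = r$ci_high, cutoff = r$cutoff, sensitivity = r$sensitivity,
  specificity = r$specificity)

#' Compare the prognostic value of the four tumor compartments
#'
#' The full downstream stage: per compartment (full section, hot spot,
#' cold spot, scleral margin) it converts percent-positive to
#' percent-negative scores, calibrates a metastasis ROC cutoff, splits the
#' cohort into BAP-1 high/low, and runs Kaplan-Meier/log-rank and
#' univariate Cox; it then builds the likelihood-ratio chi-square change
#' cross-tables (each region added over each other region, over AJCC
#' T-category, and over gene expression class). ROC against gene
#' expression class 2 is reported alongside.
#'
#' @param measurements `data.frame` with `patient_id` and the four
#'   compartment percent-positive columns `full_pct`, `hot_pct`,
#'   `cold_pct`, `scleral_pct`.
#' @param cohort cohort `data.frame` (see [read_cohort()]).
#' @param ties tie handling for the Cox fits.
#' @return a `bap1_report`: `roc_metastasis`, `roc_gep2`, `km`,
#'   `cox_table`, `lr_region`, `lr_tcategory`, `lr_gep`, `estimable`.
#'   When the cohort has no metastases (or a single state class) the
#'   survival sections are flagged not estimable and returned as `NA`
#'   rows.
#' @export
compartment_comparison <- function(measurements, cohort,
                                   ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (!"patient_id" %in% names(measurements) &&
      "tumor_id" %in% names(measurements))
    names(measurements)[names(measurements) == "tumor_id"] <- "patient_id"
  need <- c("patient_id", COMPARTMENTS)
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    abort_validation(paste0("measurements missing column(s): ",
                            paste(miss, collapse = ", ")))
  cohort <- cohort[, setdiff(names(cohort), unname(COMPARTMENTS)), drop = FALSE]
  d <- merge(cohort, measurements[, need], by = "patient_id")
  if (nrow(d) == 0L) abort_validation("no patients shared by cohort and measurements")
  if (any(!complete.cases(d[, COMPARTMENTS])))
    abort_validation("all four compartment scores must be present per tumor")

  state <- as.logical(d$metastasis_event)
  estimable <- length(unique(state)) == 2L
  gep2 <- ifelse(is.na(d$gep_class), NA, d$gep_class == "2")
  gep_ok <- sum(gep2 == TRUE, na.rm = TRUE) >= 1L &&
    sum(gep2 == FALSE, na.rm = TRUE) >= 1L

  roc_met <- list(); roc_gep <- list(); km <- list(); cox_rows <- list()
  groups <- list()
  for (comp in names(COMPARTMENTS)) {
    neg <- 100 - d[[COMPARTMENTS[[comp]]]]
    if (estimable) {
      r <- roc_with_cutoff(neg, state, state_variable = "metastasis")
      roc_met[[comp]] <- .roc_row(comp, r)
      g <- dichotomize(neg, r$cutoff)
      groups[[comp]] <- g
      km[[comp]] <- tryCatch(
        km_logrank(g, d$follow_up_months, state),
        bap1_error = function(e) NULL)
      cx <- tryCatch(
        cox_univariate(g, d$follow_up_months, state, ties = ties),
        bap1_error = function(e) NULL)
      cox_rows[[comp]] <- if (is.null(cx)) data.frame(
        area = comp, b = NA_real_, se = NA_real_, wald = NA_real_,
        p = NA_real_, hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        logrank_p = NA_real_, unstable = NA)
      else data.frame(
        area = comp, b = cx$b, se = cx$se, wald = cx$wald, p = cx$p_value,
        hr = cx$hr, ci_low = cx$ci_low, ci_high = cx$ci_high,
        logrank_p = if (is.null(km[[comp]])) NA_real_ else km[[comp]]$p_value,
        unstable = cx$unstable)
    } else {
      roc_met[[comp]] <- .na_roc_row(comp)
      cox_rows[[comp]] <- data.frame(
        area = comp, b = NA_real_, se = NA_real_, wald = NA_real_,
        p = NA_real_, hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        logrank_p = NA_real_, unstable = NA)
    }
    roc_gep[[comp]] <- if (gep_ok)
      .roc_row(comp, roc_with_cutoff(neg[!is.na(gep2)], gep2[!is.na(gep2)],
                                     state_variable = "gep_class_2"))
    else .na_roc_row(comp)
  }

  lr_try <- function(base_df, added, name) {
    res <- tryCatch(
      lr_chisq_change(base_df, added, d$follow_up_months, state,
                      added_name = name, ties = ties),
      error = function(e) NULL)
    if (is.null(res)) c(lr_chi2 = NA_real_, df = NA_real_, p = NA_real_)
    else c(lr_chi2 = res$lr_chi2, df = res$df, p = res$p_value)
  }

  # The LR cross-tables compare the information in the compartment SCORES
  # themselves (continuous percent-negative covariates); the dichotomized
  # groups are used only for the KM/Cox tables they mirror. A dichotomized
  # base model would leave residual score information that any correlated
  # compartment picks up, blurring exactly the region-vs-region contrast
  # the cross-table is meant to isolate.
  lr_region <- NULL; lr_tcat <- NULL; lr_gep <- NULL
  if (estimable) {
    neg_scores <- lapply(COMPARTMENTS, function(col) 100 - d[[col]])
    rows <- list()
    for (base in names(neg_scores)) for (added in names(neg_scores)) {
      if (base == added) next
      v <- lr_try(stats::setNames(data.frame(neg_scores[[base]]),
                                  paste0(base, "_neg")),
                  neg_scores[[added]], paste0(added, "_neg"))
      rows[[length(rows) + 1L]] <- data.frame(
        base = base, added = added, lr_chi2 = v[["lr_chi2"]],
        df = v[["df"]], p = v[["p"]])
    }
    lr_region <- do.call(rbind, rows)

    t_ord <- as.integer(substr(d$ajcc_t_category, 1L, 1L))
    rows <- lapply(names(neg_scores), function(comp) {
      v <- lr_try(data.frame(t_category = t_ord), neg_scores[[comp]],
                  paste0(comp, "_neg"))
      data.frame(base = "ajcc_t_category", added = comp,
                 lr_chi2 = v[["lr_chi2"]], df = v[["df"]], p = v[["p"]])
    })
    lr_tcat <- do.call(rbind, rows)

    has_gep <- !is.na(d$gep_class)
    if (sum(has_gep) >= 3L && length(unique(d$gep_class[has_gep])) >= 2L &&
        length(unique(state[has_gep])) == 2L) {
      dg <- d[has_gep, ]
      rows <- lapply(names(neg_scores), function(comp) {
        res <- tryCatch(
          lr_chisq_change(data.frame(gep = factor(dg$gep_class)),
                          neg_scores[[comp]][has_gep], dg$follow_up_months,
                          as.logical(dg$metastasis_event),
                          added_name = paste0(comp, "_neg"), ties = ties),
          error = function(e) NULL)
        data.frame(base = "gep_class", added = comp,
                   lr_chi2 = if (is.null(res)) NA_real_ else res$lr_chi2,
                   df = if (is.null(res)) NA_real_ else res$df,
                   p = if (is.null(res)) NA_real_ else res$p_value)
      })
      lr_gep <- do.call(rbind, rows)
    }
  }

  structure(list(
    roc_metastasis = do.call(rbind, roc_met),
    roc_gep2 = do.call(rbind, roc_gep),
    cox_table = do.call(rbind, cox_rows),
    km = km, groups = groups,
    lr_region = lr_region, lr_tcategory = lr_tcat, lr_gep = lr_gep,
    estimable = estimable, n = nrow(d), n_events = sum(state)),
    class = "bap1_report")
}

#' @export
print.bap1_report <- function(x, ...) {
  cat(sprintf("Compartment comparison: n = %d, %d metastasis events%s\n\n",
              x$n, x$n_events,
              if (!x$estimable) " [survival sections NOT ESTIMABLE]" else ""))
  cat("ROC vs metastasis (percent negative cells):\n")
  print(x$roc_metastasis, row.names = FALSE, digits = 3)
  cat("\nROC vs gene expression class 2:\n")
  print(x$roc_gep2, row.names = FALSE, digits = 3)
  cat("\nUnivariate Cox per dichotomized compartment:\n")
  print(x$cox_table, row.names = FALSE, digits = 3)
  if (!is.null(x$lr_region)) {
    cat("\nLR chi-square change, region over region:\n")
    print(x$lr_region, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$lr_tcategory)) {
    cat("\nLR chi-square change over AJCC T-category:\n")
    print(x$lr_tcategory, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$lr_gep)) {
    cat("\nLR chi-square change over gene expression class:\n")
    print(x$lr_gep, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
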