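# Heterogeneity metric, semi-ellipsoid tumor volume, group comparisons and
# the eleven-family regression screen of heterogeneity against volume.

#' Intratumor heterogeneity in percentage points
#'
#' The difference between a tumor's hot-spot and cold-spot percent-positive
#' scores. The scan guarantees hot >= cold; a violation signals an internal
#' inconsistency upstream and raises an error.
#'
#' @param hot_pct,cold_pct percent positive in \[0, 100\].
#' @return heterogeneity in percentage points (pp).
#' @export
heterogeneity <- function(hot_pct, cold_pct) {
  if (any(hot_pct < 0 | hot_pct > 100 | cold_pct < 0 | cold_pct > 100,
          na.rm = TRUE))
    abort_validation("compartment scores must lie in [0, 100]")
  if (any(hot_pct < cold_pct, na.rm = TRUE))
    abort_internal("hot-spot score below cold-spot score; scan inconsistency")
  hot_pct - cold_pct
}

#' Semi-ellipsoid tumor volume
#'
#' Volume of a tumor modeled as a semi-ellipsoid with circular base:
#' `pi/6 * t * lbd^2`, where `t` is the apical thickness and `lbd` the
#' largest basal diameter, both in millimetres.
#'
#' @param t apical thickness (mm), > 0.
#' @param lbd largest basal diameter (mm), > 0.
#' @return volume in cubic millimetres.
#' @examples
#' tumor_volume(6, 10)  # 100 * pi
#' @export
tumor_volume <- function(t, lbd) {
  if (any(!is.finite(t) | t <= 0) || any(!is.finite(lbd) | lbd <= 0))
    abort_validation("thickness and basal diameter must be positive")
  pi / 6 * t * lbd^2
}

CURVE_FAMILIES <- c("linear", "logarithmic", "inverse", "quadratic", "cubic",
                    "compound", "power", "S", "growth", "exponential",
                    "logistic")

# Design matrix (without intercept) and transformed response for each
# family, following the classic curve-estimation parameterizations:
#   linear      y = b0 + b1 x
#   logarithmic y = b0 + b1 ln x
#   inverse     y = b0 + b1 / x
#   quadratic   y = b0 + b1 x + b2 x^2
#   cubic       y = b0 + b1 x + b2 x^2 + b3 x^3
#   compound    y = b0 * b1^x          (fit: ln y on x)
#   power       y = b0 * x^b1          (fit: ln y on ln x)
#   S           y = exp(b0 + b1 / x)   (fit: ln y on 1/x)
#   growth      y = exp(b0 + b1 x)     (fit: ln y on x)
#   exponential y = b0 * exp(b1 x)     (fit: ln y on x)
#   logistic    y = 1 / (1/u + b0 b1^x), u = 1.01 * max(y)
#                                      (fit: ln(1/y - 1/u) on x)
.family_design <- function(family, x, y) {
  u <- 1.01 * max(y)
  switch(family,
    linear      = list(X = cbind(x = x), z = y, ok = TRUE),
    logarithmic = list(X = cbind(lnx = suppressWarnings(log(x))), z = y,
                       ok = all(x > 0)),
    inverse     = list(X = cbind(invx = 1 / x), z = y, ok = all(x != 0)),
    quadratic   = list(X = cbind(x = x, x2 = x^2), z = y, ok = TRUE),
    cubic       = list(X = cbind(x = x, x2 = x^2, x3 = x^3), z = y, ok = TRUE),
    compound    = list(X = cbind(x = x), z = suppressWarnings(log(y)),
                       ok = all(y > 0)),
    power       = list(X = cbind(lnx = suppressWarnings(log(x))),
                       z = suppressWarnings(log(y)), ok = all(x > 0 & y > 0)),
    S           = list(X = cbind(invx = 1 / x), z = suppressWarnings(log(y)),
                       ok = all(x != 0 & y > 0)),
    growth      = list(X = cbind(x = x), z = suppressWarnings(log(y)),
                       ok = all(y > 0)),
    exponential = list(X = cbind(x = x), z = suppressWarnings(log(y)),
                       ok = all(y > 0)),
    logistic    = list(X = cbind(x = x),
                       z = suppressWarnings(log(1 / y - 1 / u)),
                       ok = all(y > 0 & y < u)),
    abort_validation(paste0("unknown curve family: ", family)))
}

#' Screen regression curve families
#'
#' Fits each of eleven classic curve families to (x, y) by least squares
#' (intrinsically nonlinear families are fitted on their linearizing
#' scale) and reports the coefficient of determination, the overall-
#' regression F statistic and its p-value per family, on the family's
#' fitted scale. Used to test whether intratumor heterogeneity is a
#' function of tumor volume.
#'
#' @param x predictor (tumor volume, must be positive for the log, power,
#'   inverse and S families).
#' @param y response (heterogeneity in pp).
#' @param families subset of linear, logarithmic, inverse, quadratic,
#'   cubic, compound, power, S, growth, exponential, logistic.
#' @return a `data.frame` (class `bap1_curvefit`) with one row per family:
#'   `family`, `r_squared`, `f_statistic`, `df1`, `df2`, `p_value`.
#'   Families whose transform is undefined for the data are returned with
#'   `NA` statistics.
#' @export
fit_curve_families <- function(x, y, families = CURVE_FAMILIES) {
  if (length(x) != length(y)) abort_validation("x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) abort_validation("need at least 5 complete observations")
  families <- match.arg(families, CURVE_FAMILIES, several.ok = TRUE)
  rows <- lapply(families, function(fam) {
    d <- .family_design(fam, x, y)
    if (!isTRUE(d$ok) || any(!is.finite(d$z)))
      return(data.frame(family = fam, r_squared = NA_real_,
                        f_statistic = NA_real_, df1 = NA_integer_,
                        df2 = NA_integer_, p_value = NA_real_))
    fit <- lm(d$z ~ d$X)
    p <- sum(!is.na(fit$coefficients)) - 1L
    n <- length(d$z)
    rss <- sum(fit$residuals^2)
    tss <- sum((d$z - mean(d$z))^2)
    if (tss < 1e-12 || p < 1L) {
      r2 <- 0; fstat <- 0; pval <- 1
    } else {
      r2 <- 1 - rss / tss
      fstat <- (tss - rss) / p / (rss / (n - p - 1L))
      pval <- pf(fstat, p, n - p - 1L, lower.tail = FALSE)
    }
    data.frame(family = fam, r_squared = r2, f_statistic = fstat,
               df1 = p, df2 = n - p - 1L, p_value = pval)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bap1_curvefit", "data.frame")
  out
}

#' Compare a continuous measure between groups
#'
#' Two groups: independent-samples Student's t-test with equal variances
#' assumed. More than two: one-way ANOVA. Contract-level wrappers around
#' the standard routines.
#'
#' @param values numeric vector.
#' @param grouping factor-like vector, same length.
#' @param test `"t"` or `"anova"`.
#' @return list with `statistic`, `p_value`, `df` and `method`.
#' @export
compare_groups <- function(values, grouping, test = c("t", "anova")) {
  test <- match.arg(test)
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L)
    abort_validation("need at least two groups")
  if (any(table(grouping) < 2L))
    abort_validation("every group needs at least two observations")
  if (test == "t") {
    if (nlevels(grouping) != 2L)
      abort_validation("the t-test needs exactly two groups")
    ht <- t.test(values ~ grouping, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         df = unname(ht$parameter), method = "t")
  } else {
    tab <- anova(aov(values ~ grouping))
    list(statistic = tab$`F value`[1L], p_value = tab$`Pr(>F)`[1L],
         df = c(tab$Df[1L], tab$Df[2L]), method = "anova")
  }
}
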