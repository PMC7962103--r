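# Seeded generators replacing the study's undeposited measurements:
# dome-shaped tumor geometries over a flat scleral base, marked cell point
# patterns with controlled spatial positivity structure, and
# survival-linked cohorts. Every output is a pure function of its spec
# (including the seed), and the observable cell table never carries the
# ground-truth labels - classification has to be earned through the
# simulated stain intensities.

#' Specification of a synthetic cell point pattern
#'
#' @param width_mm,height_mm basal width and apical height of the dome-
#'   shaped (half-ellipse) tumor cross-section, in millimetres.
#' @param cell_density expected cells per square millimetre. The default
#'   yields a desk-scale tumor of a few tens of thousands of cells; raise
#'   it (e.g. to 10000) for section-scale stress tests in the
#'   hundreds of thousands.
#' @param background_positivity probability that a cell outside any
#'   planted spot is truly BAP-1 positive, before the optional smooth
#'   field.
#' @param planted_spots list of `list(center = c(x, y), radius, positivity)`
#'   discs (micrometres) in which the true positivity is overridden; where
#'   discs overlap the nearest center wins.
#' @param smooth_field optional `list(length_scale, amplitude)`: a smooth
#'   random field (micrometre length scale, logit-scale amplitude) added
#'   to the background log-odds.
#' @param od_separation mean chromogen optical-density gap between truly
#'   positive and truly negative cells (negatives center on 0.2).
#' @param od_noise standard deviation of the per-cell chromogen OD.
#' @param small_cell_fraction fraction of detections given lymphocyte-
#'   sized nuclei (below 30 square micrometres), exercising the size
#'   filter.
#' @param seed integer seed making the pattern reproducible.
#' @return a `bap1_pattern_spec` list.
#' @export
pattern_spec <- function(width_mm = 8, height_mm = 3.5, cell_density = 1500,
                         background_positivity = 0.5, planted_spots = list(),
                         smooth_field = NULL, od_separation = 0.6,
                         od_noise = 0.1, small_cell_fraction = 0.05,
                         seed = 1L) {
  if (width_mm <= 0 || height_mm <= 0)
    abort_validation("tumor dimensions must be positive")
  if (cell_density <= 0) abort_validation("cell_density must be positive")
  if (background_positivity < 0 || background_positivity > 1)
    abort_validation("background_positivity must lie in [0, 1]")
  for (sp in planted_spots) {
    if (is.null(sp$center) || is.null(sp$radius) || is.null(sp$positivity))
      abort_validation("each planted spot needs center, radius and positivity")
    if (sp$radius <= 0) abort_validation("planted spot radius must be > 0")
    if (sp$positivity < 0 || sp$positivity > 1)
      abort_validation("planted spot positivity must lie in [0, 1]")
  }
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 cell_density = cell_density,
                 background_positivity = background_positivity,
                 planted_spots = planted_spots, smooth_field = smooth_field,
                 od_separation = od_separation, od_noise = od_noise,
                 small_cell_fraction = small_cell_fraction,
                 seed = as.integer(seed)),
            class = "bap1_pattern_spec")
}

#' Generate a dome-shaped tumor geometry
#'
#' A half-ellipse standing on a flat base: the choroidal melanoma
#' cross-section idealized as a dome whose flat (scleral) edge is the
#' tumor base. In image convention the base lies at the bottom
#' (y = height) and the apex at y = 0. The base polyline is the flat
#' edge.
#'
#' @param width_mm basal width in millimetres.
#' @param height_mm apical height in millimetres.
#' @param n_arc number of vertices on the dome arc.
#' @return a [tumor_geometry()] with a base polyline and no exclusions.
#' @export
generate_geometry <- function(width_mm = 8, height_mm = 3.5, n_arc = 72L) {
  if (width_mm <= 0 || height_mm <= 0)
    abort_validation("tumor dimensions must be positive")
  w <- width_mm * 1000; h <- height_mm * 1000
  a <- w / 2
  theta <- seq(0, pi, length.out = n_arc)
  arc <- cbind(a + a * cos(theta), h - h * sin(theta))  # (w,h) -> apex -> (0,h)
  roi <- unique(round(arc, 9))
  base <- rbind(c(0, h), c(w, h))
  tumor_geometry(roi, base = base)
}

.smooth_field_fun <- function(field, seed) {
  # a few random plane waves; amplitude calibrated to the requested
  # logit-scale SD
  set.seed(seed + 7654321L)
  k <- 6L
  ang <- runif(k, 0, 2 * pi)
  phase <- runif(k, 0, 2 * pi)
  amp <- field$amplitude / sqrt(k / 2)
  L <- field$length_scale
  function(x, y) {
    v <- 0
    for (i in seq_len(k))
      v <- v + cos(2 * pi * (x * cos(ang[i]) + y * sin(ang[i])) / L + phase[i])
    amp * v
  }
}

#' Generate a marked cell point pattern
#'
#' Homogeneous Poisson cell positions clipped to the ROI. Each cell's true
#' positivity probability is the planted-spot value where a disc covers it
#' (nearest center wins), otherwise the logistic of the background
#' log-odds plus the optional smooth field. Chromogen OD is drawn from the
#' label-conditional Gaussian (negatives centered on 0.2, positives on
#' 0.2 + `od_separation`, floored at 0), so classification is imperfect
#' exactly when the OD distributions overlap. A configured fraction of
#' nuclei is drawn below the 30 square-micrometre filter.
#'
#' @param geometry a [tumor_geometry()], typically from
#'   [generate_geometry()].
#' @param spec a [pattern_spec()].
#' @return list with `cells` (the observable, unclassified cell table),
#'   `truth` (`cell_id`, `true_label`, `p_true` - kept separate from the
#'   observable table), and `exemplar`
#'   (`positive_exemplar_od`, `negative_exemplar_od`: the simulator's
#'   designated calibration cells, the median OD of each true class).
#' @export
generate_cells <- function(geometry, spec) {
  stopifnot(inherits(geometry, "bap1_geometry"),
            inherits(spec, "bap1_pattern_spec"))
  set.seed(spec$seed)
  roi <- geometry$roi
  bbox <- c(min(roi[, 1]), max(roi[, 1]), min(roi[, 2]), max(roi[, 2]))
  bbox_area_mm2 <- (bbox[2] - bbox[1]) * (bbox[4] - bbox[3]) / 1e6
  n_bbox <- rpois(1L, spec$cell_density * bbox_area_mm2)
  if (spec$cell_density * polygon_area(roi) / 1e6 < 1)
    abort_validation("expected cell count below 1; raise density or size")
  x <- runif(n_bbox, bbox[1], bbox[2])
  y <- runif(n_bbox, bbox[3], bbox[4])
  keep <- points_in_polygon(x, y, roi)
  x <- x[keep]; y <- y[keep]
  n <- length(x)

  # true positivity probability
  logit <- qlogis(min(max(spec$background_positivity, 1e-12), 1 - 1e-12))
  if (!is.null(spec$smooth_field)) {
    f <- .smooth_field_fun(spec$smooth_field, spec$seed)
    p <- plogis(logit + f(x, y))
  } else p <- rep(plogis(logit), n)
  if (length(spec$planted_spots)) {
    best_d2 <- rep(Inf, n)
    for (sp in spec$planted_spots) {
      d2 <- (x - sp$center[1])^2 + (y - sp$center[2])^2
      hit <- d2 <= sp$radius^2 & d2 < best_d2
      p[hit] <- sp$positivity
      best_d2[hit] <- d2[hit]
    }
  }
  pos <- runif(n) < p

  od <- pmax(0, rnorm(n, mean = 0.2 + ifelse(pos, spec$od_separation, 0),
                      sd = spec$od_noise))
  cst <- pmax(0, rnorm(n, 0.5, 0.1))
  small <- runif(n) < spec$small_cell_fraction
  area <- ifelse(small, runif(n, 10, 29),
                 pmin(295, pmax(31, rlnorm(n, log(60), 0.25))))

  cells <- new_cell_table(cell_id = sprintf("c%06d", seq_len(n)),
                          x = x, y = y, nucleus_area = area,
                          chromogen_od = od, counterstain_od = cst)
  exemplar <- list(
    positive_exemplar_od = if (any(pos)) median(od[pos]) else
      0.2 + spec$od_separation,
    negative_exemplar_od = if (any(!pos)) median(od[!pos]) else 0.2)
  list(cells = cells,
       truth = data.frame(cell_id = cells$cell_id,
                          true_label = ifelse(pos, "positive", "negative"),
                          p_true = p, stringsAsFactors = FALSE),
       exemplar = exemplar)
}

#' Specification of a synthetic cohort
#'
#' Survival model: exponential metastasis times with per-patient monthly
#' hazard `baseline_hazard * exp(log_hr_per_pp * (neg_driver - 50) +
#' log_hr_class2 * [gep class 2])`, where `neg_driver` is the percent of
#' BAP-1 negative cells in the `driver` compartment, with administrative
#' censoring at `horizon_months`. Compartment scores are built from a
#' planted hot-cold gap drawn from the requested heterogeneity
#' distribution.
#'
#' @param n_patients cohort size.
#' @param class2_fraction probability of gene expression class 2.
#' @param gep_na_fraction probability the gene expression assay is
#'   missing.
#' @param baseline_hazard monthly metastasis hazard at neg-driver 50 and
#'   gene expression class 1.
#' @param log_hr_per_pp log hazard ratio per percentage point of the
#'   driver compartment's percent-negative score.
#' @param log_hr_class2 log hazard ratio of gene expression class 2.
#' @param driver compartment whose score drives the hazard: `"full"`,
#'   `"hot"`, `"cold"` or `"scleral"`.
#' @param horizon_months administrative censoring horizon.
#' @param het_mean_pp,het_sd_pp mean and SD of the planted hot-cold gap in
#'   percentage points.
#' @param seed integer seed.
#' @return a `bap1_cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 40L, class2_fraction = 0.25,
                        gep_na_fraction = 0.3, baseline_hazard = 0.006,
                        log_hr_per_pp = 0.03, log_hr_class2 = 1.0,
                        driver = c("full", "hot", "cold", "scleral"),
                        horizon_months = 120, het_mean_pp = 41,
                        het_sd_pp = 29, seed = 1L) {
  driver <- match.arg(driver)
  if (n_patients < 2L) abort_validation("need at least 2 patients")
  if (baseline_hazard <= 0) abort_validation("baseline_hazard must be > 0")
  if (horizon_months < 0) abort_validation("horizon_months must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 class2_fraction = class2_fraction,
                 gep_na_fraction = gep_na_fraction,
                 baseline_hazard = baseline_hazard,
                 log_hr_per_pp = log_hr_per_pp,
                 log_hr_class2 = log_hr_class2, driver = driver,
                 horizon_months = horizon_months, het_mean_pp = het_mean_pp,
                 het_sd_pp = het_sd_pp, seed = as.integer(seed)),
            class = "bap1_cohort_spec")
}

T_CATEGORY_PROBS <- c("1a" = 0.03, "2a" = 0.20, "2b" = 0.05, "3a" = 0.40,
                      "3b" = 0.13, "4a" = 0.14, "4b" = 0.05)

#' Generate a survival-linked synthetic cohort
#'
#' Draws per-patient compartment scores with a planted hot-cold gap,
#' clinical covariates with uveal-melanoma-like margins, and exponential
#' metastasis times under the hazard model of [cohort_spec()]. For each
#' patient a matching [pattern_spec()] is returned that plants the
#' patient's hot and cold positivities as discs on the patient's own
#' background, so full cohorts of cell-level tumors can be simulated and
#' pushed through the scan.
#'
#' @param spec a [cohort_spec()].
#' @return list with `cohort` (a cohort `data.frame` including the true
#'   compartment scores and tumor dimensions) and `patterns` (per-patient
#'   `bap1_pattern_spec`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "bap1_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients

  gap <- pmin(100, pmax(0, rnorm(n, spec$het_mean_pp, spec$het_sd_pp)))
  hot <- runif(n, gap, 100)
  cold <- hot - gap
  full <- cold + gap * runif(n, 0.25, 0.75)
  scleral <- cold + (full - cold) * runif(n, 0, 0.5)

  u <- runif(n)
  gep <- ifelse(u < spec$gep_na_fraction, NA_character_,
         ifelse(u < spec$gep_na_fraction + spec$class2_fraction, "2",
                sample(c("1a", "1b"), n, replace = TRUE)))
  scores <- cbind(full = full, hot = hot, cold = cold, scleral = scleral)
  neg_driver <- 100 - scores[, spec$driver]
  lp <- spec$log_hr_per_pp * (neg_driver - 50) +
    spec$log_hr_class2 * (!is.na(gep) & gep == "2")
  rate <- spec$baseline_hazard * exp(lp)
  t_event <- rexp(n, rate)
  event <- t_event <= spec$horizon_months
  follow <- pmin(t_event, spec$horizon_months)

  width <- pmin(24, pmax(6, rnorm(n, 15.1, 3.7)))
  height <- pmin(pmax(2, rnorm(n, 8.8, 3.4)), width * 0.9)
  cohort <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age_years = round(pmin(95, pmax(22, rnorm(n, 64, 13)))),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45)),
    ajcc_t_category = sample(names(T_CATEGORY_PROBS), n, replace = TRUE,
                             prob = T_CATEGORY_PROBS),
    gep_class = gep,
    follow_up_months = follow,
    metastasis_event = event,
    full_pct = full, hot_pct = hot, cold_pct = cold, scleral_pct = scleral,
    thickness_t = height, diameter_lbd = width,
    stringsAsFactors = FALSE)

  patterns <- lapply(seq_len(n), function(i) {
    w <- 6000; h <- 3000  # desk-scale scan geometry, independent of clinical size
    near_base <- runif(1) < 0.55
    cold_y <- if (near_base) h - 600 else h - 1800
    pattern_spec(
      width_mm = w / 1000, height_mm = h / 1000, cell_density = 1500,
      background_positivity = full[i] / 100,
      planted_spots = list(
        list(center = c(0.70 * w, h - 1500), radius = 250,
             positivity = hot[i] / 100),
        list(center = c(0.30 * w, cold_y), radius = 250,
             positivity = cold[i] / 100)),
      seed = (as.numeric(spec$seed) * 1009 + i) %% 2147483647)
  })
  list(cohort = cohort, patterns = patterns)
}
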