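# Circular-window scan for extreme-positivity regions.
#
# The hot spot / cold spot / scleral-margin compartments are 0.5
# mm-diameter circles (0.196 mm^2, about one 400x high-power field) with
# the extreme proportion of BAP-1 positive cells. Candidate centers form a
# regular grid clipped to the ROI, a reproducible surrogate for the manual
# circle placement on a positivity heatmap that the compartments were
# defined with. Windows may protrude beyond the ROI; only classifiable
# cells are counted (excluded cells are invisible to the scan).

#' Scan parameters
#'
#' @param spot_diameter window diameter in micrometres (default 500, i.e.
#'   0.5 mm).
#' @param candidate_spacing grid spacing of candidate centers in
#'   micrometres; must not exceed half the diameter so windows overlap
#'   (default 50).
#' @param min_cells_per_spot smallest number of classifiable cells a window
#'   must hold to be a candidate (default 100). A floor prevents degenerate
#'   one-cell "extremes" at the tumor edge; spots in practice hold on the
#'   order of a thousand cells.
#' @param margin_distance width of the scleral band measured from the tumor
#'   base polyline, in micrometres (default 1000, i.e. 1 mm).
#' @return a `bap1_scan_params` list.
#' @export
scan_params <- function(spot_diameter = 500, candidate_spacing = 50,
                        min_cells_per_spot = 100, margin_distance = 1000) {
  if (spot_diameter <= 0) abort_validation("spot_diameter must be > 0")
  if (candidate_spacing > spot_diameter / 2)
    abort_validation("candidate_spacing must be <= spot_diameter / 2")
  if (min_cells_per_spot < 1) abort_validation("min_cells_per_spot must be >= 1")
  structure(list(spot_diameter = spot_diameter,
                 candidate_spacing = candidate_spacing,
                 min_cells_per_spot = min_cells_per_spot,
                 margin_distance = margin_distance),
            class = "bap1_scan_params")
}

#' Area of a circular scan window
#' @param diameter window diameter in micrometres.
#' @return area in square millimetres.
#' @export
spot_area_mm2 <- function(diameter = 500) pi * (diameter / 2000)^2

new_spot <- function(center, diameter, n_positive, n_negative, compartment) {
  structure(list(center = as.numeric(center), diameter = diameter,
                 n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 proportion = 100 * n_positive / (n_positive + n_negative),
                 compartment = compartment),
            class = "bap1_spot")
}

#' @export
print.bap1_spot <- function(x, ...) {
  cat(sprintf("%s spot at (%.0f, %.0f) um: %.1f%% positive (%d+/%d-, d = %.0f um)\n",
              x$compartment, x$center[1L], x$center[2L], x$proportion,
              x$n_positive, x$n_negative, x$diameter))
  invisible(x)
}

#' Positivity proportion inside one circular window
#'
#' Counts labeled cells whose centroid lies within `diameter/2` of
#' `center` (boundary inclusive); excluded cells are ignored.
#'
#' @param cells labeled cell table.
#' @param center numeric length-2 center (micrometres).
#' @param diameter window diameter (micrometres).
#' @return list with `n_positive`, `n_negative` and `proportion` (percent);
#'   `proportion` is `NA` when the window holds no classifiable cell (the
#'   empty-window sentinel, for the caller to filter).
#' @export
spot_proportion <- function(cells, center, diameter = 500) {
  if (diameter <= 0) abort_validation("diameter must be > 0")
  d2 <- (cells$x - center[1L])^2 + (cells$y - center[2L])^2
  inside <- d2 <= (diameter / 2)^2
  np <- sum(inside & cells$label == "positive")
  nn <- sum(inside & cells$label == "negative")
  list(n_positive = np, n_negative = nn,
       proportion = if (np + nn > 0L) 100 * np / (np + nn) else NA_real_)
}

# Regular candidate grid over the ROI bounding box, nodes at integer
# multiples of `spacing` (so the grid is independent of cell ordering and
# identical between the scan and any exhaustive re-evaluation).
candidate_grid <- function(roi, spacing) {
  ox <- floor(min(roi[, 1L]) / spacing) * spacing
  oy <- floor(min(roi[, 2L]) / spacing) * spacing
  nx <- floor((max(roi[, 1L]) - ox) / spacing) + 1L
  ny <- floor((max(roi[, 2L]) - oy) / spacing) + 1L
  list(ox = ox, oy = oy, spacing = spacing, nx = as.integer(nx),
       ny = as.integer(ny))
}

grid_coords <- function(grid) {
  i <- rep(seq_len(grid$nx) - 1L, each = grid$ny)
  j <- rep(seq_len(grid$ny) - 1L, times = grid$nx)
  list(x = grid$ox + i * grid$spacing, y = grid$oy + j * grid$spacing)
}

# Exact window counts at every grid node, by accumulating each cell into
# the nodes within `radius` of it (a bounded set of grid offsets). Exactly
# equivalent to evaluating Euclidean distance at every node, but linear in
# the number of cells.
window_counts <- function(x, y, positive, grid, radius) {
  nbin <- grid$nx * grid$ny
  npos <- integer(nbin); ntot <- integer(nbin)
  if (length(x) == 0L)
    return(list(n_positive = npos, n_total = ntot))
  s <- grid$spacing
  r2 <- radius^2
  k <- ceiling(radius / s)
  i0 <- as.integer(floor((x - grid$ox) / s))
  j0 <- as.integer(floor((y - grid$oy) / s))
  for (di in (-k):(k + 1L)) {
    i <- i0 + di
    okx <- i >= 0L & i < grid$nx
    if (!any(okx)) next
    dx2 <- (grid$ox + i * s - x)^2
    for (dj in (-k):(k + 1L)) {
      j <- j0 + dj
      ok <- okx & j >= 0L & j < grid$ny &
        dx2 + (grid$oy + j * s - y)^2 <= r2
      if (!any(ok)) next
      idx <- i[ok] * grid$ny + j[ok] + 1L
      ntot <- ntot + tabulate(idx, nbins = nbin)
      pidx <- idx[positive[ok]]
      if (length(pidx)) npos <- npos + tabulate(pidx, nbins = nbin)
    }
  }
  list(n_positive = npos, n_total = ntot)
}

# Deterministic extreme pick: extreme proportion, then larger classifiable
# count, then smallest y, then smallest x of the center.
pick_extreme <- function(prop, ntot, x, y, mode) {
  key <- if (mode == "max") -prop else prop
  order(key, -ntot, y, x)[1L]
}

#' Find the circular window with extreme positivity
#'
#' Evaluates the positivity proportion in a window of fixed diameter at
#' every node of a regular candidate grid clipped to the ROI (and to
#' `constraint` when given) and returns the window with the highest
#' (`mode = "max"`, hot spot) or lowest (`mode = "min"`, cold spot)
#' proportion among candidates holding at least `min_cells_per_spot`
#' classifiable cells. Ties are broken deterministically: larger
#' classifiable-cell count, then smaller y, then smaller x.
#'
#' @param cells labeled cell table from [classify_cells()].
#' @param geometry a [tumor_geometry()].
#' @param params a [scan_params()].
#' @param mode `"max"` or `"min"`.
#' @param constraint optional extra restriction on candidate centers:
#'   either a polygon matrix or a predicate `function(x, y)` returning a
#'   logical vector.
#' @param compartment label stored on the returned spot.
#' @return a `bap1_spot`.
#' @export
find_extreme_spot <- function(cells, geometry, params = scan_params(),
                              mode = c("max", "min"), constraint = NULL,
                              compartment = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "bap1_geometry"))
  if (is.null(compartment))
    compartment <- if (mode == "max") "hot" else "cold"
  keep <- cells$label %in% c("positive", "negative")
  cx <- cells$x[keep]; cy <- cells$y[keep]
  cpos <- cells$label[keep] == "positive"

  grid <- candidate_grid(geometry$roi, params$candidate_spacing)
  gc <- grid_coords(grid)
  valid <- points_in_polygon(gc$x, gc$y, geometry$roi)
  if (!is.null(constraint)) {
    ok <- if (is.function(constraint)) constraint(gc$x, gc$y)
    else points_in_polygon(gc$x, gc$y, as_ring(constraint))
    valid <- valid & ok
  }
  counts <- window_counts(cx, cy, cpos, grid, params$spot_diameter / 2)
  valid <- valid & counts$n_total >= params$min_cells_per_spot
  if (!any(valid))
    abort_no_spot(sprintf(
      "no candidate window holds >= %d classifiable cells%s",
      params$min_cells_per_spot,
      if (is.null(constraint)) "" else " in the constraint region"))
  idx <- which(valid)
  prop <- counts$n_positive[idx] / counts$n_total[idx]
  best <- idx[pick_extreme(prop, counts$n_total[idx], gc$x[idx], gc$y[idx], mode)]
  new_spot(center = c(gc$x[best], gc$y[best]),
           diameter = params$spot_diameter,
           n_positive = counts$n_positive[best],
           n_negative = counts$n_total[best] - counts$n_positive[best],
           compartment = compartment)
}

#' Find the scleral-margin spot
#'
#' The minimum-positivity window whose center lies within
#' `params$margin_distance` (1 mm by default) of the tumor base polyline,
#' on or inside the ROI. Equivalent to [find_extreme_spot()] with
#' `mode = "min"` constrained to the scleral band; only the window center
#' is constrained to the band (the circle may protrude).
#'
#' @inheritParams find_extreme_spot
#' @return a `bap1_spot` with compartment `"scleral"`.
#' @export
find_scleral_margin_spot <- function(cells, geometry, params = scan_params()) {
  if (is.null(geometry$base))
    abort_geometry("geometry has no base polyline; cannot form the scleral band")
  band <- function(x, y)
    dist_to_polyline(x, y, geometry$base) <= params$margin_distance
  find_extreme_spot(cells, geometry, params, mode = "min",
                    constraint = band, compartment = "scleral")
}

#' Is the cold spot inside the scleral band?
#'
#' @param spot a `bap1_spot` (typically the cold spot).
#' @param geometry a [tumor_geometry()] with a base polyline.
#' @param margin_distance band width in micrometres (boundary inclusive).
#' @return `TRUE` when the spot center lies within `margin_distance` of the
#'   base polyline.
#' @export
coldspot_within_base_band <- function(spot, geometry, margin_distance = 1000) {
  stopifnot(inherits(spot, "bap1_spot"))
  if (is.null(geometry$base))
    abort_geometry("geometry has no base polyline")
  dist_to_polyline(spot$center[1L], spot$center[2L], geometry$base) <=
    margin_distance
}

#' Build a positivity heatmap
#'
#' Local percent-positive values on a regular grid: each grid node stores
#' the window proportion at its location, `NA` where the window holds
#' fewer than `min_cells` classifiable cells or the node falls outside the
#' ROI.
#'
#' @param cells labeled cell table.
#' @param geometry a [tumor_geometry()].
#' @param cell_size grid spacing in micrometres.
#' @param window_radius counting radius in micrometres.
#' @param min_cells minimum classifiable cells per window for a value.
#' @return a `bap1_heatmap`: list with `x`, `y` (node coordinates) and
#'   `values` (matrix, rows = x, cols = y, percent positive).
#' @export
build_heatmap <- function(cells, geometry, cell_size = 100,
                          window_radius = 250, min_cells = 10) {
  stopifnot(inherits(geometry, "bap1_geometry"))
  keep <- cells$label %in% c("positive", "negative")
  grid <- candidate_grid(geometry$roi, cell_size)
  gc <- grid_coords(grid)
  counts <- window_counts(cells$x[keep], cells$y[keep],
                          cells$label[keep] == "positive", grid, window_radius)
  vals <- 100 * counts$n_positive / counts$n_total
  vals[counts$n_total < min_cells] <- NA_real_
  vals[!points_in_polygon(gc$x, gc$y, geometry$roi)] <- NA_real_
  # grid_coords enumerates y fastest: column-major in (y, x) => ny x nx
  m <- matrix(vals, nrow = grid$ny, ncol = grid$nx)
  structure(list(x = grid$ox + (seq_len(grid$nx) - 1L) * cell_size,
                 y = grid$oy + (seq_len(grid$ny) - 1L) * cell_size,
                 values = t(m), cell_size = cell_size,
                 window_radius = window_radius),
            class = "bap1_heatmap")
}

#' @export
print.bap1_heatmap <- function(x, ...) {
  cat(sprintf("Positivity heatmap: %d x %d grid (%g um cells), %d valued nodes, range %s\n",
              length(x$x), length(x$y), x$cell_size, sum(!is.na(x$values)),
              if (all(is.na(x$values))) "-" else
                sprintf("%.0f-%.0f%%", min(x$values, na.rm = TRUE),
                        max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Plot a positivity heatmap
#'
#' Blue (low) through green (intermediate) to red (high) percent-positive,
#' y axis flipped to match image convention.
#'
#' @param x a `bap1_heatmap`.
#' @param ... passed to [graphics::image()].
#' @export
plot.bap1_heatmap <- function(x, ...) {
  pal <- colorRampPalette(c("blue", "green", "red"))(64L)
  image(x$x, rev(-x$y), x$values[, rev(seq_along(x$y)), drop = FALSE],
        col = pal, zlim = c(0, 100), xlab = "x (um)", ylab = "-y (um)",
        useRaster = TRUE, ...)
  invisible(x)
}

#' Score one tumor across the four compartments
#'
#' Runs classification and the spatial scan and returns the full-section,
#' hot-spot, cold-spot and (when a base polyline exists) scleral-margin
#' percent-positive scores together with the heterogeneity in percentage
#' points.
#'
#' @param cells unlabeled or labeled cell table.
#' @param geometry a [tumor_geometry()].
#' @param threshold per-slide threshold from [calibrate_threshold()];
#'   ignored when `cells` are already labeled and `reclassify = FALSE`.
#' @param class_params a [classification_params()].
#' @param params a [scan_params()].
#' @param reclassify force re-running [classify_cells()].
#' @return a `bap1_measurements` list: `full_pct`, `hot_pct`, `cold_pct`,
#'   `scleral_pct` (NA without a base polyline), `heterogeneity_pp`, the
#'   three `bap1_spot`s, and cell counts.
#' @export
score_tumor <- function(cells, geometry, threshold = NULL,
                        class_params = classification_params(),
                        params = scan_params(), reclassify = FALSE) {
  if (reclassify || all(cells$label == "unclassified")) {
    if (is.null(threshold))
      abort_validation("threshold required to classify unlabeled cells")
    cells <- classify_cells(cells, geometry, threshold, class_params)
  }
  full <- full_section_proportion(cells)
  hot <- find_extreme_spot(cells, geometry, params, mode = "max")
  cold <- find_extreme_spot(cells, geometry, params, mode = "min")
  scleral <- if (is.null(geometry$base)) NULL
    else find_scleral_margin_spot(cells, geometry, params)
  structure(list(
    full_pct = full, hot_pct = hot$proportion, cold_pct = cold$proportion,
    scleral_pct = if (is.null(scleral)) NA_real_ else scleral$proportion,
    heterogeneity_pp = heterogeneity(hot$proportion, cold$proportion),
    hot = hot, cold = cold, scleral = scleral,
    n_cells = nrow(cells),
    n_classifiable = sum(cells$label %in% c("positive", "negative"))),
    class = "bap1_measurements")
}

#' @export
print.bap1_measurements <- function(x, ...) {
  cat(sprintf(paste0(
    "BAP-1 compartment scores (%d cells, %d classifiable)\n",
    "  full section: %5.1f%%\n  hot spot:     %5.1f%%\n",
    "  cold spot:    %5.1f%%\n  scleral:      %s\n",
    "  heterogeneity: %.1f pp\n"),
    x$n_cells, x$n_classifiable, x$full_pct, x$hot_pct, x$cold_pct,
    if (is.na(x$scleral_pct)) "n/a (no base polyline)"
    else sprintf("%5.1f%%", x$scleral_pct),
    x$heterogeneity_pp))
  invisible(x)
}
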