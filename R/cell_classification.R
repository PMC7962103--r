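# Per-slide exemplar calibration and positive/negative classification.
#
# Staining is binarized: any chromogen signal above the calibrated
# background level counts as positive; graded intensity scoring is
# deliberately not performed.

#' Classification parameters
#'
#' Nucleus-size gates and the (metadata-only) cytoplasm expansion used by
#' the upstream detector. The 30 square-micrometre floor removes
#' tumor-infiltrating lymphocytes, whose nuclei are smaller than melanoma
#' cell nuclei; the 300 square-micrometre ceiling removes fused or
#' mis-segmented objects.
#'
#' @param min_nucleus_area smallest nucleus retained, in square micrometres
#'   (default 30).
#' @param max_nucleus_area largest nucleus retained, in square micrometres
#'   (default 300).
#' @param cell_expansion cytoplasm expansion radius applied by the upstream
#'   detector, in micrometres (default 6). Carried as provenance metadata
#'   only; no geometry is expanded here.
#' @return a `bap1_class_params` list.
#' @export
classification_params <- function(min_nucleus_area = 30,
                                  max_nucleus_area = 300,
                                  cell_expansion = 6) {
  if (!(min_nucleus_area > 0 && min_nucleus_area < max_nucleus_area))
    abort_validation("need 0 < min_nucleus_area < max_nucleus_area")
  structure(list(min_nucleus_area = min_nucleus_area,
                 max_nucleus_area = max_nucleus_area,
                 cell_expansion = cell_expansion),
            class = "bap1_class_params")
}

#' Calibrate the positivity threshold from an exemplar pair
#'
#' Each slide is calibrated on one clearly BAP-1 positive cell (red
#' chromogen in the nucleus) and one clearly negative cell (hematoxylin
#' only), compensating for slide-to-slide differences in staining
#' intensity. The threshold is the midpoint of the two exemplar
#' intensities; cells strictly above it are called positive.
#'
#' @param positive_exemplar_od chromogen intensity of the designated
#'   positive cell.
#' @param negative_exemplar_od chromogen intensity of the designated
#'   negative cell.
#' @return the scalar threshold, strictly between the two exemplars.
#' @examples
#' calibrate_threshold(0.8, 0.2)  # 0.5
#' @export
calibrate_threshold <- function(positive_exemplar_od, negative_exemplar_od) {
  if (!is.finite(positive_exemplar_od) || !is.finite(negative_exemplar_od))
    abort_calibration("exemplar intensities must be finite")
  if (positive_exemplar_od <= negative_exemplar_od)
    abort_calibration(paste0(
      "positive exemplar intensity (", positive_exemplar_od,
      ") must exceed the negative exemplar (", negative_exemplar_od,
      "); re-pick the exemplar cells"))
  (positive_exemplar_od + negative_exemplar_od) / 2
}

#' Classify cells as BAP-1 positive, negative or excluded
#'
#' A cell is `excluded` when its centroid lies outside the ROI, inside any
#' exclusion polygon (boundary points count as inside in both cases), or
#' its nucleus area falls outside the size gates. Every remaining cell is
#' `positive` when its chromogen intensity strictly exceeds the threshold,
#' otherwise `negative` (intensity exactly at threshold is not "above
#' background", hence negative).
#'
#' @param cells a cell table (see [read_cell_table()]).
#' @param geometry a [tumor_geometry()].
#' @param threshold per-slide threshold from [calibrate_threshold()].
#' @param params a [classification_params()].
#' @return the cell table with `label` filled in; the three labels
#'   partition the rows.
#' @export
classify_cells <- function(cells, geometry, threshold,
                           params = classification_params()) {
  cells <- validate_cell_table(cells)
  stopifnot(inherits(geometry, "bap1_geometry"))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    abort_validation("threshold must be a single finite number")

  keep <- points_in_polygon(cells$x, cells$y, geometry$roi)
  for (ex in geometry$exclusions)
    keep <- keep & !points_in_polygon(cells$x, cells$y, ex)
  keep <- keep & cells$nucleus_area >= params$min_nucleus_area &
    cells$nucleus_area <= params$max_nucleus_area

  label <- ifelse(keep,
                  ifelse(cells$chromogen_od > threshold, "positive", "negative"),
                  "excluded")
  cells$label <- label
  cells
}

#' Proportion of BAP-1 positive cells in the full section
#'
#' Percent positive among classifiable (non-excluded) cells over the whole
#' tumor cross-section.
#'
#' @param cells a labeled cell table from [classify_cells()].
#' @return percent in \[0, 100\].
#' @export
full_section_proportion <- function(cells) {
  np <- sum(cells$label == "positive")
  nn <- sum(cells$label == "negative")
  if (np + nn == 0L)
    abort_empty("no classifiable cells in the section")
  100 * np / (np + nn)
}
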