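# On-disk dialects: TSV cell tables (upstream detector export), GeoJSON
# annotations, cohort CSV.

#' Column dialect for cell detection tables
#'
#' Whole-slide analysis tools export per-cell measurement tables with
#' tool-specific column names. A dialect maps the package's canonical field
#' names to the source columns so exports can be ingested without code
#' changes.
#'
#' @param x,y source column names of the nucleus centroid coordinates.
#' @param nucleus_area source column of the nucleus area (square units).
#' @param chromogen_od source column of the red-chromogen (BAP-1) intensity.
#' @param counterstain_od source column of the hematoxylin intensity.
#' @param cell_id optional source column of a per-cell identifier; row
#'   numbers are used when absent.
#' @param microns_per_unit scale from source coordinate units to micrometres
#'   (1 when the export is already in micrometres). Areas are scaled by its
#'   square.
#' @return a `bap1_dialect` list.
#' @export
cell_dialect <- function(x = "x", y = "y", nucleus_area = "nucleus_area",
                         chromogen_od = "chromogen_od",
                         counterstain_od = "counterstain_od",
                         cell_id = NULL, microns_per_unit = 1) {
  if (!is.numeric(microns_per_unit) || length(microns_per_unit) != 1L ||
      !is.finite(microns_per_unit) || microns_per_unit <= 0)
    abort_validation("microns_per_unit must be a single positive number")
  structure(list(x = x, y = y, nucleus_area = nucleus_area,
                 chromogen_od = chromogen_od,
                 counterstain_od = counterstain_od, cell_id = cell_id,
                 microns_per_unit = microns_per_unit),
            class = "bap1_dialect")
}

CELL_LABELS <- c("unclassified", "positive", "negative", "excluded")

new_cell_table <- function(cell_id, x, y, nucleus_area, chromogen_od,
                           counterstain_od,
                           label = rep("unclassified", length(x))) {
  df <- data.frame(cell_id = as.character(cell_id), x = as.numeric(x),
                   y = as.numeric(y), nucleus_area = as.numeric(nucleus_area),
                   chromogen_od = as.numeric(chromogen_od),
                   counterstain_od = as.numeric(counterstain_od),
                   label = as.character(label), stringsAsFactors = FALSE)
  validate_cell_table(df)
}

validate_cell_table <- function(df) {
  need <- c("cell_id", "x", "y", "nucleus_area", "chromogen_od",
            "counterstain_od", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_format(paste0("cell table missing column(s): ",
                        paste(miss, collapse = ", ")))
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    abort_validation("cell coordinates must be finite")
  if (any(!is.finite(df$nucleus_area) | df$nucleus_area <= 0))
    abort_validation("nucleus_area must be positive and finite")
  if (any(df$chromogen_od < 0, na.rm = TRUE) ||
      any(df$counterstain_od < 0, na.rm = TRUE))
    abort_validation("stain intensities must be >= 0")
  if (!all(df$label %in% CELL_LABELS))
    abort_validation("unknown cell label")
  df
}

#' Read a per-cell detection table
#'
#' Reads the tab-separated export of an upstream positive-cell detector
#' (one row per detected cell) and converts it to the package's canonical
#' cell table: columns `cell_id`, `x`, `y` (micrometres), `nucleus_area`
#' (square micrometres), `chromogen_od`, `counterstain_od` and `label`
#' (all rows start `"unclassified"`).
#'
#' @param path path to a TSV file with a header row.
#' @param dialect a [cell_dialect()] mapping canonical fields to source
#'   columns and carrying the unit scale.
#' @return a cell table `data.frame`.
#' @seealso [write_cell_table()], [classify_cells()]
#' @export
read_cell_table <- function(path, dialect = cell_dialect()) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mapped <- c(x = dialect$x, y = dialect$y, nucleus_area = dialect$nucleus_area,
              chromogen_od = dialect$chromogen_od,
              counterstain_od = dialect$counterstain_od)
  miss <- mapped[!(mapped %in% names(raw))]
  if (length(miss))
    abort_format(paste0("cell table is missing mapped column(s): ",
                        paste(miss, collapse = ", ")))
  num <- function(field) {
    v <- raw[[mapped[[field]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad))
      abort_format(sprintf("non-numeric value in column '%s' at row %d",
                           mapped[[field]], bad[1L]))
    out
  }
  m <- dialect$microns_per_unit
  ids <- if (!is.null(dialect$cell_id) && dialect$cell_id %in% names(raw))
    as.character(raw[[dialect$cell_id]]) else as.character(seq_len(nrow(raw)))
  new_cell_table(cell_id = ids, x = num("x") * m, y = num("y") * m,
                 nucleus_area = num("nucleus_area") * m^2,
                 chromogen_od = num("chromogen_od"),
                 counterstain_od = num("counterstain_od"))
}

#' Write a cell table
#'
#' Writes a canonical cell table as TSV with enough digits that a
#' read-back round-trips numerically (within 1e-9).
#'
#' @param cells a cell table `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  cells <- validate_cell_table(cells)
  out <- cells
  for (col in c("x", "y", "nucleus_area", "chromogen_od", "counterstain_od"))
    out[[col]] <- format(out[[col]], digits = 17, trim = TRUE, scientific = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- GeoJSON annotations ------------------------------------------------------

.geojson_ring <- function(geom) {
  if (identical(geom$type, "Polygon")) {
    ring <- geom$coordinates[[1L]]
  } else abort_format(paste0("unsupported geometry type: ", geom$type))
  as_ring(do.call(rbind, lapply(ring, function(p) unlist(p[1:2]))))
}

.geojson_line <- function(geom) {
  if (!identical(geom$type, "LineString"))
    abort_format(paste0("base feature must be a LineString, got ", geom$type))
  m <- do.call(rbind, lapply(geom$coordinates, function(p) unlist(p[1:2])))
  storage.mode(m) <- "double"
  unname(m)
}

#' Read tumor geometry from GeoJSON
#'
#' Reads a GeoJSON `FeatureCollection` in which each feature carries a
#' `classification` property: exactly one `"tumor"` polygon (the ROI), zero
#' or one `"base"` LineString (the scleral side of the tumor), and any
#' number of `"exclusion"` polygons. Coordinates are interpreted as
#' micrometres in image convention.
#'
#' @param path path to a GeoJSON file.
#' @param microns_per_unit scale from file units to micrometres.
#' @return a [tumor_geometry()] object.
#' @export
read_geometry <- function(path, microns_per_unit = 1) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    abort_format("geometry file must be a GeoJSON FeatureCollection")
  roi <- NULL; base <- NULL; exclusions <- list()
  for (f in gj$features) {
    cls <- f$properties$classification
    if (is.list(cls)) cls <- cls$name  # tolerate nested classification objects
    if (is.null(cls)) abort_format("feature without a 'classification' property")
    if (cls == "tumor") {
      if (!is.null(roi)) abort_format("more than one tumor ROI feature")
      roi <- .geojson_ring(f$geometry) * microns_per_unit
    } else if (cls == "base") {
      if (!is.null(base)) abort_format("more than one base feature")
      base <- .geojson_line(f$geometry) * microns_per_unit
    } else if (cls == "exclusion") {
      exclusions <- c(exclusions,
                      list(.geojson_ring(f$geometry) * microns_per_unit))
    } else abort_format(paste0("unknown classification: ", cls))
  }
  if (is.null(roi)) abort_format("geometry file contains no tumor ROI feature")
  tumor_geometry(roi, base = base, exclusions = exclusions,
                 microns_per_unit = microns_per_unit)
}

.feature <- function(classification, type, coords) {
  list(type = "Feature",
       properties = list(classification = classification),
       geometry = list(type = type, coordinates = coords))
}

.ring_coords <- function(ring) {
  ring <- rbind(ring, ring[1L, , drop = FALSE])  # close the ring
  list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))
}

#' Write tumor geometry as GeoJSON
#'
#' Inverse of [read_geometry()]; coordinates are written in micrometres.
#'
#' @param geometry a [tumor_geometry()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "bap1_geometry"))
  feats <- list(.feature("tumor", "Polygon", .ring_coords(geometry$roi)))
  if (!is.null(geometry$base))
    feats <- c(feats, list(.feature("base", "LineString",
      lapply(seq_len(nrow(geometry$base)),
             function(i) as.numeric(geometry$base[i, ])))))
  for (ex in geometry$exclusions)
    feats <- c(feats, list(.feature("exclusion", "Polygon", .ring_coords(ex))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# -- cohort CSV ---------------------------------------------------------------

T_CATEGORIES <- as.vector(outer(1:4, letters[1:4], paste0))
GEP_CLASSES <- c("1a", "1b", "2")

#' Read a cohort metadata table
#'
#' One row per patient: `patient_id`, `age_years`, `sex`, `ajcc_t_category`
#' (e.g. `"3a"`), `gep_class` (`1a`, `1b`, `2`, or `NA` when the gene
#' expression assay was not run), `follow_up_months`, `metastasis_event`
#' (0/1), and optionally the four compartment scores `full_pct`, `hot_pct`,
#' `cold_pct`, `scleral_pct` (percent BAP-1 positive cells).
#'
#' @param path path to a CSV file.
#' @return a validated `data.frame`; `gep_class` keeps `NA` for missing.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_format(paste0("no such file: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age_years", "sex", "ajcc_t_category", "gep_class",
            "follow_up_months", "metastasis_event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_format(paste0("cohort table missing column(s): ",
                        paste(miss, collapse = ", ")))
  df$gep_class <- as.character(df$gep_class)
  df$gep_class[df$gep_class %in% c("NA", "Na", "na", "")] <- NA_character_
  bad <- !is.na(df$gep_class) & !(df$gep_class %in% GEP_CLASSES)
  if (any(bad))
    abort_validation(paste0("unknown gene expression class: ",
                            df$gep_class[which(bad)[1L]]))
  if (any(!is.finite(df$follow_up_months) | df$follow_up_months < 0))
    abort_validation("follow_up_months must be >= 0")
  bad <- !(tolower(df$ajcc_t_category) %in% T_CATEGORIES)
  if (any(bad))
    abort_validation(paste0("unknown AJCC T-category: ",
                            df$ajcc_t_category[which(bad)[1L]]))
  df$ajcc_t_category <- tolower(df$ajcc_t_category)
  df$metastasis_event <- as.logical(df$metastasis_event)
  if (any(is.na(df$metastasis_event)))
    abort_validation("metastasis_event must be 0/1 or TRUE/FALSE")
  for (col in intersect(c("full_pct", "hot_pct", "cold_pct", "scleral_pct"),
                        names(df))) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      abort_validation(paste0(col, " must lie in [0, 100]"))
  }
  df
}

#' Write a cohort table
#' @param cohort a cohort `data.frame` as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$metastasis_event <- as.integer(out$metastasis_event)
  out$gep_class[is.na(out$gep_class)] <- "NA"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
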