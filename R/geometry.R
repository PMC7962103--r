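# Planar geometry primitives shared by the readers, the classifier and the
# spatial scan. All polygons are two-column (x, y) matrices in micrometres,
# image convention (y-down); rings are stored open and treated as closed.

as_ring <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L || nrow(m) < 3L)
    abort_geometry("a polygon needs a two-column matrix with >= 3 vertices")
  # drop an explicitly repeated closing vertex
  n <- nrow(m)
  if (isTRUE(all(m[1L, ] == m[n, ]))) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3L) abort_geometry("degenerate polygon (< 3 distinct vertices)")
  if (!all(is.finite(m))) abort_geometry("polygon has non-finite coordinates")
  unname(m)
}

polygon_area <- function(ring) abs(pracma::polyarea(ring[, 1L], ring[, 2L]))

# Points on the boundary count as inside (closed polygons).
points_in_polygon <- function(x, y, ring) {
  if (length(x) == 0L) return(logical(0L))
  pracma::inpolygon(x, y, ring[, 1L], ring[, 2L], boundary = TRUE)
}

# orientation of the triplet (p, q, r); 0 = collinear
.orient <- function(px, py, qx, qy, rx, ry) {
  v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
  sign(v)
}

.on_segment <- function(px, py, qx, qy, rx, ry) {
  # r collinear with pq: does r lie within the segment's bounding box?
  rx >= pmin(px, qx) & rx <= pmax(px, qx) & ry >= pmin(py, qy) & ry <= pmax(py, qy)
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- .orient(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  d2 <- .orient(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  if (d1 != d2 && d3 != d4) return(TRUE)
  (d1 == 0 && .on_segment(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])) ||
  (d2 == 0 && .on_segment(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])) ||
  (d3 == 0 && .on_segment(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])) ||
  (d4 == 0 && .on_segment(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2]))
}

# Simple-polygon check: no two non-adjacent edges intersect. O(n^2), fine for
# annotation-sized rings.
polygon_is_simple <- function(ring) {
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # skip adjacent edges (shared endpoint) including the wrap-around pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(ring[i, ], ring[nxt[i], ], ring[j, ], ring[nxt[j], ]))
        return(FALSE)
    }
  }
  TRUE
}

polygons_overlap <- function(a, b) {
  if (any(points_in_polygon(a[, 1L], a[, 2L], b))) return(TRUE)
  if (any(points_in_polygon(b[, 1L], b[, 2L], a))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  nxa <- c(seq_len(na)[-1L], 1L); nxb <- c(seq_len(nb)[-1L], 1L)
  for (i in seq_len(na)) for (j in seq_len(nb))
    if (segments_intersect(a[i, ], a[nxa[i], ], b[j, ], b[nxb[j], ])) return(TRUE)
  FALSE
}

# Minimum Euclidean distance from each point to an open polyline
# (point-to-segment, vectorised over points).
dist_to_polyline <- function(x, y, line) {
  if (nrow(line) < 2L) abort_geometry("polyline needs >= 2 vertices")
  best <- rep(Inf, length(x))
  for (i in seq_len(nrow(line) - 1L)) {
    ax <- line[i, 1L]; ay <- line[i, 2L]
    bx <- line[i + 1L, 1L]; by <- line[i + 1L, 2L]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(x)) else pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / L2))
    dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    best <- pmin(best, sqrt(dx * dx + dy * dy))
  }
  best
}

#' Construct a tumor geometry
#'
#' Bundles the tumor region of interest (ROI), the optional base polyline
#' marking the scleral side, and any exclusion polygons (necrosis,
#' hemorrhage, inflammation, heavy pigment) into a validated object.
#'
#' @param roi two-column matrix of ROI vertices (micrometres, image
#'   convention: origin top-left, y increases downward). Must be a simple
#'   (non-self-intersecting) polygon.
#' @param base optional two-column matrix: open polyline marking the tumor
#'   base toward the sclera.
#' @param exclusions list of polygon matrices; each must overlap the ROI.
#' @param microns_per_unit scale factor recorded for provenance (coordinates
#'   are already in micrometres once constructed).
#' @return an object of class `bap1_geometry`.
#' @export
tumor_geometry <- function(roi, base = NULL, exclusions = list(),
                           microns_per_unit = 1) {
  roi <- as_ring(roi)
  if (!polygon_is_simple(roi))
    abort_geometry("ROI polygon is self-intersecting")
  if (!is.null(base)) {
    base <- as.matrix(base)
    storage.mode(base) <- "double"
    if (ncol(base) != 2L || nrow(base) < 2L)
      abort_geometry("base polyline needs a two-column matrix with >= 2 vertices")
  }
  exclusions <- lapply(exclusions, as_ring)
  for (ex in exclusions)
    if (!polygons_overlap(ex, roi))
      abort_geometry("an exclusion polygon does not intersect the ROI")
  structure(list(roi = roi, base = base, exclusions = exclusions,
                 microns_per_unit = microns_per_unit),
            class = "bap1_geometry")
}

#' @export
print.bap1_geometry <- function(x, ...) {
  cat(sprintf("Tumor geometry: ROI %d vertices, area %.3f mm^2; %s; %d exclusion(s)\n",
              nrow(x$roi), polygon_area(x$roi) / 1e6,
              if (is.null(x$base)) "no base polyline"
              else sprintf("base polyline %d vertices", nrow(x$base)),
              length(x$exclusions)))
  invisible(x)
}
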