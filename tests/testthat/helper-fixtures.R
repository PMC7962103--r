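# In-code fixtures and independent oracles shared across the suite.

# simple rectangular tumor with the base along the bottom edge
square_geom <- function(side = 1000, base = TRUE) {
  tumor_geometry(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
                 base = if (base) rbind(c(0, side), c(side, side)))
}

# build a canonical cell table directly (bypasses the readers)
make_cells <- function(x, y, nucleus_area = 50, chromogen_od = 0.1,
                       counterstain_od = 0.5, label = "unclassified") {
  n <- length(x)
  data.frame(cell_id = as.character(seq_len(n)), x = x, y = y,
             nucleus_area = rep_len(nucleus_area, n),
             chromogen_od = rep_len(chromogen_od, n),
             counterstain_od = rep_len(counterstain_od, n),
             label = rep_len(label, n), stringsAsFactors = FALSE)
}

# uniform labeled cells in a rectangle, positivity p
random_labeled_cells <- function(n, p, xmax = 1000, ymax = 1000) {
  make_cells(runif(n, 0, xmax), runif(n, 0, ymax),
             label = ifelse(runif(n) < p, "positive", "negative"))
}

# Exhaustive scan oracle: evaluates every candidate grid node by direct
# Euclidean distance and applies the documented tie rule. Independent of
# the package's accumulation algorithm (shares only the grid definition).
brute_extreme_spot <- function(cells, geometry, params, mode,
                               constraint = NULL) {
  s <- params$candidate_spacing
  roi <- geometry$roi
  ox <- floor(min(roi[, 1]) / s) * s
  oy <- floor(min(roi[, 2]) / s) * s
  gx <- seq(ox, max(roi[, 1]), by = s)
  gy <- seq(oy, max(roi[, 2]), by = s)
  cand <- expand.grid(x = gx, y = gy)
  keep <- pracma::inpolygon(cand$x, cand$y, roi[, 1], roi[, 2],
                            boundary = TRUE)
  if (!is.null(constraint)) keep <- keep & constraint(cand$x, cand$y)
  cand <- cand[keep, , drop = FALSE]
  cl <- cells[cells$label %in% c("positive", "negative"), , drop = FALSE]
  r2 <- (params$spot_diameter / 2)^2
  res <- t(vapply(seq_len(nrow(cand)), function(i) {
    d2 <- (cl$x - cand$x[i])^2 + (cl$y - cand$y[i])^2
    inside <- d2 <= r2
    c(np = sum(inside & cl$label == "positive"), nt = sum(inside))
  }, c(np = 0, nt = 0)))
  ok <- res[, "nt"] >= params$min_cells_per_spot
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]; res <- res[ok, , drop = FALSE]
  prop <- res[, "np"] / res[, "nt"]
  key <- if (mode == "max") -prop else prop
  i <- order(key, -res[, "nt"], cand$y, cand$x)[1L]
  list(center = c(cand$x[i], cand$y[i]),
       n_positive = unname(res[i, "np"]),
       n_negative = unname(res[i, "nt"] - res[i, "np"]),
       proportion = unname(100 * res[i, "np"] / res[i, "nt"]))
}

# 1-D Newton maximizer of the Cox partial log-likelihood (Breslow ties),
# used as the oracle for tiny fits.
newton_cox <- function(x, time, event, tol = 1e-12, maxit = 200L) {
  score <- function(b) {
    s <- 0; i1 <- 0
    for (i in which(event == 1L)) {
      risk <- time >= time[i]
      w <- exp(b * x[risk])
      mu <- sum(w * x[risk]) / sum(w)
      v <- sum(w * x[risk]^2) / sum(w) - mu^2
      s <- s + (x[i] - mu); i1 <- i1 + v
    }
    c(s, i1)
  }
  b <- 0
  for (it in seq_len(maxit)) {
    sv <- score(b)
    if (abs(sv[2]) < 1e-300) break
    step <- sv[1] / sv[2]
    b <- b + step
    if (abs(step) < tol) break
  }
  b
}

# Mann-Whitney pair-count AUC oracle
pair_count_auc <- function(scores, state) {
  s1 <- scores[as.logical(state)]; s0 <- scores[!as.logical(state)]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

write_geojson_fixture <- function(path, roi, base = NULL, exclusions = list()) {
  feat <- function(cls, type, coords)
    list(type = "Feature", properties = list(classification = cls),
         geometry = list(type = type, coordinates = coords))
  ring <- function(m) {
    m <- rbind(m, m[1, ])
    list(lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))
  }
  feats <- list(feat("tumor", "Polygon", ring(roi)))
  if (!is.null(base))
    feats <- c(feats, list(feat("base", "LineString",
      lapply(seq_len(nrow(base)), function(i) as.numeric(base[i, ])))))
  for (ex in exclusions) feats <- c(feats, list(feat("exclusion", "Polygon", ring(ex))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}
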