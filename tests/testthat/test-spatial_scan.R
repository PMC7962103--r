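test_that("spot_proportion counts by inclusive Euclidean distance", {
  cells <- make_cells(c(0, 100, 200, 250, 400), rep(0, 5),
                      label = c("positive", "positive", "positive",
                                "negative", "positive"))
  r <- spot_proportion(cells, center = c(0, 0), diameter = 500)
  expect_equal(r$n_positive, 3L)  # the cell at exactly r = 250 is included
  expect_equal(r$n_negative, 1L)
  expect_equal(r$proportion, 75)

  # empty window sentinel
  r <- spot_proportion(cells, center = c(5000, 5000), diameter = 500)
  expect_true(is.na(r$proportion))
  expect_equal(r$n_positive + r$n_negative, 0L)
})

test_that("spot_proportion matches a brute-force distance sort", {
  set.seed(31)
  cells <- random_labeled_cells(100, p = 0.4)
  center <- c(500, 500)
  d <- sqrt((cells$x - center[1])^2 + (cells$y - center[2])^2)
  radius <- sort(d)[10]  # window covering exactly the 10 nearest cells
  r <- spot_proportion(cells, center, diameter = 2 * radius)
  nearest <- order(d)[1:10]
  expect_equal(r$n_positive + r$n_negative, 10L)
  expect_equal(r$proportion,
               100 * mean(cells$label[nearest] == "positive"))
})

test_that("homogeneous tumors give equal hot and cold spots", {
  set.seed(32)
  g <- square_geom(1500)
  cells <- make_cells(runif(3000, 0, 1500), runif(3000, 0, 1500),
                      label = "positive")
  p <- scan_params()
  hot <- find_extreme_spot(cells, g, p, mode = "max")
  cold <- find_extreme_spot(cells, g, p, mode = "min")
  expect_equal(hot$proportion, 100)
  expect_equal(cold$proportion, 100)
  # identical extreme value => identical deterministic tie-break pick
  expect_equal(hot$center, cold$center)
})

test_that("fast scan equals the exhaustive oracle exactly", {
  p <- scan_params(min_cells_per_spot = 20)
  for (seed in 1:4) {
    set.seed(seed)
    g <- generate_geometry(2, 1)
    cells <- make_cells(runif(1500, 0, 2000), runif(1500, 0, 1000),
                        label = ifelse(runif(1500) < 0.35, "positive",
                                       "negative"))
    cells <- cells[points_in_polygon(cells$x, cells$y, g$roi), ]
    for (mode in c("max", "min")) {
      fast <- find_extreme_spot(cells, g, p, mode = mode)
      slow <- brute_extreme_spot(cells, g, p, mode)
      expect_identical(fast$center, slow$center)
      expect_identical(fast$n_positive + fast$n_negative,
                       as.integer(slow$n_positive + slow$n_negative))
      expect_identical(fast$proportion, slow$proportion)
    }
  }
})

test_that("planted hot and cold discs are recovered", {
  geom <- generate_geometry(4, 2)
  spec <- pattern_spec(width_mm = 4, height_mm = 2, cell_density = 2500,
                       background_positivity = 0.30,
                       planted_spots = list(
                         list(center = c(2800, 800), radius = 250,
                              positivity = 0.95),
                         list(center = c(1200, 1400), radius = 250,
                              positivity = 0.05)),
                       seed = 7)
  sim <- generate_cells(geom, spec)
  thr <- calibrate_threshold(sim$exemplar$positive_exemplar_od,
                             sim$exemplar$negative_exemplar_od)
  cells <- classify_cells(sim$cells, geom, thr)
  hot <- find_extreme_spot(cells, geom, mode = "max")
  cold <- find_extreme_spot(cells, geom, mode = "min")
  expect_lt(sqrt(sum((hot$center - c(2800, 800))^2)), 250)
  expect_lt(sqrt(sum((cold$center - c(1200, 1400))^2)), 250)
  expect_gt(hot$proportion, 85)
  expect_lt(cold$proportion, 15)
})

test_that("scan result is invariant to cell ordering", {
  set.seed(33)
  g <- square_geom(1200)
  cells <- random_labeled_cells(2000, p = 0.5, xmax = 1200, ymax = 1200)
  p <- scan_params()
  a <- find_extreme_spot(cells, g, p, mode = "min")
  b <- find_extreme_spot(cells[sample(nrow(cells)), ], g, p, mode = "min")
  expect_identical(a$center, b$center)
  expect_identical(a$n_positive, b$n_positive)
  expect_identical(a$n_negative, b$n_negative)
})

test_that("scleral spot equals cold spot when the cold center is in the band", {
  set.seed(34)
  g <- square_geom(1500)  # base along y = 1500
  # cold region near the base
  n <- 4000
  x <- runif(n, 0, 1500); y <- runif(n, 0, 1500)
  p <- ifelse(sqrt((x - 750)^2 + (y - 1200)^2) < 300, 0.05, 0.8)
  cells <- make_cells(x, y, label = ifelse(runif(n) < p, "positive",
                                           "negative"))
  sp <- scan_params()
  cold <- find_extreme_spot(cells, g, sp, mode = "min")
  scl <- find_scleral_margin_spot(cells, g, sp)
  expect_true(coldspot_within_base_band(cold, g, 1000))
  expect_identical(scl$center, cold$center)
  expect_identical(scl$proportion, cold$proportion)
})

test_that("scleral band errors without a base polyline or cells in the band", {
  g_nobase <- square_geom(1000, base = FALSE)
  cells <- random_labeled_cells(500, 0.5)
  expect_error(find_scleral_margin_spot(cells, g_nobase),
               class = "bap1_geometry_error")
  expect_error(coldspot_within_base_band(
    find_extreme_spot(cells, g_nobase, scan_params(min_cells_per_spot = 10)),
    g_nobase), class = "bap1_geometry_error")

  g <- tumor_geometry(rbind(c(0, 0), c(1000, 0), c(1000, 5000), c(0, 5000)),
                      base = rbind(c(0, 5000), c(1000, 5000)))
  top_cells <- make_cells(runif(500, 0, 1000), runif(500, 0, 500),
                          label = "positive")  # all far from the base
  expect_error(find_scleral_margin_spot(top_cells, g, scan_params()),
               class = "bap1_no_spot_error")
})

test_that("band membership at exactly the margin distance is inclusive", {
  g <- square_geom(2000)  # base at y = 2000
  mk_spot <- function(yc) {
    cells <- make_cells(runif(500, 0, 2000), runif(500, yc - 50, yc + 50),
                        label = "positive")
    find_extreme_spot(cells, g, scan_params(min_cells_per_spot = 10),
                      mode = "min")
  }
  expect_true(coldspot_within_base_band(mk_spot(1600), g, 1000))   # 0.4 mm
  expect_true(coldspot_within_base_band(mk_spot(1000), g, 1000))   # exactly 1 mm
  expect_false(coldspot_within_base_band(mk_spot(0), g, 1000))     # 2 mm
})

test_that("compartment ordering holds on synthetic tumors", {
  for (seed in 1:6) {
    geom <- generate_geometry(3, 1.5)
    spec <- pattern_spec(width_mm = 3, height_mm = 1.5, cell_density = 2500,
                         background_positivity = runif(1, 0.2, 0.8),
                         smooth_field = list(length_scale = 800,
                                             amplitude = 1.0),
                         seed = 100 + seed)
    sim <- generate_cells(geom, spec)
    thr <- calibrate_threshold(sim$exemplar$positive_exemplar_od,
                               sim$exemplar$negative_exemplar_od)
    m <- score_tumor(sim$cells, geom, thr)
    expect_gte(m$hot_pct, m$full_pct)
    expect_gte(m$full_pct, m$cold_pct)
    expect_gte(m$scleral_pct, m$cold_pct)
    expect_gte(m$heterogeneity_pp, 0)
  }
})

test_that("heatmap reflects local structure and handles degenerate input", {
  g <- square_geom(1000)
  homog <- make_cells(runif(3000, 0, 1000), runif(3000, 0, 1000),
                      label = "positive")
  hm <- build_heatmap(homog, g, cell_size = 100, window_radius = 200)
  vals <- hm$values[!is.na(hm$values)]
  expect_true(length(vals) > 0 && all(vals == 100))

  set.seed(35)
  x <- runif(6000, 0, 1000); y <- runif(6000, 0, 1000)
  hot <- sqrt((x - 300)^2 + (y - 300)^2) < 200
  cells <- make_cells(x, y, label = ifelse(hot & runif(6000) < 0.95, "positive",
                                    ifelse(runif(6000) < 0.1, "positive",
                                           "negative")))
  hm <- build_heatmap(cells, g, cell_size = 50, window_radius = 150)
  peak <- which(hm$values == max(hm$values, na.rm = TRUE), arr.ind = TRUE)[1, ]
  px <- hm$x[peak[1]]; py <- hm$y[peak[2]]
  expect_lt(sqrt((px - 300)^2 + (py - 300)^2), 200)

  empty <- make_cells(numeric(0), numeric(0))
  hm <- build_heatmap(empty, g, cell_size = 100, window_radius = 200)
  expect_true(all(is.na(hm$values)))
})

test_that("window area matches the analytic circle area", {
  expect_equal(spot_area_mm2(500), pi * 0.25^2)
  expect_equal(round(spot_area_mm2(500), 1), 0.2)
})

test_that("no-valid-spot error when the cell floor cannot be met", {
  g <- square_geom(1000)
  few <- random_labeled_cells(10, 0.5)
  expect_error(find_extreme_spot(few, g, scan_params(min_cells_per_spot = 100)),
               class = "bap1_no_spot_error")
})
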