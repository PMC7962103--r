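# bap1scan

Intratumor heterogeneity of BAP-1 immunohistochemistry in uveal melanoma,
quantified from per-cell detections.

Loss of nuclear BAP-1 is among the strongest markers of metastatic risk in
uveal melanoma, but its expression varies across a tumor cross-section:
where you measure changes what you conclude. `bap1scan` takes the per-cell
table exported by a whole-slide image analysis tool (centroid, nucleus
area, stain intensities), together with GeoJSON annotations of the tumor
ROI, its scleral base and any exclusion regions, and computes:

* per-slide **exemplar-calibrated classification** of every cell as BAP-1
  positive/negative (midpoint threshold between a designated positive and
  negative cell; nucleus area gated to [30, 300] µm²; exclusion regions
  masked);
* a **circular-window spatial scan** locating the *hot spot*, *cold spot*
  and *scleral-margin* minimum — 0.5 mm-diameter windows
  (`π(0.25)² ≈ 0.196 mm²`, one 400× high-power field) evaluated
  exhaustively on a 50 µm candidate grid — plus positivity heatmaps;
* **intratumor heterogeneity** `hot − cold` in percentage points,
  semi-ellipsoid tumor volume `π/6·t·lbd²`, and an 11-family regression
  screen of heterogeneity against volume;
* **prognostics** on the percent of BAP-1 *negative* cells per
  compartment: Youden-index ROC cutoffs (Mann–Whitney AUC, Hanley–McNeil
  SE), dichotomization into BAP-1 high/low, Kaplan–Meier/log-rank,
  univariate Cox, and likelihood-ratio χ² change between nested Cox
  models (which region adds prognostic information to which);
* a **synthetic-data module** — seeded generators for dome-shaped tumor
  geometries, marked cell point patterns with planted hot/cold discs or
  smooth positivity fields, and survival-linked cohorts — so the whole
  pipeline is testable with no patient data.

## Worked example

Simulate one tumor with a planted hot (95%) and cold (5%) disc on a 45%
background, then run the full per-tumor pipeline:

```r
library(bap1scan)

geom <- generate_geometry(width_mm = 6, height_mm = 3)
spec <- pattern_spec(width_mm = 6, height_mm = 3, cell_density = 1500,
                     background_positivity = 0.45,
                     planted_spots = list(
                       list(center = c(4200, 1500), radius = 250, positivity = 0.95),
                       list(center = c(1800, 2400), radius = 250, positivity = 0.05)),
                     seed = 11)
sim <- generate_cells(geom, spec)

thr <- calibrate_threshold(sim$exemplar$positive_exemplar_od,
                           sim$exemplar$negative_exemplar_od)
m <- score_tumor(sim$cells, geom, thr)
m
#> BAP-1 compartment scores (21098 cells, 20043 classifiable)
#>   full section:  44.7%
#>   hot spot:      94.2%
#>   cold spot:      5.2%
#>   scleral:        5.2%
#>   heterogeneity: 89.0 pp
m$hot
#> hot spot at (4200, 1500) um: 94.2% positive (277+/17-, d = 500 um)
coldspot_within_base_band(m$cold, geom)
#> [1] TRUE
```

The scan recovered both planted disc centers exactly and their
proportions within sampling noise; the full-section score sits between
the extrema, and this tumor's cold spot lies within 1 mm of the scleral
base. For real data, replace the generator calls with
`read_cell_table()` (a column dialect maps your tool's export schema) and
`read_geometry()`, and feed per-patient compartment scores plus clinical
covariates to `compartment_comparison()` for the ROC/KM/Cox/LRΔχ² stage.

A thin command-line wrapper is included at `inst/cli/bap1.R`
(subcommands `simulate`, `score`, `cohort`).

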