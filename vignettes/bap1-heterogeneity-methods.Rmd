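---
title: "Quantifying intratumor heterogeneity of BAP-1 expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumor heterogeneity of BAP-1 expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bap1scan)
```

## The problem

Loss of nuclear BAP-1 expression in uveal melanoma is a strong marker of
metastatic risk, but expression is spatially heterogeneous within a tumor:
the answer a pathologist gets can depend on where they look. `bap1scan`
quantifies that heterogeneity from per-cell immunohistochemistry detections
(the tabular export of a whole-slide analysis tool) by scoring four
compartments of each tumor cross-section:

1. **Full section** — percent BAP-1 positive cells over the whole ROI;
2. **Hot spot** — the 0.5 mm-diameter circle with the *highest* percent
   positive anywhere in the tumor;
3. **Cold spot** — the 0.5 mm circle with the *lowest* percent positive;
4. **Scleral margin** — the lowest-positivity 0.5 mm circle whose center
   lies within 1 mm of the tumor base toward the sclera.

A 0.5 mm circle covers `r round(spot_area_mm2(500), 3)` mm², about one
400× high-power field. Intratumor heterogeneity is the hot-minus-cold
difference in percentage points. Downstream, the percent of BAP-1
*negative* cells per compartment is calibrated into a prognostic cutoff by
ROC and carried into Kaplan–Meier, Cox and likelihood-ratio comparisons of
metastasis-free survival.

## Per-cell classification

Each slide is calibrated on one designated clearly-positive and one
clearly-negative cell, compensating for slide-to-slide staining
differences; the classification threshold is the **midpoint** of the two
exemplar intensities. The midpoint makes the rule symmetric in the two
exemplars and deterministic; "any staining above background" is then
operationalized as chromogen OD **strictly above** the threshold (a value
exactly at threshold is not above it, hence negative). Staining is
binarized only — no graded intensity scores.

Cells are excluded (and invisible to every later stage) when their
centroid falls outside the ROI or inside an exclusion polygon (boundary
points count as inside, i.e. polygons are closed), or when the nucleus
area falls outside [30, 300] µm². The 30 µm² floor removes
tumor-infiltrating lymphocytes, whose nuclei are smaller than melanoma
nuclei; it is the only defense against scoring non-tumor cells, a known
limitation of this class of pipeline. The 6 µm cytoplasm expansion used
by the upstream detector is carried as provenance metadata only.

## The spatial scan

The compartment extrema were originally found by repeated manual circle
placement over a positivity heatmap. The reproducible surrogate here is an
exhaustive evaluation over a **regular candidate grid** (default spacing
50 µm, snapped to multiples of the spacing so results do not depend on
cell ordering), clipped to the ROI. At each candidate center the window
proportion is computed over classifiable cells within 250 µm (boundary
inclusive). Implementation note: instead of looping over candidates, each
cell is accumulated into the bounded set of grid nodes within one radius
of it, which is algebraically identical to brute-force distance
evaluation (the test suite asserts exact equality against such an oracle)
but linear in the number of cells — a 2×10⁵-cell section scans in
seconds.

Design choices that needed deciding:

* **Minimum cells per window** (default 100): a window holding one cell
  would trivially attain 0% or 100%. Real spots hold on the order of a
  thousand cells, so a floor of 100 excludes only degenerate edge windows.
  It is exposed as a parameter.
* **Tie-breaking** among equal extreme proportions: larger classifiable
  count first (prefer better-supported extremes), then smallest y, then
  smallest x — a total order, so the scan is deterministic.
* **Windows may protrude** past the ROI; only in-ROI classifiable cells
  are counted. A circle hugging the tumor edge is legitimate — in the
  motivating material over half of cold spots sat against the scleral
  margin.
* **The scleral band constrains the window center only** (distance from
  center to the base polyline ≤ 1 mm, point-to-segment, boundary
  inclusive). Whether the *entire* circle must sit in the band is
  genuinely ambiguous in the source description; constraining the center
  mirrors how a circle is placed on a heatmap near a margin, and is the
  choice recorded here.

Two ordering invariants are asserted on every synthetic tumor: hot ≥ full
section ≥ cold (the full section is a mixture of windows; the extrema
bound it), and scleral ≥ cold (a constrained minimum cannot undercut the
global one).

## Heterogeneity, volume, and the curve screen

Heterogeneity is the paired per-tumor difference `hot − cold` in
percentage points (pp). Note the distinction between the mean of paired
differences and the difference of compartment means — the pipeline's
headline metric is the paired version.

Tumor volume assumes a semi-ellipsoid: `V = π/6 · t · lbd²` with apical
thickness `t` and largest basal diameter `lbd` in mm.

To ask whether heterogeneity is a function of volume, eleven classic
curve-estimation families are screened: linear, logarithmic, inverse,
quadratic, cubic, compound (`y = b₀b₁ˣ`), power (`y = b₀xᵇ¹`), S-shaped
(`y = e^(b₀+b₁/x)`), growth (`y = e^(b₀+b₁x)`), exponential
(`y = b₀e^(b₁x)`) and logistic (`y = 1/(1/u + b₀b₁ˣ)`). Each intrinsically
nonlinear family is fitted by least squares on its linearizing scale and
R², F and p are reported **on that fitted scale** — the convention of the
statistics packages these families come from, and therefore the scale on
which published values of this screen are comparable. Compound, growth
and exponential are re-parameterizations of the same regression and
deliberately report identical fit statistics. The logistic family needs a
fixed upper bound; it is set to `1.01 · max(y)`, a choice documented
rather than inherited (no standard value exists). Families whose
transform is undefined for the data (e.g. log of a non-positive volume)
are returned as unfit-able rather than failing the screen.

## Prognostics

All prognostic scores are **percent negative cells** (`100 − percent
positive`): BAP-1 *loss* marks risk, so higher scores mean higher risk and
cutoffs live on that scale.

* **ROC**: the AUC is the Mann–Whitney probability that a state-positive
  tumor outscores a state-negative one (ties ½) — identical, and asserted
  identical in exact arithmetic, to the trapezoidal area under the
  empirical ROC. The standard error is Hanley–McNeil with an
  asymptotic-normal 95% CI, and the p-value tests AUC = 0.5 with the
  corresponding z statistic (the "asymptotic" column convention of the
  statistics package this mirrors).
* **Cutoff**: "equal emphasis on sensitivity and specificity" is
  operationalized as maximizing Youden's J; ties prefer higher
  specificity, then the lower cutoff. The decision rule is `score ≥
  cutoff → low-BAP-1 (high-risk)`, boundary inclusive, so `dichotomize()`
  reproduces the quoted sensitivity/specificity bit-for-bit.
* **KM / log-rank / Cox** delegate to the `survival` package
  (product-limit estimates, two-sided log-rank, partial likelihood with
  Breslow ties by default, switchable to Efron). With no events the
  log-rank p is reported as 1 with a warning rather than NaN. A monotone
  partial likelihood (e.g. one group event-free, or a diverging estimate)
  flags the fit `unstable` instead of reporting a meaningless huge hazard
  ratio.
* **LRΔχ²** between nested Cox models is `2(LL_full − LL_base)` with df =
  parameters added; adding a constant (or collinear) covariate yields
  exactly 0 on 0 df, p = 1.

One design decision deserves emphasis: in `compartment_comparison()` the
LR cross-tables (region over region, region over AJCC T-category, region
over gene expression class) use the **continuous** percent-negative
scores as covariates, while the KM/Cox tables use the ROC-dichotomized
groups they conventionally report. If the base model only carried a
dichotomized group, the residual information in the underlying continuous
score would leak through any correlated compartment and masquerade as
"added prognostic value" — precisely the contrast the cross-table is
meant to isolate. With continuous scores, a compartment that truly
carries no extra information tests at its nominal level.

## The synthetic-data module

No patient-level data are distributed with this class of study, so the
generators are first-class, tested code rather than fixtures:

* **Geometry**: a dome (half-ellipse) over a flat base — the idealized
  choroidal melanoma cross-section; the flat edge is the base polyline.
* **Cells**: homogeneous Poisson positions clipped to the ROI; true
  positivity is a planted disc value where covered (nearest center wins),
  otherwise the logistic of background log-odds plus an optional smooth
  plane-wave field. Chromogen OD is drawn per true label (negatives
  centered on 0.2, positives 0.2 + separation, floored at 0), so the
  exemplar calibration is meaningful and classification is imperfect when
  the distributions overlap. A configured fraction of nuclei is drawn
  below 30 µm² to exercise the size filter. The observable table never
  contains the truth labels.
* **Cohort**: compartment scores built from a planted hot−cold gap
  (default mean 41 pp, SD 29 pp), exponential metastasis times under
  `h(t) = h₀ · exp(β_pp (neg_driver − 50) + β₂·[class 2])` with
  administrative censoring, and clinical covariates with uveal-melanoma-
  like margins. Defaults (`h₀ = 0.006`/month, `β_pp = 0.03`,
  `β₂ = 1.0`, 120-month horizon) put the event fraction near the ~65%
  of the motivating cohort. Each patient also gets a matching
  `pattern_spec()` planting their own hot/cold positivities as discs, so
  a full cohort can be simulated at cell level and pushed through the
  entire pipeline.

What the generators deliberately do **not** emulate: pigment artifacts
and the pathologist's re-calibration judgment, necrosis/hemorrhage
exclusion drawing, the empirical (bimodal) joint distribution of real
compartment scores, and non-administrative censoring. Passing tests
therefore demonstrate the pipeline's correctness and statistical
calibration on known structure — not that real cohort values are
recoverable.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so a
full cohort exercises every stage in minutes: tumors of roughly
15,000–35,000 cells (density 1,500–2,500 cells/mm² on 3–6 mm domes),
cohorts of 40–200 patients, and replicate counts of 100–500 for the
calibration and power simulations. Scan windows are evaluated on a 50 µm
grid (≤ half the window radius, so adjacent windows overlap
substantially). Planted-spot recovery uses discs of radius 250 µm holding
≥ 300 cells, recovered to within one disc radius with proportions inside
99% binomial intervals. The per-tumor scan is exact, so these sizes trade
only statistical resolution, not correctness; density can be raised to
~10⁴ cells/mm² to stress section-scale inputs.

Degenerate inputs are handled by structured conditions:
self-intersecting ROIs, missing base polylines, empty windows (a sentinel
the caller filters), zero classifiable cells, single-class ROC states and
event-free log-rank all raise or flag rather than silently producing
numbers.

## Known limitations

* The size filter is the only guard against non-tumor cells; macrophages
  and large lymphocytes inside the gates are scored.
* The scan optimizes over a fixed-diameter circle on a fixed grid;
  sub-grid extrema are resolved only to the grid spacing (50 µm against
  a 500 µm window).
* Cox results on cohorts of ~40 with few events are honest but fragile;
  the `unstable` flag should be respected rather than the point estimate
  quoted.
* The curve screen inherits the transformed-scale R² convention; it is
  not comparable to R² computed on the raw scale for the nonlinear
  families.
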