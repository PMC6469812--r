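---
title: "Methods: 2D cortical bone morphometry and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D cortical bone morphometry and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`cortimetry` measures the pore microstructure of cortical bone on a single
calibrated 2D cross-section and relates the resulting parameters to
skeletal outcome variables. The underlying biological model is the
remodeling-deficit picture of aging cortex: impaired refilling of
resorption cavities enlarges and coalesces Haversian canals, so the
informative signal is not total porosity per se but the *tail* of the
pore-diameter distribution — the share of porosity carried by pores wider
than a threshold (60–385 µm). All parameters are therefore derived from a
per-pore table with a well-defined diameter, not from bulk pixel counts
alone.

Assumptions baked into the chain:

* The section is a single connected cortical shell; the endosteal
  (marrow-facing) boundary is *supplied* by the analyst. Automatic
  endosteal detection is deliberately out of scope: in 2D, marrow notches
  and large endosteal pores are not distinguishable from the compartment
  geometry itself.
* Pixels are isotropic and small relative to the pores of interest
  (≤ 20 µm for reliable per-pore diameters; see the recovery results).
* Intensity separates tissue from background/pores either globally
  (Otsu) or after local-mean normalization (adaptive), i.e. the image is
  approximately two-level plus noise and possibly a smooth illumination
  field.

## Segmentation stage

The order is fixed and logged: **smooth → threshold → clean → trace →
build**.

* *Smoothing* (σ = 1.1 px, radius 2 px, truncated Gaussian) is disabled
  by default and intended for CT-density input. For near-resolution
  pores, pre-smoothing biases the largest-inscribed-circle diameter low
  by ~1–2 px, which is why the impedance-map path thresholds directly —
  this was measured on the synthetic suite, and it mirrors how the two
  modalities are treated in practice.
* *Thresholding.* Otsu maximizes between-class variance over a 256-bin
  histogram; a constant image is a defined fallback (all-background with
  a warning flag). The adaptive variant subtracts a local square-window
  mean (default 201 px ≈ 2.4 mm at 12 µm) with an offset of 0.1 of the
  intensity range; the offset keeps pure-background regions from
  speckling at the percolation threshold. Both record their effective
  threshold in the provenance attributes.
* *Cleaning.* 8-connected objects with area **strictly below 0.144 mm²**
  (exactly 1000 px at 12 µm) are removed; interior background components
  of exactly one pixel are filled. The operation is idempotent. The
  single-pixel fill deliberately erases pores at the resolution limit —
  a known, intended bias shared with the reference processing.
* *Periosteal tracing.* The tissue mask is morphologically closed with a
  disk of radius 0.48 mm. Closing is computed as an exact Euclidean
  distance-transform round trip (dilate: EDT of the complement ≤ r;
  erode: EDT of the mask > r), which is O(N) in the image regardless of
  radius, and the mask is padded by the radius first so the structuring
  element never interacts with the image border. The largest component
  is hole-filled to give the total-bone mask; its outer boundary is the
  periosteal contour.
* *Compartment and pores.* Cortical = total minus the endosteal
  interior. Pore candidates are 8-connected components (background
  4-connected, the standard duality) of `cortical & !tissue`; any
  component 8-adjacent to the marrow is excluded and removed from the
  compartment — such regions are treated as marrow, because nothing in a
  single section distinguishes them from endosteal notches.
* *Angular ROI.* A sector about the total-mask centroid (default width
  60°) restricts the compartment; a pore belongs to the ROI iff its
  centroid does, and kept pores contribute all their pixels. The 60°
  default is a package choice for the ultrasound-accessible anteromedial
  window; no authoritative numeric extent exists, so it is
  config-exposed.

## Morphometry stage

* **Po.Dm** (pore diameter) is the largest inscribed circle, computed
  from the Euclidean distance transform of the pore map as
  `2 · (max distance-to-nearest-non-pore-pixel-center − 0.5) · pixel size`.
  The −0.5 px convention makes a single pixel measure exactly 1 px and
  digital disks unbiased; it is verified against an exhaustive
  inscribed-circle search on every pore up to 400 px in the test suite.
  Diameter thresholds use strict comparison (`> 100 µm`), so a pore
  measuring exactly 100 µm is *not* large. Data files carry Po.Dm in mm;
  displays use µm (the field's tables mix both, which is flagged rather
  than silently normalized).
* **Ct.Th** (cortical thickness) is the mode of the per-vertex minimum
  distances from the periosteal to the endosteal contour, with 1 px
  histogram bins and ties broken toward the smaller bin (conservative
  thickness). With bin width → 0 this degenerates to the exact mode of
  quantized distances.
* **Areas.** Ct.Ar is the *compartment* area (pores included); the
  "cortical tissue" numerator of Ct.Wba excludes pores. This resolves the
  ambiguity between the two readings consistently with the porosity
  formula Ct.Po = 100·(1 − tissue/compartment).
* **Pore density** uses the compartment area as denominator
  (config-switchable to tissue area via the `corticalPixels` argument).
* Within-section SDs are population SDs (÷ n); cohort summaries use the
  sample convention (÷ n−1). Quantiles interpolate linearly between order
  statistics.
* Zero pores: Ct.Po = 0 is reported, ratio metrics (relPo.n_x,
  relCt.Po_x, Po.Dm summaries) are NA with a `"no-pores"` flag rather
  than 0 — they are undefined, not empty.

## Statistics stage

α = 0.05, two-sided, everywhere; no multiple-testing correction is
applied and the association table says so in its metadata. Pearson r
carries a Fisher-z 95% CI (`atanh(r) ± 1.96/√(n−3)`, back-transformed,
clamped to [−1, 1] at degenerate r = ±1). Partial correlation is the
Pearson correlation of the residuals of `x ~ z` and `y ~ z`; the closed
form `(r_xy − r_xz·r_yz)/√((1−r_xz²)(1−r_yz²))` is kept as an alternate
method and the two agree to 1e−12 (property-tested). Its p uses n − 3
degrees of freedom. Paired side comparisons gate on Shapiro–Wilk of the
differences (paired t if normal, Wilcoxon signed-rank otherwise);
identical sides are a degenerate case with p = 1. Model fits z-score all
variables with the sample SD when standardized, so a single-predictor β
equals Pearson r; adjusted R² = 1 − (1−R²)(n−1)/(n−p−1). Missing data are
handled pairwise-complete with n reported per cell. Left/right outcome
averaging is an explicit transform (`averageSides`) so correlations
against the average are always computed at matched n.

## The synthetic generator

The generator is the package's validation instrument, not a biophysical
simulation. One section is an annular shell (periosteal ellipse or
third-harmonic "rounded triangle", endosteal contour at a radial offset)
carrying non-overlapping circular pores:

* **Diameter mixture** (defaults): small-canal lognormal
  (median 42 µm, σ_log = 0.55) mixed with a large-pore lognormal
  (median 150 µm, σ_log = 0.45) at weight 0.06, clamped to
  [15 µm, 400 µm]; pore density 17 /mm². These values were set once from
  the field's reported tibial statistics (mean Po.Dm ≈ 50 µm, deciles
  ≈ 20/90 µm, ~5–10% of pores above 100 µm carrying about half the
  porosity) and are config-exposed; the distribution family itself is a
  modeling choice, since no empirical family is established.
* **Endosteal bias**: pores above 100 µm are rejection-sampled toward
  the endosteal side (acceptance linear in the normalized radial
  position, strength 0.6), reproducing the observed spatial pattern
  without inventing a growth model.
* **Geometry**: pores are filled circles with centers snapped to the
  pixel lattice — the ground-truth diameter is then unambiguous and
  recoverable within one pixel — with ≥ 1 px separation (enforced at
  1.5 px center clearance, above the √2 px 8-connectivity limit) and
  full clearance from both contours. Infeasible packings fail loudly
  with achieved vs. requested counts after bounded retries.
* **Intensity**: two levels (0.25 background/pores, 0.75 tissue) plus
  Gaussian noise given as a fraction of the separation (default 0.1);
  both thresholding paths are exercised by this model.
* **Truth**: contours are emitted as dense polygons whose star-shaped
  rasterization is pixel-identical to the emitted masks; true Ct.Po is
  the rasterized pore/compartment pixel ratio; relPo.n_x / relCt.Po_x
  truths are analytic on the planted list.

What it does *not* emulate: partial-volume edge blur, pore coalescence
and irregular pore shapes, osteonal texture, field inhomogeneity beyond
what the adaptive-threshold test constructs, and 3D continuity. Passing
the recovery tests therefore demonstrates correctness of the measurement
chain on well-posed input, not robustness to every real-image artifact.
Because real pores are irregular while planted pores are circles, the
generator's Ct.Po (~5–7%) sits at the low end of the realistic range for
its Po.Dm distribution: an inscribed circle carries less area in an
irregular pore than in a circular one at equal Po.Dm.

The cohort generator wraps per-subject sections (uniformly varied
geometry, pore density and large-pore weight) and plants linear outcomes
on standardized predictors: `y = β₁·z(latent) + β₂·z(relCt.Po_100µm) + ε`
with β = (0.72, −0.60) for stance and (0.78, −0.35) for fall loads, and
ε chosen for unit outcome variance unless overridden. The covariate-only
model then has R² ≈ 0.52 — the regime of interest where the large-pore
term must add predictive value. Outcomes are rescaled to realistic units
(aBMD 529 ± 96 mgHA/cm², stance ultimate force 2605 ± 903 N). The planted
outcome uses the *true* large-pore share while the analysis uses the
*measured* one, so recovered coefficients include realistic measurement
attenuation (true-vs-measured correlation ≈ 0.95).

## Validation problem sizes

The test suite and `scripts/acceptance.R` use sections scaled down from a
real tibia (periosteal semi-axes ~1.3–2.3 mm instead of ~15 mm) so that a
12 µm/px raster stays near 400 px; cortical band width, pore density and
the diameter mixture are kept realistic, which is what the per-pore
measurements actually see. Validation runs comprise: 100 sections for the
morphometry invariants and the brute-force inscribed-circle oracle; 50
sections at 12 µm/px and 10% noise through the full segmentation chain
(observed: Ct.Po within 0.1 pp, Ct.Th exact, matched Po.Dm within 1 px,
with ~16% of pores at the resolution limit removed by the cleaning rule);
one n = 500 cohort for standardized-β recovery (±0.1) plus 100 seeds at
n = 60 for the partial-correlation sign; 2000 replicates (n = 19) for
Fisher-CI coverage and 1000 for paired-test size; and 100 study-scale
(n = 19) cohorts for the adjusted-R² gain of the large-pore term.

## Known limitations

* 2D only: no sphere-fitting thickness, no 3D pore connectivity; a
  coalesced 3D network appears as separate 2D pores.
* The endosteal boundary is trusted as given; errors in it propagate
  directly into Ct.Ar, Ct.Po and Ct.Th.
* Pores opening through the periosteal surface (notch-like) are not
  specially handled; only marrow-touching exclusion is implemented.
* Near-resolution pores (< ~2 px) are systematically removed by the
  single-pixel fill; Po.D is therefore resolution-dependent, while
  Ct.Po, Ct.Th and the large-pore metrics are robust to it.
* The statistics layer implements the analysis conventions it documents
  (no multiplicity correction, pairwise deletion); it is a faithful
  reimplementation, not a recommendation of those conventions.
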