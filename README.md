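# cortimetry

Cortical bone loses mechanical competence with age not only by thinning
but by a characteristic remodeling failure: resorption cavities are
refilled late or not at all, so Haversian canals enlarge and coalesce. On
a 2D cross-section this shows up as a right-skewed pore-size distribution
in which a small fraction of pores with diameter above 100 µm carries a
disproportionate share of the total porosity, concentrated at the
endosteal side. `cortimetry` quantifies exactly this signature from
calibrated cross-section images (acoustic impedance maps at ~12 µm/px, or
CT density slices) and relates it to skeletal outcome variables such as
femoral-neck areal BMD and finite-element hip stiffness/strength, which
are consumed as given covariates.

It is intended for researchers doing quantitative bone imaging who need a
reproducible, fully testable 2D cortical morphometry chain: every stage
can be validated against a seeded synthetic generator with exact ground
truth.

## What it computes

Segmentation (fixed order smooth → threshold → clean → trace → build):

* tissue segmentation by global Otsu or adaptive local-mean thresholding;
* mask cleaning: removal of unconnected objects below 0.144 mm², filling
  of single-pixel pores;
* periosteal contour by morphological closing (disk radius 0.48 mm,
  implemented as an exact Euclidean distance-transform round trip) and
  hole filling;
* cortical compartment = total bone minus the interior of a *manually
  delineated* endosteal boundary (supplied as polygon or mask — never
  auto-detected); pores = 8-connected components of `cortical & !tissue`,
  with components touching the marrow excluded;
* optional angular ROI about the section centroid (the
  ultrasound-accessible anteromedial window; pores kept by centroid).

Morphometry, per section or ROI:

* pore diameter Po.Dm as the largest inscribed circle,
  `Po.Dm = 2 · (max EDT − ½ px)`, so a single-pixel pore measures 1 px;
* modal cortical thickness Ct.Th: the most frequent minimum distance
  between periosteal and endosteal contours (1 px histogram bins, ties
  toward the smaller distance);
* areas Tt.Ar / Ct.Ar / T.Ar, cortical tissue fraction Ct.Wba, cortical
  porosity Ct.Po = 100 · pore px / cortical px, pore density Po.D;
* threshold-stratified large-pore metrics at x ∈ {60, 100, 160, 300,
  385} µm (strict `Po.Dm > x`): densities Po.D_x, prevalences relPo.n_x,
  porosities Ct.Po_x and porosity shares relCt.Po_x, plus Po.Dm mean, SD
  and deciles, and calibrated intensity statistics (a vBMD surrogate).

Statistics: Shapiro–Wilk normality gating, paired t / Wilcoxon
signed-rank side comparisons, Pearson r with Fisher-z 95% CIs, partial
correlation controlling for `aBMD_neck`, and multivariate linear models
with standardized β and adjusted R² (α = 0.05, two-sided, no
multiple-testing correction — flagged in the output metadata).

## Worked example

```r
library(cortimetry)

spec <- sectionSpec(seed = 7)          # 12 um/px synthetic section
sec  <- generateCrossSection(spec)
sec$truth
#> GroundTruth: 112 planted pores
#>   Ct.Po 5.01 % | Po.D 17 /mm2 | Ct.Th 0.642 mm

res <- segmentSection(sec$image, endostealContour(sec$masks))
ms  <- computeMorphometry(res$masks, img = sec$image)
round(metricValues(ms)[c("Ct.Po", "Ct.Th", "Po.D", "relCt.Po_100")], 3)
#>        Ct.Po        Ct.Th         Po.D relCt.Po_100
#>        4.983        0.642       15.006       27.508
```

The recovered porosity (4.98%) sits within 0.03 pp of the planted truth
and the modal thickness is exact; the pore density is lower than the
planted 17/mm² because pores at the resolution limit are removed by the
single-pixel-fill rule, as in real processing.

Cohort analysis with a planted outcome model
(`y = 0.72·z(aBMD) − 0.60·z(relCt.Po_100µm) + ε`):

```r
ch  <- generateCohort(cohortSpec(n = 50, seed = 1))
fit <- fitLinearModel(ch$cohort$hvFE_Fu_stance,
                      ch$cohort[, c("aBMD_neck", "relCt.Po_100")])
round(fit$beta, 2)
#>    aBMD_neck relCt.Po_100
#>         0.79        -0.62
partialCorrelation(ch$cohort$relCt.Po_100, ch$cohort$hvFE_Fu_stance,
                   ch$cohort$aBMD_neck)$r
#> -0.83
```

The standardized coefficients recover the planted effects; the
large-pore share stays strongly negatively associated with simulated hip
strength after controlling for the aBMD-like covariate.

A thin command-line wrapper lives at `inst/cli/cortimetry.R`
(`simulate | segment | morph | stats | run` subcommands).

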