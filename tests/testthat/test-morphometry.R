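# Morphometry stage: inscribed-circle diameters against the brute-force
# oracle, modal thickness, areal and porosity arithmetic, scale behavior.

test_that("inscribed-circle diameters follow the half-pixel convention", {
  px <- 0.012
  lab <- matrix(0L, 30, 30)
  # digital disk of radius 5 px
  X <- matrix(1:30, 30, 30); Y <- t(X)
  lab[(X - 15)^2 + (Y - 15)^2 <= 25] <- 1L
  pd <- poreDiameters(lab, px)
  expect_lt(abs(pd$podm_mm - 0.120) / px, 1 + 1e-9)
  # 3 x 10 rectangle -> 3 px
  lab2 <- matrix(0L, 20, 20)
  lab2[5:7, 4:13] <- 1L
  pd2 <- poreDiameters(lab2, px)
  expect_equal(pd2$podm_mm, 3 * px, tolerance = 1e-9)
  expect_equal(pd2$area_mm2, 30 * px^2, tolerance = 1e-12)
  # single pixel -> 1 px
  lab3 <- matrix(0L, 5, 5); lab3[3, 3] <- 1L
  expect_equal(poreDiameters(lab3, px)$podm_mm, px, tolerance = 1e-9)
  # empty map -> empty table, not an error
  expect_identical(nrow(poreDiameters(matrix(0L, 4, 4), px)), 0L)
})

test_that("Po.Dm equals the brute-force inscribed-circle search on random
           blobs", {
  set.seed(3)
  px <- 0.012
  for (rep in 1:12) {
    m <- matrix(FALSE, 26, 26)
    m[8:18, 8:18] <- matrix(runif(121) < 0.75, 11, 11)
    lab <- label8(m)
    if (max(lab) == 0) next
    pd <- poreDiameters(lab, px)
    for (k in pd$label) {
      expect_equal(pd$podm_mm[pd$label == k],
                   bruteForcePoDm(lab == k, px), tolerance = 1e-9)
    }
  }
})

test_that("pore diameters respect the area bound", {
  sec <- generateCrossSection(smallSectionSpec(17))
  pd <- poreDiameters(poreLabels(sec$masks), pixelSize(sec$masks))
  px <- pixelSize(sec$masks)
  expect_true(all(pd$podm_mm <= 2 * sqrt(pd$area_mm2 / pi) + px + 1e-12))
  expect_true(all(pd$area_mm2 >= px^2 - 1e-15))
})

test_that("modal cortical thickness matches analytic geometry", {
  px <- 0.012
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  mk <- function(r, cx = 0) cbind((cx + r * cos(th)) / px, r * sin(th) / px)
  # concentric circles 10 / 7 mm
  expect_lt(abs(corticalThickness(mk(10), mk(7), px) - 3), px + 1e-12)
  # eccentric: inner circle shifted 1 mm; analytic minimum distance from an
  # outer point at angle phi is |P - c| - 7
  analytic <- sqrt((10 * cos(th) - 1)^2 + (10 * sin(th))^2) - 7
  mode <- cortimetry:::modalValue(analytic / px, 1) * px
  got <- corticalThickness(mk(10), mk(7, cx = 1), px)
  expect_lt(abs(got - mode), 2 * px + 1e-12)
  expect_error(corticalThickness(mk(10)[1:2, ], mk(7), px), "degenerate")
})

test_that("areal metrics are pixel-count arithmetic", {
  px <- 0.02
  ann <- annulusMasks(2, 1.2, px,
                      holes = data.frame(cx_px = 100, cy_px = 100, r_px = 3))
  v <- arealMetrics(ann)
  expect_equal(v[["Tt.Ar"]], sum(totalMask(ann)) * px^2, tolerance = 1e-12)
  expect_equal(v[["Ct.Ar"]], sum(corticalMask(ann)) * px^2, tolerance = 1e-12)
  expect_equal(v[["T.Ar"]], sum(tissueMask(ann)) * px^2, tolerance = 1e-12)
  expect_equal(v[["Ct.Wba"]],
               100 * sum(tissueMask(ann) & corticalMask(ann)) /
                 sum(totalMask(ann)), tolerance = 1e-12)
  # saturation: cortical = total, tissue everywhere
  full <- new("SectionMasks",
              tissue = matrix(TRUE, 10, 10), total = matrix(TRUE, 10, 10),
              cortical = matrix(TRUE, 10, 10),
              poreLabels = matrix(0L, 10, 10),
              periostealContour = annulusMasks(2, 1, px)@periostealContour,
              endostealContour = annulusMasks(2, 1, px)@endostealContour,
              pixelSize = px)
  expect_equal(arealMetrics(full)[["Ct.Wba"]], 100)
  empt <- initialize(full, total = matrix(FALSE, 10, 10),
                     cortical = matrix(FALSE, 10, 10),
                     tissue = matrix(FALSE, 10, 10))
  expect_error(arealMetrics(empt), "empty total mask")
})

test_that("porosity metrics are ratio arithmetic with strict thresholds", {
  px <- 0.012
  # cortical 10,000 px, pore 1,110 px -> Ct.Po = 11.1%
  pores <- data.frame(label = 1L, area_mm2 = 1110 * px^2, podm_mm = 0.1)
  expect_equal(porosityMetrics(pores, 10000, px)$values[["Ct.Po"]], 11.1,
               tolerance = 1e-9)
  # total pore area 1.0 mm2, area above 100 um 0.4 mm2 -> relCt.Po_100 = 40%
  pores2 <- data.frame(label = 1:2, area_mm2 = c(0.6, 0.4),
                       podm_mm = c(0.08, 0.2))
  v2 <- porosityMetrics(pores2, 10 / px^2, px)$values
  expect_equal(v2[["relCt.Po_100"]], 40, tolerance = 1e-9)
  # 170 pores in 10 mm2 -> Po.D = 17 per mm2
  pores3 <- data.frame(label = 1:170, area_mm2 = rep(1e-3, 170),
                       podm_mm = rep(0.03, 170))
  expect_equal(porosityMetrics(pores3, 10 / px^2, px)$values[["Po.D"]], 17,
               tolerance = 1e-9)
  # a strict threshold: a pore at exactly 100 um does not count as > 100 um
  poresEq <- data.frame(label = 1L, area_mm2 = 1e-3, podm_mm = 0.100)
  vEq <- porosityMetrics(poresEq, 10 / px^2, px)$values
  expect_equal(vEq[["relPo.n_100"]], 0)
  expect_gt(vEq[["relPo.n_60"]], 0)
  # zero pores: undefined ratios flagged and NA
  z <- porosityMetrics(poreDiameters(matrix(0L, 5, 5), px), 100, px)
  expect_equal(z$values[["Ct.Po"]], 0)
  expect_true(is.na(z$values[["relPo.n_100"]]))
  expect_true("no-pores" %in% z$flags)
})

test_that("threshold-stratified metrics are monotone and consistent at 0", {
  sec <- generateCrossSection(smallSectionSpec(23))
  pd <- poreDiameters(poreLabels(sec$masks), pixelSize(sec$masks))
  v <- porosityMetrics(pd, sum(corticalMask(sec$masks)),
                       pixelSize(sec$masks),
                       thresholdsUm = c(0, 60, 100, 160, 300, 385))$values
  for (fam in c("Po.D_", "relPo.n_", "Ct.Po_", "relCt.Po_")) {
    x <- v[paste0(fam, c(0, 60, 100, 160, 300, 385))]
    expect_true(all(diff(x) <= 1e-12), info = fam)
  }
  expect_equal(v[["Ct.Po_0"]], v[["Ct.Po"]], tolerance = 1e-12)
  expect_equal(v[["relCt.Po_0"]], 100, tolerance = 1e-12)
  expect_true(all(v[paste0("Ct.Po_", c(60, 100, 160))] <= v[["Ct.Po"]] + 1e-12))
})

test_that("calibrated intensity statistics apply the linear mapping", {
  img <- CalibratedImage(matrix(4, 6, 6), 0.012,
                         calibration = c(slope = 2.5, intercept = 1))
  v <- calibratedIntensityStats(img, matrix(TRUE, 6, 6))
  expect_equal(unname(v), c(2.5 * 4 + 1, 0), tolerance = 1e-12)
  img2 <- CalibratedImage(matrix(c(0, 2, 5, 5), 2, 2), 0.012,
                          calibration = c(slope = 1, intercept = 0))
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(unname(calibratedIntensityStats(img2, m2)), c(1, 1),
               tolerance = 1e-12)
  expect_error(calibratedIntensityStats(img2, matrix(FALSE, 2, 2)), "empty")
  noCal <- CalibratedImage(matrix(1, 3, 3), 0.012)
  expect_error(calibratedIntensityStats(noCal, matrix(TRUE, 3, 3)),
               "calibration")
})

test_that("doubling the pixel size scales lengths, areas and leaves ratios", {
  sec <- generateCrossSection(smallSectionSpec(29))
  m1 <- sec$masks
  m2 <- initialize(m1, pixelSize = 2 * pixelSize(m1))
  v1 <- metricValues(computeMorphometry(m1))
  # diameters double in mm, so the relative metrics are compared at
  # correspondingly scaled thresholds
  v2 <- metricValues(computeMorphometry(m2,
                                        thresholdsUm = 2 * c(60, 100, 160, 300, 385)))
  expect_equal(v2[["Ct.Th"]], 2 * v1[["Ct.Th"]], tolerance = 1e-9)
  expect_equal(v2[["Po.Dm_mean"]], 2 * v1[["Po.Dm_mean"]], tolerance = 1e-9)
  expect_equal(v2[["Tt.Ar"]], 4 * v1[["Tt.Ar"]], tolerance = 1e-9)
  expect_equal(v2[["Ct.Ar"]], 4 * v1[["Ct.Ar"]], tolerance = 1e-9)
  for (nm in c("Ct.Po", "Ct.Wba"))
    expect_equal(v2[[nm]], v1[[nm]], tolerance = 1e-9, info = nm)
  expect_equal(v2[["relPo.n_200"]], v1[["relPo.n_100"]], tolerance = 1e-9)
  expect_equal(v2[["relCt.Po_200"]], v1[["relCt.Po_100"]], tolerance = 1e-9)
  expect_equal(v2[["Po.D"]], v1[["Po.D"]] / 4, tolerance = 1e-9)
})

test_that("the morphometry vector carries the canonical column set", {
  sec <- generateCrossSection(smallSectionSpec(31))
  ms <- computeMorphometry(sec$masks, img = sec$image)
  expect_identical(names(metricValues(ms)), morphometryColumns())
  df <- as.data.frame(ms)
  expect_identical(names(df), morphometryColumns())
  expect_false(is.na(df[["vcal_mean"]]))
})
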