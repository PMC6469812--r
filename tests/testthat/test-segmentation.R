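# Segmentation stage: smoothing, thresholding, mask cleaning, periosteal
# tracing, cortical compartment construction and the angular ROI.

mkImage <- function(x, px = 0.012) CalibratedImage(x, px)
stripAttrs <- function(m) { attributes(m) <- list(dim = dim(m)); m }

test_that("Gaussian smoothing preserves constants and mass, rejects sigma <= 0", {
  cst <- mkImage(matrix(5, 20, 20))
  expect_equal(intensities(smoothImage(cst)), matrix(5, 20, 20),
               tolerance = 1e-12)
  # single bright pixel away from the border: kernel response sums to the
  # original value (normalized kernel)
  x <- matrix(0, 21, 21); x[11, 11] <- 3
  sm <- smoothImage(mkImage(x), sigmaPx = 1.1, radiusPx = 2)
  expect_equal(sum(intensities(sm)), 3, tolerance = 1e-9)
  expect_error(smoothImage(cst, sigmaPx = 0), "sigmaPx")
})

test_that("Otsu matches the exhaustive between-class-variance oracle", {
  set.seed(1)
  x <- matrix(sample(c(30, 100), 400, replace = TRUE), 20, 20)
  m <- segmentTissue(mkImage(x), "otsu")
  thr <- attr(m, "threshold")
  expect_gt(thr, 30); expect_lt(thr, 100)
  expect_identical(stripAttrs(m), x == 100)
  # oracle agreement on the implied classification for graded data
  y <- matrix(c(rnorm(200, 2, 0.3), rnorm(200, 5, 0.3)), 20, 20)
  mo <- segmentTissue(mkImage(y), "otsu")
  to <- bruteForceOtsu(y)
  expect_identical(stripAttrs(mo), y > to)
})

test_that("an all-background image yields an empty mask with a warning", {
  expect_warning(m <- segmentTissue(mkImage(matrix(0, 10, 10)), "otsu"),
                 "constant")
  expect_false(any(m))
  expect_true(attr(m, "constantInput"))
})

test_that("adaptive thresholding survives an illumination gradient that
           defeats global Otsu", {
  # 10x10 checkerboard pattern (levels 0 / 0.3) under a 0 -> 1 ramp
  n <- 200
  blk <- (outer(0:(n - 1) %/% 10, 0:(n - 1) %/% 10, "+") %% 2) == 0
  ramp <- matrix(seq(0, 1, length.out = n), n, n)
  img <- mkImage(ramp + ifelse(blk, 0.3, 0))
  ad <- segmentTissue(img, "adaptive", windowPx = 21, offsetFrac = 0.1)
  ot <- segmentTissue(img, "otsu")
  interior <- matrix(FALSE, n, n); interior[21:(n - 20), 21:(n - 20)] <- TRUE
  expect_lt(mean(ad[interior] != blk[interior]), 0.01)
  expect_gt(mean(ot[interior] != blk[interior]), 0.2)
})

test_that("mask cleaning removes sub-threshold objects and fills only
           single-pixel pores, idempotently", {
  px <- 0.012                      # 0.144 mm2 = exactly 1000 px
  m <- matrix(FALSE, 140, 140)
  m[2:28, 2:38] <- TRUE            # 27 x 37 = 999 px -> removed
  m[40:64, 60:99] <- TRUE          # 25 x 40 = 1000 px -> kept
  m[80:104, 60:103] <- TRUE        # 25 x 44 = 1100 px -> kept
  m[90, 70] <- FALSE               # single-pixel pore -> filled
  m[95, 80:81] <- FALSE            # 2-px pore -> retained
  cl <- cleanTissueMask(m, px, 0.144)
  expect_false(any(cl[2:28, 2:38]))
  expect_true(all(cl[40:64, 60:99]))
  expect_true(cl[90, 70])
  expect_false(any(cl[95, 80:81]))
  expect_true(all(cl[80:104, 60:103] == {
    k <- matrix(TRUE, 25, 44); k[16, 21:22] <- FALSE; k
  }))
  expect_identical(cleanTissueMask(cl, px, 0.144), cl)
})

test_that("periosteal tracing closes notches according to the disk radius", {
  px <- 0.025
  # solid disk, radius 5 mm: area within 2% of pi * 25
  disk <- annulusMasks(5, 0.001, px)
  tr <- tracePeriosteal(totalMask(disk), px, 0.48)
  expect_lt(abs(sum(tr$totalMask) * px^2 - pi * 25) / (pi * 25), 0.02)
  # annulus with a 0.5 mm-wide radial notch at angle 0
  px <- 0.05
  ann <- annulusMasks(4, 2.5, px)
  tis <- tissueMask(ann)
  dm <- dim(tis); c0 <- (dm[1] - 1) / 2
  X <- matrix(seq_len(dm[1]) - 1 - c0, dm[1], dm[2])
  Y <- matrix(seq_len(dm[2]) - 1 - c0, dm[1], dm[2], byrow = TRUE)
  notch <- X > 0 & abs(Y) * px <= 0.25
  tisN <- tis & !notch
  bridged <- tracePeriosteal(tisN, px, 0.48)$totalMask
  open <- tracePeriosteal(tisN, px, 0.10)$totalMask
  outerNotch <- notch & sqrt(X^2 + Y^2) * px > 3.2 & sqrt(X^2 + Y^2) * px < 3.9
  expect_true(all(bridged[outerNotch]))
  expect_false(all(open[outerNotch]))
  expect_error(tracePeriosteal(matrix(FALSE, 5, 5), px), "empty")
})

test_that("distance-transform closing equals the brute-force disk closing", {
  set.seed(7)
  for (r in c(2.0, 3.7)) {
    m <- matrix(runif(1600) < 0.25, 40, 40)
    expect_identical(cortimetry:::diskClose(m, r), bruteForceClosing(m, r))
  }
})

test_that("cortical compartment and pore labeling follow the marrow rule", {
  px <- 0.02
  ann <- annulusMasks(2, 1.2, px)
  masks <- buildCorticalMask(totalMask(ann), tissueMask(ann),
                             endostealContour(ann), px)
  expect_identical(corticalMask(masks), corticalMask(ann))
  expect_identical(max(poreLabels(masks)), 0L)
  # three planted holes -> exactly three labels
  dm <- dim(tissueMask(ann)); c0 <- (dm[1] - 1) / 2
  # hole centers in the cortical band (inner radius 60 px, outer 100 px)
  holes <- data.frame(cx_px = c0 + c(78, -80, 0), cy_px = c0 + c(0, 10, -82),
                      r_px = c(3, 4, 2))
  ann3 <- annulusMasks(2, 1.2, px, holes = holes)
  m3 <- buildCorticalMask(totalMask(ann3), tissueMask(ann3),
                          endostealContour(ann3), px)
  expect_identical(max(poreLabels(m3)), 3L)
  # a hole straddling the endosteal boundary is marrow, not a pore
  holesE <- data.frame(cx_px = c0 + 1.2 / px, cy_px = c0, r_px = 4)
  annE <- annulusMasks(2, 1.2, px, holes = holesE)
  mE <- buildCorticalMask(totalMask(annE), tissueMask(annE),
                          endostealContour(annE), px)
  expect_identical(max(poreLabels(mE)), 0L)
  # crossing contours are rejected
  thv <- seq(0, 2 * pi, length.out = 73)[-73]
  tooBig <- cbind(c0 + (2.5 / px) * cos(thv), c0 + (2.5 / px) * sin(thv))
  expect_error(buildCorticalMask(totalMask(ann), tissueMask(ann), tooBig, px),
               "crossing")
})

test_that("the angular ROI keeps pores by centroid and scales areas", {
  px <- 0.02
  ann <- annulusMasks(2, 1.2, px)
  full <- buildCorticalMask(totalMask(ann), tissueMask(ann),
                            endostealContour(ann), px)
  ident <- extractRoiUs(full, 0, 360)
  expect_identical(corticalMask(ident), corticalMask(full))
  quarter <- extractRoiUs(full, 0, 90)
  expect_lt(abs(sum(corticalMask(quarter)) / sum(corticalMask(full)) - 0.25),
            0.02 * 0.25 + 0.002)
  # pore centroid just outside a 60-degree sector is dropped, inside kept
  dm <- dim(tissueMask(ann)); c0 <- (dm[1] - 1) / 2
  rMid <- 1.6 / px
  holes <- data.frame(
    cx_px = c0 + rMid * cos(c(50, 20) * pi / 180),
    cy_px = c0 + rMid * sin(c(50, 20) * pi / 180),
    r_px = c(3, 3))
  annP <- annulusMasks(2, 1.2, px, holes = holes)
  mP <- buildCorticalMask(totalMask(annP), tissueMask(annP),
                          endostealContour(annP), px)
  roi <- extractRoiUs(mP, 0, 60)
  expect_identical(max(poreLabels(roi)), 1L)
  expect_error(extractRoiUs(full, 0, 0), "sectorWidthDeg")
})

test_that("pore labeling is 8-connected", {
  m <- matrix(FALSE, 8, 8)
  m[cbind(2:5, 2:5)] <- TRUE       # diagonal chain
  lab <- label8(m)
  expect_identical(max(lab), 1L)
  m[7, 7] <- TRUE
  expect_identical(max(label8(m)), 2L)
})

test_that("the full segmentation chain recovers a noisy synthetic section", {
  sec <- generateCrossSection(smallSectionSpec(5, noiseSD = 0.2))
  res <- segmentSection(sec$image, endostealContour(sec$masks),
                        pipelineConfig(simulate = list()))
  dis <- mean(tissueMask(res$masks) != tissueMask(sec$masks))
  expect_lt(dis, 0.01)             # < 1% of pixels at 20% noise
  expect_true(all(corticalMask(res$masks) | !(poreLabels(res$masks) > 0)))
})
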