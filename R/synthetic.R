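# Synthetic cross-section and cohort generation.
#
# Sections are scaled-down annular shells (periosteal ellipse or rounded
# triangle, endosteal contour at a radial offset) carrying a planted
# population of circular pores whose diameter distribution is a right-skewed
# lognormal mixture: a dominant small-canal component plus a heavy
# large-pore component biased towards the endosteal side. Pores are
# rasterized as filled circles so the ground-truth largest-inscribed-circle
# diameter is unambiguous.

#' Specification of one synthetic cross-section
#'
#' Bundles every parameter of the section generator. Defaults emulate an
#' elderly human tibia midshaft at reduced scale: pore density ~17 per mm2,
#' pore diameters from a lognormal mixture giving a mean inscribed-circle
#' diameter near 50 um with ~5-10 percent of pores above 100 um that carry
#' roughly half of the total porosity, large pores biased towards the
#' endosteal side.
#'
#' @param shape periosteal shape, `"ellipse"` or `"rounded-triangle"` (an
#'   ellipse modulated by a third angular harmonic of amplitude `triAmp`).
#' @param semiAxes periosteal semi-axes in mm, `c(a, b)`.
#' @param triAmp relative amplitude of the 3-lobe harmonic for
#'   `"rounded-triangle"`.
#' @param endoOffset radial distance from periosteal to endosteal contour,
#'   mm; must be positive and smaller than both semi-axes.
#' @param endoOffsetAmp,endoOffsetPhase optional angular modulation of the
#'   offset: offset(theta) = endoOffset * (1 + endoOffsetAmp *
#'   cos(theta - endoOffsetPhase)).
#' @param poreDensity target number of pores per mm2 of cortical compartment.
#' @param poreMix pore-diameter mixture (mm): named list with `wLarge`
#'   (mixing weight of the large component, in \[0,1\]), `meanlogSmall`,
#'   `sdlogSmall`, `meanlogLarge`, `sdlogLarge`.
#' @param largePoreBias endosteal bias in \[0,1\] for pores above
#'   `biasThresholdUm`: 0 = uniform across the cortex, 1 = concentrated at
#'   the endosteal side (rejection sampling on the radial position).
#' @param biasThresholdUm diameter (um) above which the endosteal bias
#'   applies.
#' @param minPoreDiam,maxPoreDiam clamp for sampled diameters, mm.
#' @param pixelSize raster pixel size, mm (isotropic).
#' @param noiseSD additive Gaussian image noise, as a fraction of the
#'   tissue-background level separation.
#' @param levels intensity levels `c(background=, tissue=)` on a 0-1 scale.
#' @param marginMm background margin around the periosteal contour, mm.
#' @param nVertices number of vertices of the emitted contour polygons.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return a validated list of class `"SectionSpec"`.
#' @export
sectionSpec <- function(shape = c("ellipse", "rounded-triangle"),
                        semiAxes = c(2.1, 1.8),
                        triAmp = 0.10,
                        endoOffset = 0.65,
                        endoOffsetAmp = 0,
                        endoOffsetPhase = 0,
                        poreDensity = 17,
                        poreMix = list(wLarge = 0.06,
                                       meanlogSmall = log(0.042),
                                       sdlogSmall = 0.55,
                                       meanlogLarge = log(0.150),
                                       sdlogLarge = 0.45),
                        largePoreBias = 0.6,
                        biasThresholdUm = 100,
                        minPoreDiam = 0.015,
                        maxPoreDiam = 0.40,
                        pixelSize = 0.012,
                        noiseSD = 0.1,
                        levels = c(background = 0.25, tissue = 0.75),
                        marginMm = 0.7,
                        nVertices = 1440,
                        seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(length(semiAxes) == 2, all(semiAxes > 0))
  if (!(endoOffset > 0 && all(semiAxes > endoOffset)))
    stop("semi-axes must exceed the endosteal offset, which must be positive")
  w <- poreMix$wLarge
  if (is.null(w) || w < 0 || w > 1)
    stop("poreMix$wLarge must lie in [0, 1]")
  if (pixelSize <= 0) stop("pixelSize must be positive")
  if (poreDensity < 0) stop("poreDensity must be non-negative")
  if (noiseSD < 0) stop("noiseSD must be non-negative")
  if (largePoreBias < 0 || largePoreBias > 1)
    stop("largePoreBias must lie in [0, 1]")
  structure(list(
    shape = shape, semiAxes = semiAxes, triAmp = triAmp,
    endoOffset = endoOffset, endoOffsetAmp = endoOffsetAmp,
    endoOffsetPhase = endoOffsetPhase,
    poreDensity = poreDensity, poreMix = poreMix,
    largePoreBias = largePoreBias, biasThresholdUm = biasThresholdUm,
    minPoreDiam = minPoreDiam, maxPoreDiam = maxPoreDiam,
    pixelSize = pixelSize, noiseSD = noiseSD, levels = levels,
    marginMm = marginMm, nVertices = nVertices, seed = as.integer(seed)),
    class = "SectionSpec")
}

# periosteal radius (mm) at angle theta for a spec
periRadius <- function(spec, theta) {
  a <- spec$semiAxes[1]; b <- spec$semiAxes[2]
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (spec$shape == "rounded-triangle")
    r <- r * (1 + spec$triAmp * cos(3 * theta))
  r
}

endoRadius <- function(spec, theta) {
  off <- spec$endoOffset *
    (1 + spec$endoOffsetAmp * cos(theta - spec$endoOffsetPhase))
  periRadius(spec, theta) - off
}

#' Rasterize a star-shaped polygon given about a center
#'
#' Interprets the polygon as samples of a radius function r(theta) about
#' `center` and marks every pixel whose center radius is at most the
#' linearly interpolated boundary radius at its angle. This is the
#' rasterization rule used by the section generator, so ground-truth
#' polygons rasterize to exactly the emitted masks.
#'
#' @param poly n x 2 polygon, 0-based pixel coordinates, star-shaped about
#'   `center`.
#' @param dim raster dimension `c(nx, ny)`.
#' @param center `c(x, y)` in 0-based pixel coordinates.
#' @param strict mark pixels with radius strictly below the boundary
#'   (used for open interiors).
#' @return logical matrix.
#' @export
rasterizeStarPolygon <- function(poly, dim, center, strict = FALSE) {
  th <- atan2(poly[, 2] - center[2], poly[, 1] - center[1])
  rr <- sqrt((poly[, 1] - center[1])^2 + (poly[, 2] - center[2])^2)
  o <- order(th)
  th <- th[o]; rr <- rr[o]
  # wrap for circular interpolation
  th2 <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  rr2 <- c(rr[length(rr)], rr, rr[1])
  px <- (seq_len(dim[1]) - 1) - center[1]
  py <- (seq_len(dim[2]) - 1) - center[2]
  X <- matrix(px, dim[1], dim[2])
  Y <- matrix(py, dim[1], dim[2], byrow = TRUE)
  ang <- atan2(Y, X)
  rad <- sqrt(X * X + Y * Y)
  bnd <- stats::approx(th2, rr2, xout = as.vector(ang), rule = 2)$y
  if (strict) matrix(rad < matrix(bnd, dim[1], dim[2]), dim[1], dim[2])
  else        matrix(rad <= matrix(bnd, dim[1], dim[2]), dim[1], dim[2])
}

# sample pore diameters (mm) from the mixture
samplePoreDiameters <- function(n, mix, lo, hi) {
  if (n == 0L) return(numeric(0))
  large <- stats::runif(n) < mix$wLarge
  d <- numeric(n)
  d[!large] <- stats::rlnorm(sum(!large), mix$meanlogSmall, mix$sdlogSmall)
  d[large] <- stats::rlnorm(sum(large), mix$meanlogLarge, mix$sdlogLarge)
  pmin(pmax(d, lo), hi)
}

#' Generate one synthetic cross-section with exact ground truth
#'
#' Rasterizes the cortical shell described by `spec` at `spec$pixelSize`,
#' plants a non-overlapping pore population (minimum one-pixel separation,
#' every pore fully inside the cortical compartment), and emits the noisy
#' two-level intensity image together with the ground-truth masks, contours
#' and morphometry.
#'
#' @param spec a [sectionSpec()].
#' @return list with elements `image` ([CalibratedImage-class]), `masks`
#'   ([SectionMasks-class]) and `truth` ([GroundTruth-class]).
#' @examples
#' sec <- generateCrossSection(sectionSpec(poreDensity = 5, pixelSize = 0.02))
#' sec$truth
#' @export
generateCrossSection <- function(spec) {
  stopifnot(inherits(spec, "SectionSpec"))
  withr::with_seed(spec$seed, generateCrossSectionImpl(spec))
}

generateCrossSectionImpl <- function(spec) {
  px <- spec$pixelSize
  thv <- seq(0, 2 * pi, length.out = spec$nVertices + 1L)[-(spec$nVertices + 1L)]
  rPeri <- periRadius(spec, thv)
  rEndo <- endoRadius(spec, thv)
  if (any(rEndo <= 0))
    stop("endosteal offset profile leaves no marrow cavity (radius <= 0)")

  ext <- max(rPeri) + spec$marginMm
  n <- 2L * ceiling(ext / px) + 1L            # odd => integer center pixel
  c0 <- (n - 1) / 2                           # center, 0-based px
  periPolyPx <- cbind(c0 + rPeri * cos(thv) / px, c0 + rPeri * sin(thv) / px)
  endoPolyPx <- cbind(c0 + rEndo * cos(thv) / px, c0 + rEndo * sin(thv) / px)

  total <- rasterizeStarPolygon(periPolyPx, c(n, n), c(c0, c0))
  endoInt <- rasterizeStarPolygon(endoPolyPx, c(n, n), c(c0, c0), strict = TRUE)
  cortical <- total & !endoInt

  ctAreaMm2 <- sum(cortical) * px^2
  nPores <- round(spec$poreDensity * ctAreaMm2)
  diams <- sort(samplePoreDiameters(nPores, spec$poreMix,
                                    spec$minPoreDiam, spec$maxPoreDiam),
                decreasing = TRUE)
  sep <- 1.5 * px                             # > sqrt(2) px: labels stay apart
  placed <- placePores(diams, spec, thv, rPeri, rEndo, sep)
  # shift pore centers from section-centered to image-origin coordinates
  placed$cx_mm <- placed$cx_mm + c0 * px
  placed$cy_mm <- placed$cy_mm + c0 * px

  poreLabels <- matrix(0L, n, n)
  if (nrow(placed)) {
    for (k in seq_len(nrow(placed))) {
      r <- placed$diam_mm[k] / 2
      cxp <- placed$cx_mm[k] / px
      cyp <- placed$cy_mm[k] / px
      rp <- r / px
      xi <- max(0, floor(cxp - rp - 1)):min(n - 1, ceiling(cxp + rp + 1))
      yi <- max(0, floor(cyp - rp - 1)):min(n - 1, ceiling(cyp + rp + 1))
      dx <- outer(xi - cxp, rep(1, length(yi)))
      dy <- outer(rep(1, length(xi)), yi - cyp)
      hit <- (dx * dx + dy * dy) <= rp * rp
      sub <- poreLabels[xi + 1L, yi + 1L]
      sub[hit] <- k
      poreLabels[xi + 1L, yi + 1L] <- sub
    }
  }
  poreMask <- poreLabels > 0L
  tissue <- cortical & !poreMask

  lv <- spec$levels
  sdAbs <- spec$noiseSD * (lv[["tissue"]] - lv[["background"]])
  img <- matrix(lv[["background"]], n, n)
  img[tissue] <- lv[["tissue"]]
  if (sdAbs > 0) img <- img + matrix(stats::rnorm(n * n, 0, sdAbs), n, n)

  # ground-truth morphometry
  thrUm <- c(60, 100, 160, 300, 385)
  dUm <- placed$diam_mm * 1000
  areas <- pi / 4 * placed$diam_mm^2
  if (nrow(placed)) {
    relPoN <- vapply(thrUm, function(t) 100 * mean(dUm > t), numeric(1))
    relCtPo <- vapply(thrUm, function(t) 100 * sum(areas[dUm > t]) / sum(areas),
                      numeric(1))
  } else relPoN <- relCtPo <- rep(NA_real_, length(thrUm))
  names(relPoN) <- names(relCtPo) <- as.character(thrUm)

  periPolyMm <- periPolyPx * px
  endoPolyMm <- endoPolyPx * px
  ctTh <- truthCorticalThickness(periPolyMm, endoPolyMm, px)

  truth <- new("GroundTruth",
    periosteal = periPolyMm, endosteal = endoPolyMm,
    pores = placed,
    ctPo = if (sum(cortical)) 100 * sum(poreMask) / sum(cortical) else NA_real_,
    poD = if (ctAreaMm2 > 0) nrow(placed) / ctAreaMm2 else NA_real_,
    ctTh = ctTh, relPoN = relPoN, relCtPo = relCtPo)

  image <- CalibratedImage(img, px, "acoustic-impedance",
                           calibration = c(slope = 10, intercept = 0))
  masks <- SectionMasks(tissue = tissue, total = total, cortical = cortical,
                        poreLabels = poreLabels,
                        periostealContour = periPolyPx,
                        endostealContour = endoPolyPx,
                        pixelSize = px)
  list(image = image, masks = masks, truth = truth)
}

# modal (1-px bin) minimum distance between the true contours
truthCorticalThickness <- function(periMm, endoMm, px) {
  d <- minDistToSet(periMm, endoMm)
  modalValue(d, px)
}

# midpoint of the most populated histogram bin; ties towards the smaller bin
modalValue <- function(d, binWidth) {
  if (!length(d)) return(NA_real_)
  idx <- floor(d / binWidth)
  tab <- table(idx)
  win <- as.numeric(names(tab)[which.max(tab)])   # which.max: first = smallest
  (win + 0.5) * binWidth
}

# rejection-sampled pore placement; errors when packing is infeasible
placePores <- function(diams, spec, thv, rPeri, rEndo, sep) {
  nReq <- length(diams)
  out <- data.frame(cx_mm = numeric(0), cy_mm = numeric(0),
                    diam_mm = numeric(0))
  if (!nReq) return(out)
  periXY <- cbind(rPeri * cos(thv), rPeri * sin(thv))
  endoXY <- cbind(rEndo * cos(thv), rEndo * sin(thv))
  cx <- cy <- rr <- numeric(nReq)
  placedN <- 0L
  maxTries <- 2000L
  for (k in seq_len(nReq)) {
    r <- diams[k] / 2
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      th <- stats::runif(1, 0, 2 * pi)
      # thv is a uniform angular grid: nearest-vertex lookup replaces approx
      iv <- (round(th / (2 * pi) * length(thv)) %% length(thv)) + 1L
      ri <- rEndo[iv] + r + sep
      ro <- rPeri[iv] - r - sep
      if (ro <= ri) next
      u <- stats::runif(1)
      rad <- ri + u * (ro - ri)
      if (diams[k] * 1000 > spec$biasThresholdUm && spec$largePoreBias > 0) {
        tt <- (rad - ri) / (ro - ri)     # 0 at endosteal side
        if (stats::runif(1) > (1 - spec$largePoreBias) +
              spec$largePoreBias * (1 - tt)) next
      }
      # snap centers to the pixel lattice: the planted diameter is then
      # uniquely recoverable from the rasterized disk (within one pixel)
      x <- round(rad * cos(th) / spec$pixelSize) * spec$pixelSize
      y <- round(rad * sin(th) / spec$pixelSize) * spec$pixelSize
      # exact clearance from both contours (polygon vertices are denser
      # than one pixel)
      if (min((periXY[, 1] - x)^2 + (periXY[, 2] - y)^2) < (r + sep)^2) next
      if (min((endoXY[, 1] - x)^2 + (endoXY[, 2] - y)^2) < (r + sep)^2) next
      if (placedN > 0L) {
        dd <- sqrt((cx[seq_len(placedN)] - x)^2 + (cy[seq_len(placedN)] - y)^2)
        if (any(dd < rr[seq_len(placedN)] + r + sep)) next
      }
      placedN <- placedN + 1L
      cx[placedN] <- x; cy[placedN] <- y; rr[placedN] <- r
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf(
        "infeasible pore packing: placed %d of %d requested pores", placedN,
        nReq))
  }
  # shift to image coordinates relative to the section center at the origin
  data.frame(cx_mm = cx[seq_len(placedN)], cy_mm = cy[seq_len(placedN)],
             diam_mm = 2 * rr[seq_len(placedN)])
}

#' Specification of a synthetic cohort
#'
#' Defines a cohort in which a planted linear outcome depends on an
#' aBMD-like latent variable and on the true share of porosity carried by
#' pores above 100 um (relCt.Po_100um), on standardized scales:
#' y = betaLatent * z(latent) + betaLargePore * z(relCt.Po_100um) + eps.
#' When `noiseSD` is `NULL` it is set to sqrt(1 - betaLatent^2 -
#' betaLargePore^2) so the standardized coefficients of the planted model
#' are exactly the supplied betas.
#'
#' @param n number of subjects (>= 3).
#' @param betaLatent,betaLargePore standardized effect sizes for the
#'   stance-load outcomes.
#' @param betaLatentFall,betaLargePoreFall effect sizes for the fall-load
#'   outcomes.
#' @param noiseSD residual SD on the standardized outcome scale, or `NULL`
#'   for unit outcome variance.
#' @param sectionRanges per-subject uniform sampling ranges for the section
#'   generator: named list with `semiAxisA`, `axisRatio`, `endoOffset`,
#'   `poreDensity`, `wLarge` (each `c(lo, hi)`).
#' @param pixelSize raster pixel size of the per-subject sections, mm.
#' @param noiseSDImage image noise of the per-subject sections.
#' @param seed integer RNG seed.
#' @return a validated list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(n,
                       betaLatent = 0.72, betaLargePore = -0.60,
                       betaLatentFall = 0.78, betaLargePoreFall = -0.35,
                       noiseSD = NULL,
                       sectionRanges = list(
                         semiAxisA = c(1.3, 1.7),
                         axisRatio = c(0.85, 1.0),
                         endoOffset = c(0.45, 0.8),
                         poreDensity = c(15, 19),
                         wLarge = c(0.02, 0.12)),
                       pixelSize = 0.02,
                       noiseSDImage = 0.1,
                       seed = 1L) {
  if (n < 3) stop("a cohort needs at least 3 subjects")
  for (bl in list(c(betaLatent, betaLargePore),
                  c(betaLatentFall, betaLargePoreFall)))
    if (sum(bl^2) > 1 && is.null(noiseSD))
      stop("betaLatent^2 + betaLargePore^2 must not exceed 1 ",
           "when noiseSD is derived")
  if (!is.null(noiseSD) && noiseSD < 0) stop("noiseSD must be non-negative")
  structure(list(
    n = as.integer(n), betaLatent = betaLatent, betaLargePore = betaLargePore,
    betaLatentFall = betaLatentFall, betaLargePoreFall = betaLargePoreFall,
    noiseSD = noiseSD, sectionRanges = sectionRanges, pixelSize = pixelSize,
    noiseSDImage = noiseSDImage, seed = as.integer(seed)),
    class = "CohortSpec")
}

#' Generate a synthetic cohort with a planted outcome model
#'
#' Generates one cross-section per subject, measures its morphometry with
#' the morphometry stage (the measured columns enter the cohort table; the
#' planted outcome uses the ground-truth large-pore share), and plants
#' linear outcomes on aBMD-like and large-pore standardized predictors.
#' Outcome columns are rescaled to realistic units (aBMD_neck in mgHA/cm2,
#' stiffness in N/mm, ultimate force in N).
#'
#' @param cspec a [cohortSpec()].
#' @return list with `cohort` (data.frame, one row per subject: morphometry
#'   columns per [morphometryColumns()], `aBMD_neck`, `hvFE_S_stance`,
#'   `hvFE_Fu_stance`, `hvFE_S_fall`, `hvFE_Fu_fall`) and `truth` (list of
#'   [GroundTruth-class]).
#' @export
generateCohort <- function(cspec) {
  stopifnot(inherits(cspec, "CohortSpec"))
  withr::with_seed(cspec$seed, generateCohortImpl(cspec))
}

generateCohortImpl <- function(cspec) {
  n <- cspec$n
  rg <- cspec$sectionRanges
  secSeeds <- sample.int(.Machine$integer.max - 1L, n)
  morphRows <- vector("list", n)
  truths <- vector("list", n)
  trueLarge <- numeric(n)
  for (i in seq_len(n)) {
    a <- stats::runif(1, rg$semiAxisA[1], rg$semiAxisA[2])
    b <- a * stats::runif(1, rg$axisRatio[1], rg$axisRatio[2])
    off <- stats::runif(1, rg$endoOffset[1], rg$endoOffset[2])
    spec <- sectionSpec(
      semiAxes = c(a, b),
      endoOffset = off,
      # a pore cannot exceed the cortex width it sits in
      maxPoreDiam = min(0.4, 0.55 * off),
      poreDensity = stats::runif(1, rg$poreDensity[1], rg$poreDensity[2]),
      poreMix = utils::modifyList(
        sectionSpec()$poreMix,
        list(wLarge = stats::runif(1, rg$wLarge[1], rg$wLarge[2]))),
      pixelSize = cspec$pixelSize,
      noiseSD = cspec$noiseSDImage,
      marginMm = 0.2, nVertices = 720,
      seed = secSeeds[i])
    sec <- generateCrossSection(spec)   # per-subject seed, reproducible alone
    truths[[i]] <- sec$truth
    tl <- sec$truth@relCtPo[["100"]]
    trueLarge[i] <- if (is.na(tl)) 0 else tl
    ms <- computeMorphometry(sec$masks, img = sec$image)
    morphRows[[i]] <- as.data.frame(ms)
  }
  morph <- do.call(rbind, morphRows)

  latent <- stats::rnorm(n)
  zL <- as.numeric(scale(latent))
  zP <- as.numeric(scale(trueLarge))
  mkOutcome <- function(b1, b2) {
    s <- cspec$noiseSD
    if (is.null(s)) s <- sqrt(max(0, 1 - b1^2 - b2^2))
    b1 * zL + b2 * zP + stats::rnorm(n, 0, s)
  }
  cohort <- cbind(
    data.frame(subject = seq_len(n)),
    morph,
    data.frame(
      aBMD_neck = 529 + 96 * zL,
      hvFE_S_stance = 3210 + 1343 *
        mkOutcome(cspec$betaLatent, cspec$betaLargePore),
      hvFE_Fu_stance = 2605 + 903 *
        mkOutcome(cspec$betaLatent, cspec$betaLargePore),
      hvFE_S_fall = 1314 + 376 *
        mkOutcome(cspec$betaLatentFall, cspec$betaLargePoreFall),
      hvFE_Fu_fall = 1456 + 460 *
        mkOutcome(cspec$betaLatentFall, cspec$betaLargePoreFall)))
  rownames(cohort) <- NULL
  list(cohort = cohort, truth = truths)
}
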