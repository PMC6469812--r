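# Morphometry stage: per-pore largest-inscribed-circle diameters, modal
# cortical thickness, areal quantities and every threshold-stratified
# large-pore metric, from a SectionMasks object.

#' Canonical morphometry column names
#'
#' Order and names of the parameter vector emitted per section/ROI.
#'
#' @param thresholdsUm pore-diameter thresholds in um.
#' @return character vector of column names.
#' @export
morphometryColumns <- function(thresholdsUm = c(60, 100, 160, 300, 385)) {
  t <- thresholdsUm
  c("Tt.Ar", "Ct.Ar", "T.Ar", "Ct.Wba", "Ct.Th", "Ct.Po", "Po.D",
    paste0("Po.D_", t), paste0("relPo.n_", t),
    paste0("Ct.Po_", t), paste0("relCt.Po_", t),
    "Po.Dm_mean", "Po.Dm_SD",
    paste0("Po.Dm_q", seq(10, 90, 10)),
    "vcal_mean", "vcal_SD")
}

popSD <- function(x) {
  if (length(x) < 1L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Per-pore table with largest-inscribed-circle diameters
#'
#' For each labeled pore, the diameter of the largest inscribed circle is
#' computed from the Euclidean distance transform as
#' `Po.Dm = 2 * (max distance-to-nearest-non-pore-pixel-center - 0.5) * pixelSize`,
#' so a single-pixel pore has a diameter of exactly one pixel and digital
#' disks are measured without bias.
#'
#' @param poreLabels integer label map (0 = non-pore, 8-connected labels).
#' @param pixelSize mm per pixel.
#' @param endostealContour optional n x 2 polygon (0-based px) used to fill
#'   the centroid distance-to-endosteal column.
#' @param roiMask optional logical mask setting the `in_roi` flag from the
#'   pore centroid.
#' @return data.frame (one row per pore): `label`, `area_mm2`, `podm_mm`,
#'   `cx_px`, `cy_px`, `dist_endo_mm`, `in_roi`. Empty when the label map
#'   has no pores.
#' @export
poreDiameters <- function(poreLabels, pixelSize,
                          endostealContour = NULL, roiMask = NULL) {
  lab <- poreLabels
  ids <- sort(unique(lab[lab > 0L]))
  empty <- data.frame(label = integer(0), area_mm2 = numeric(0),
                      podm_mm = numeric(0), cx_px = numeric(0),
                      cy_px = numeric(0), dist_endo_mm = numeric(0),
                      in_roi = logical(0))
  if (!length(ids)) return(empty)
  d <- EBImage::distmap(matrix(as.numeric(lab > 0L), nrow(lab), ncol(lab)))
  idx <- which(lab > 0L)
  labv <- lab[idx]
  dv <- as.numeric(d)[idx]
  xs <- (idx - 1L) %% nrow(lab)
  ys <- (idx - 1L) %/% nrow(lab)
  maxd <- tapply(dv, labv, max)
  npx <- tapply(dv, labv, length)
  cx <- tapply(xs, labv, mean)
  cy <- tapply(ys, labv, mean)
  out <- data.frame(
    label = as.integer(names(maxd)),
    area_mm2 = as.numeric(npx) * pixelSize^2,
    podm_mm = 2 * (as.numeric(maxd) - 0.5) * pixelSize,
    cx_px = as.numeric(cx), cy_px = as.numeric(cy))
  out <- out[order(out$label), , drop = FALSE]
  out$dist_endo_mm <- if (!is.null(endostealContour))
    minDistToSet(cbind(out$cx_px, out$cy_px), endostealContour) * pixelSize
  else NA_real_
  out$in_roi <- if (!is.null(roiMask))
    roiMask[cbind(round(out$cx_px) + 1L, round(out$cy_px) + 1L)]
  else TRUE
  rownames(out) <- NULL
  out
}

#' Modal cortical thickness
#'
#' For every vertex of the periosteal boundary, the minimum Euclidean
#' distance to the endosteal contour is computed; the thickness is the
#' midpoint of the most populated histogram bin of these minimum distances
#' (the most frequent minimum peri-to-endosteal distance). Bin ties break
#' towards the smaller distance (conservative thickness).
#'
#' @param periostealContour,endostealContour closed polygons, n x 2
#'   matrices of 0-based pixel coordinates with at least 3 vertices.
#' @param pixelSize mm per pixel.
#' @param binWidthPx histogram bin width in pixels (default 1).
#' @return Ct.Th in mm.
#' @export
corticalThickness <- function(periostealContour, endostealContour, pixelSize,
                              binWidthPx = 1) {
  for (ct in list(periostealContour, endostealContour))
    if (!is.matrix(ct) || ncol(ct) != 2 || nrow(ct) < 3)
      stop("degenerate contour: need an n x 2 polygon with n >= 3")
  if (binWidthPx <= 0) stop("binWidthPx must be positive")
  d <- minDistToSet(periostealContour, endostealContour)
  modalValue(d, binWidthPx) * pixelSize
}

#' Areal metrics of a section
#'
#' Pixel-count areas: total cross-section area (Tt.Ar), cortical
#' compartment area (Ct.Ar, pores included), bone tissue area inside the
#' periosteal boundary (T.Ar), and the cortical tissue share of the total
#' area (Ct.Wba, pores excluded from the numerator).
#'
#' @param masks a [SectionMasks-class].
#' @param pixelSize mm per pixel (defaults to the mask's own).
#' @return named numeric: `Tt.Ar`, `Ct.Ar`, `T.Ar` (mm2), `Ct.Wba` (%).
#' @export
arealMetrics <- function(masks, pixelSize = NULL) {
  stopifnot(is(masks, "SectionMasks"))
  px <- if (is.null(pixelSize)) masks@pixelSize else pixelSize
  nTot <- sum(masks@total)
  if (nTot == 0L) stop("empty total mask: no cross-section")
  c(Tt.Ar = nTot * px^2,
    Ct.Ar = sum(masks@cortical) * px^2,
    T.Ar = sum(masks@tissue & masks@total) * px^2,
    Ct.Wba = 100 * sum(masks@tissue & masks@cortical) / nTot)
}

#' Threshold-stratified porosity metrics
#'
#' Cortical porosity Ct.Po = 100 x pore pixels / cortical pixels; pore
#' density Po.D = pore count per mm2 of cortical compartment; and for every
#' diameter threshold x (strict comparison, `Po.Dm > x`): the density
#' `Po.D_x`, prevalence `relPo.n_x` (% of pore count), porosity `Ct.Po_x`
#' (% of cortical area) and porosity share `relCt.Po_x` (% of Ct.Po)
#' carried by pores above x. Also the mean, population SD and deciles of
#' the Po.Dm distribution. With zero pores the ratio metrics are undefined
#' and reported as `NA` with a `"no-pores"` flag.
#'
#' @param pores a pore table from [poreDiameters()].
#' @param corticalPixels number of pixels of the cortical compartment, > 0.
#' @param pixelSize mm per pixel.
#' @param thresholdsUm diameter thresholds in um.
#' @return list with `values` (named numeric) and `flags` (character).
#' @export
porosityMetrics <- function(pores, corticalPixels, pixelSize,
                            thresholdsUm = c(60, 100, 160, 300, 385)) {
  if (corticalPixels <= 0) stop("corticalPixels must be positive")
  ctAreaMm2 <- corticalPixels * pixelSize^2
  poreAreaMm2 <- sum(pores$area_mm2)
  porePx <- poreAreaMm2 / pixelSize^2
  n <- nrow(pores)
  flags <- character(0)
  ctPo <- 100 * porePx / corticalPixels
  v <- c(Ct.Po = ctPo, Po.D = n / ctAreaMm2)
  dUm <- pores$podm_mm * 1000
  for (t in thresholdsUm) {
    sel <- dUm > t
    v[paste0("Po.D_", t)] <- sum(sel) / ctAreaMm2
    v[paste0("relPo.n_", t)] <- if (n > 0) 100 * sum(sel) / n else NA_real_
    ctPoT <- 100 * sum(pores$area_mm2[sel]) / ctAreaMm2
    v[paste0("Ct.Po_", t)] <- ctPoT
    v[paste0("relCt.Po_", t)] <- if (ctPo > 0) 100 * ctPoT / ctPo else NA_real_
  }
  if (n > 0) {
    q <- stats::quantile(pores$podm_mm, probs = seq(0.1, 0.9, 0.1),
                         names = FALSE, type = 7)
    v["Po.Dm_mean"] <- mean(pores$podm_mm)
    v["Po.Dm_SD"] <- popSD(pores$podm_mm)
    v[paste0("Po.Dm_q", seq(10, 90, 10))] <- q
  } else {
    flags <- c(flags, "no-pores")
    v[c("Po.Dm_mean", "Po.Dm_SD", paste0("Po.Dm_q", seq(10, 90, 10)))] <-
      NA_real_
  }
  # reorder to the canonical threshold-block layout
  t <- thresholdsUm
  ord <- c("Ct.Po", "Po.D", paste0("Po.D_", t), paste0("relPo.n_", t),
           paste0("Ct.Po_", t), paste0("relCt.Po_", t),
           "Po.Dm_mean", "Po.Dm_SD", paste0("Po.Dm_q", seq(10, 90, 10)))
  list(values = v[ord], flags = flags)
}

#' Calibrated intensity statistics within a mask
#'
#' Mean and population SD of the calibrated intensity (slope x intensity +
#' intercept) over the masked pixels — the density surrogate (vBMD_cort and
#' its SD for CT input; mean acoustic impedance for impedance maps).
#'
#' @param img a [CalibratedImage-class] with calibration present.
#' @param mask non-empty logical mask.
#' @return named numeric `c(mean=, SD=)` in physical units.
#' @export
calibratedIntensityStats <- function(img, mask) {
  stopifnot(is(img, "CalibratedImage"))
  if (is.null(img@calibration))
    stop("missing calibration: sidecar field 'calibration' (slope, intercept) required")
  m <- asLogicalMask(mask)
  if (!any(m)) stop("empty mask: calibrated statistics undefined")
  v <- img@calibration[["slope"]] * img@pixels[m] +
    img@calibration[["intercept"]]
  c(mean = mean(v), SD = popSD(v))
}

#' Full morphometry of one section or ROI
#'
#' Assembles the complete parameter set from a [SectionMasks-class]:
#' areal metrics, modal cortical thickness, per-pore diameters and all
#' threshold-stratified porosity metrics, plus calibrated intensity
#' statistics of the cortical tissue when an image is supplied.
#'
#' @param masks a [SectionMasks-class].
#' @param img optional [CalibratedImage-class] for the intensity columns
#'   (`NA` when absent or uncalibrated).
#' @param thresholdsUm pore-diameter thresholds, um.
#' @param binWidthPx histogram bin width for Ct.Th, px.
#' @return a [MorphometrySet-class].
#' @export
computeMorphometry <- function(masks, img = NULL,
                               thresholdsUm = c(60, 100, 160, 300, 385),
                               binWidthPx = 1) {
  stopifnot(is(masks, "SectionMasks"))
  px <- masks@pixelSize
  ar <- arealMetrics(masks)
  ctTh <- corticalThickness(masks@periostealContour, masks@endostealContour,
                            px, binWidthPx)
  pores <- poreDiameters(masks@poreLabels, px,
                         endostealContour = masks@endostealContour)
  po <- porosityMetrics(pores, sum(masks@cortical), px, thresholdsUm)
  vcal <- c(mean = NA_real_, SD = NA_real_)
  if (!is.null(img) && !is.null(img@calibration)) {
    ctTissue <- masks@tissue & masks@cortical
    if (any(ctTissue)) vcal <- calibratedIntensityStats(img, ctTissue)
  }
  vals <- c(ar["Tt.Ar"], ar["Ct.Ar"], ar["T.Ar"], ar["Ct.Wba"],
            Ct.Th = ctTh, po$values,
            vcal_mean = vcal[["mean"]], vcal_SD = vcal[["SD"]])
  vals <- vals[morphometryColumns(thresholdsUm)]
  names(vals) <- morphometryColumns(thresholdsUm)
  new("MorphometrySet", values = vals, thresholdsUm = thresholdsUm,
      flags = po$flags)
}
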