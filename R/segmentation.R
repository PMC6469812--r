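# Segmentation stage: calibrated image + manual endosteal boundary ->
# cleaned tissue/total/cortical masks, contours and labeled pore map.
# The pipeline order is fixed: smooth -> segment -> clean -> trace -> build.

#' Gaussian smoothing with a truncated kernel
#'
#' Applies a normalized, truncated Gaussian filter (default sigma 1.1 px,
#' radius 2 px, the pre-filter used for CT density stacks) with replicated
#' borders. Pixel size and calibration metadata are preserved.
#'
#' @param img a [CalibratedImage-class].
#' @param sigmaPx kernel standard deviation in pixels, > 0.
#' @param radiusPx truncation radius in pixels, > 0; the kernel spans
#'   `2*ceiling(radiusPx) + 1` pixels.
#' @return the smoothed [CalibratedImage-class].
#' @export
smoothImage <- function(img, sigmaPx = 1.1, radiusPx = 2.0) {
  stopifnot(is(img, "CalibratedImage"))
  if (!isTRUE(sigmaPx > 0)) stop("sigmaPx must be positive")
  if (!isTRUE(radiusPx > 0)) stop("radiusPx must be positive")
  r <- ceiling(radiusPx)
  off <- (-r):r
  k1 <- exp(-off^2 / (2 * sigmaPx^2))
  k <- outer(k1, k1)
  k[sqrt(outer(off^2, off^2, "+")) > radiusPx + 1e-9] <- 0  # circular truncation
  k <- k / sum(k)
  sm <- EBImage::filter2(img@pixels, k, boundary = "replicate")
  initialize(img, pixels = matrix(as.numeric(sm), nrow(img@pixels),
                                  ncol(img@pixels)))
}

#' Segment bone tissue from the background
#'
#' Global Otsu thresholding (between-class variance maximization on a
#' 256-bin histogram) or adaptive local-mean thresholding (square window
#' mean minus an offset), as used for CT and acoustic impedance maps
#' respectively. The applied threshold is attached as a provenance
#' attribute.
#'
#' @param img a [CalibratedImage-class].
#' @param method `"otsu"` or `"adaptive"`.
#' @param windowPx side of the square local-mean window (adaptive), > 1;
#'   default 201 px (2.4 mm at 12 um).
#' @param offsetFrac offset subtracted from the local mean, as a fraction
#'   of the image intensity range (adaptive).
#' @return logical tissue mask with attributes `method`, `threshold` (the
#'   global threshold, Otsu) and `constantInput` (flag: Otsu on a constant
#'   image falls back to all-background with a warning).
#' @export
segmentTissue <- function(img, method = c("otsu", "adaptive"),
                          windowPx = 201L, offsetFrac = 0.1) {
  stopifnot(is(img, "CalibratedImage"))
  method <- match.arg(method)
  x <- img@pixels
  rng <- range(x)
  if (method == "otsu") {
    if (diff(rng) == 0) {
      warning("constant image: Otsu threshold undefined, returning all-background")
      mask <- matrix(FALSE, nrow(x), ncol(x))
      attr(mask, "method") <- "otsu"
      attr(mask, "threshold") <- NA_real_
      attr(mask, "constantInput") <- TRUE
      return(mask)
    }
    thr <- EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng)),
                         range = c(0, 1), levels = 256L)
    thr <- rng[1] + thr * diff(rng)
    mask <- x > thr
    attr(mask, "method") <- "otsu"
    attr(mask, "threshold") <- thr
    attr(mask, "constantInput") <- FALSE
    return(mask)
  }
  if (!isTRUE(windowPx > 1)) stop("windowPx must exceed 1 for adaptive thresholding")
  w <- as.integer(windowPx)
  if (w %% 2L == 0L) w <- w + 1L
  k <- matrix(1 / (w * w), w, w)
  localMean <- EBImage::filter2(x, k, boundary = "replicate")
  off <- offsetFrac * diff(rng)
  mask <- x > (localMean + off)
  attr(mask, "method") <- "adaptive"
  attr(mask, "window") <- w
  attr(mask, "offset") <- off
  attr(mask, "constantInput") <- FALSE
  mask
}

#' Clean a tissue mask
#'
#' Removes unconnected (8-connected) foreground objects with area strictly
#' below `minObjectArea` and fills all single-pixel pores (interior
#' 4-connected background components of exactly one pixel). Idempotent.
#'
#' @param mask logical tissue mask.
#' @param pixelSize mm per pixel.
#' @param minObjectArea minimum retained object area, mm2 (default
#'   0.144 mm2 = 1000 px at 12 um).
#' @return cleaned logical mask.
#' @export
cleanTissueMask <- function(mask, pixelSize, minObjectArea = 0.144) {
  if (minObjectArea < 0) stop("minObjectArea must be non-negative")
  m <- asLogicalMask(mask)
  if (minObjectArea > 0 && any(m)) {
    lab <- label8(m)
    sz <- tabulate(lab[lab > 0L])
    minPx <- minObjectArea / pixelSize^2
    drop <- which(sz < minPx)          # strict: area below the threshold
    if (length(drop)) m[lab %in% drop] <- FALSE
  }
  fillSinglePixelHoles(m)
}

#' Trace the periosteal contour
#'
#' Morphologically closes the tissue mask with a disk of radius
#' `closingRadius` (exact Euclidean disk via the distance transform), keeps
#' the largest connected object, fills its interior, and returns the filled
#' total-bone mask together with the outer boundary polygon.
#'
#' @param tissueMask logical mask of segmented (cleaned) bone tissue.
#' @param pixelSize mm per pixel.
#' @param closingRadius structuring-element radius, mm (default 0.48 mm =
#'   40 px at 12 um).
#' @return list with `contour` (n x 2 matrix, 0-based pixel coordinates of
#'   the outer boundary) and `totalMask` (logical).
#' @export
tracePeriosteal <- function(tissueMask, pixelSize, closingRadius = 0.48) {
  m <- asLogicalMask(tissueMask)
  if (!any(m)) stop("empty tissue mask: cannot trace a periosteal contour")
  rPx <- closingRadius / pixelSize
  # pad by the structuring element so the closing never sees the border
  pad <- ceiling(rPx) + 1L
  mp <- matrix(FALSE, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  mp[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  closed <- diskClose(mp, rPx)[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
  lab <- label8(closed)
  sz <- tabulate(lab[lab > 0L])
  keep <- which.max(sz)
  biggest <- lab == keep
  filled <- EBImage::fillHull(matrix(as.numeric(biggest), nrow(m), ncol(m))) > 0
  oc <- EBImage::ocontour(matrix(as.integer(filled), nrow(m), ncol(m)))[[1]]
  list(contour = oc, totalMask = filled)
}

# rasterize an endosteal input: polygon (n x 2, 0-based px) or mask
endoInterior <- function(endosteal, dm) {
  if (is.matrix(endosteal) && ncol(endosteal) == 2 && nrow(endosteal) >= 3 &&
      !is.logical(endosteal) && !identical(dim(endosteal), dm)) {
    rasterizePolygon(endosteal, dm)
  } else {
    asLogicalMask(endosteal, "endosteal mask")
  }
}

#' Build the cortical compartment and the pore map
#'
#' Subtracts the interior of the manually delineated endosteal boundary
#' from the total-bone mask to obtain the cortical compartment, then labels
#' the 8-connected components of `cortical & !tissue` as pores. Components
#' touching the marrow cavity (8-adjacent to the endosteal interior) are
#' excluded: in a 2D section they are indistinguishable from marrow
#' notches.
#'
#' @param totalMask logical total-bone mask (from [tracePeriosteal()]).
#' @param tissueMask logical cleaned tissue mask.
#' @param endosteal the endosteal boundary: an n x 2 polygon in 0-based
#'   pixel coordinates, or a logical mask of the marrow interior.
#' @param pixelSize mm per pixel.
#' @param periostealContour optional n x 2 polygon stored in the result
#'   (computed from `totalMask` when missing).
#' @return a [SectionMasks-class].
#' @export
buildCorticalMask <- function(totalMask, tissueMask, endosteal, pixelSize,
                              periostealContour = NULL) {
  total <- asLogicalMask(totalMask)
  tissue <- asLogicalMask(tissueMask)
  marrow <- endoInterior(endosteal, dim(total))
  if (any(marrow & !total))
    stop("contours crossing: endosteal interior extends outside the periosteal boundary")
  cortical <- total & !marrow
  cand <- cortical & !tissue
  lab <- label8(cand)
  if (max(lab) > 0L) {
    touching <- unique(lab[lab > 0L & diskDilate(marrow, 1.5)])
    if (length(touching)) {
      # endosteal-adjacent components are marrow, not pores
      cortical[lab %in% touching] <- FALSE
      lab[lab %in% touching] <- 0L
      u <- sort(unique(lab[lab > 0L]))
      lab[lab > 0L] <- match(lab[lab > 0L], u)
    }
  }
  if (is.null(periostealContour)) {
    periostealContour <- EBImage::ocontour(
      matrix(as.integer(total), nrow(total), ncol(total)))[[1]]
  }
  if (is.matrix(endosteal) && ncol(endosteal) == 2 && !is.logical(endosteal) &&
      !identical(dim(endosteal), dim(total))) {
    endoPoly <- endosteal
  } else {
    endoPoly <- EBImage::ocontour(
      matrix(as.integer(marrow), nrow(total), ncol(total)))[[1]]
  }
  SectionMasks(tissue = tissue & total, total = total, cortical = cortical,
               poreLabels = lab,
               periostealContour = periostealContour,
               endostealContour = endoPoly,
               pixelSize = pixelSize)
}

#' Restrict masks to an angular region of interest
#'
#' Restricts the cortical compartment and the pore map to an angular sector
#' about the centroid of the total-bone mask — the ultrasound-accessible
#' anteromedial window. A pore is kept if and only if its centroid lies
#' inside the sector; kept pores contribute all their pixels.
#'
#' @param masks a [SectionMasks-class].
#' @param sectorCenterDeg sector center direction in degrees (atan2
#'   convention: 0 = +x axis, counter-clockwise).
#' @param sectorWidthDeg sector width in degrees, in (0, 360].
#' @return a [SectionMasks-class] with restricted `cortical` and
#'   `poreLabels` (pore labels renumbered).
#' @export
extractRoiUs <- function(masks, sectorCenterDeg, sectorWidthDeg = 60) {
  stopifnot(is(masks, "SectionMasks"))
  if (!(sectorWidthDeg > 0 && sectorWidthDeg <= 360))
    stop("sectorWidthDeg must lie in (0, 360]")
  total <- masks@total
  ctr <- colMeans(whichXY(total))
  cort <- masks@cortical
  xy <- whichXY(cort | (masks@poreLabels > 0L))
  ang <- atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1]) * 180 / pi
  keepPix <- inSector(ang, sectorCenterDeg, sectorWidthDeg)
  sectorMask <- matrix(FALSE, nrow(total), ncol(total))
  sectorMask[xy[keepPix, , drop = FALSE] + 1L] <- TRUE
  lab <- masks@poreLabels
  newLab <- matrix(0L, nrow(lab), ncol(lab))
  kept <- 0L
  for (k in sort(unique(lab[lab > 0L]))) {
    pix <- whichXY(lab == k)
    cen <- colMeans(pix)
    a <- atan2(cen[2] - ctr[2], cen[1] - ctr[1]) * 180 / pi
    if (inSector(a, sectorCenterDeg, sectorWidthDeg)) {
      kept <- kept + 1L
      newLab[lab == k] <- kept
    }
  }
  # non-pore cortical pixels inside the sector, plus all pixels of kept
  # pores (pore pixels = cortical & !tissue stays exact)
  newCort <- (cort & sectorMask & !(lab > 0L)) | newLab > 0L
  if (!any(newCort)) stop("ROI sector contains no cortical pixels")
  initialize(masks, cortical = newCort, poreLabels = newLab)
}
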