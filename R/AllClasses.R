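#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Calibrated 2D cross-section image
#'
#' A grayscale raster with a physical, isotropic pixel size and an optional
#' linear calibration to physical units (MRayl for acoustic impedance maps,
#' mgHA/cm3 for density slices). This is the raw input of the morphometry
#' pipeline.
#'
#' @slot pixels numeric matrix of intensities; the first dimension is the
#'   x (horizontal) axis, 0-based pixel centers at integer coordinates.
#' @slot pixelSize positive scalar, mm per pixel (isotropic).
#' @slot modality character tag, `"acoustic-impedance"` or `"density"`.
#' @slot calibration named numeric `c(slope=, intercept=)` mapping stored
#'   intensities to physical units, or `NULL` when uncalibrated.
#'
#' @seealso [CalibratedImage()] for the constructor,
#'   [readCalibratedImage()] / [writeCalibratedImage()] for TIFF+YAML I/O.
#' @export
setClass("CalibratedImage",
  representation(
    pixels = "matrix",
    pixelSize = "numeric",
    modality = "character",
    calibration = "numericOrNULL"
  ),
  prototype(
    pixelSize = 0.012,
    modality = "acoustic-impedance",
    calibration = NULL
  )
)

setValidity("CalibratedImage", function(object) {
  msg <- character()
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar (mm)")
  if (nrow(object@pixels) < 2L || ncol(object@pixels) < 2L)
    msg <- c(msg, "pixel grid must be at least 2 x 2")
  if (!is.null(object@calibration)) {
    if (!all(c("slope", "intercept") %in% names(object@calibration)))
      msg <- c(msg, "calibration must be named c(slope=, intercept=)")
    else if (object@calibration[["slope"]] == 0)
      msg <- c(msg, "calibration slope must be non-zero")
  }
  if (length(msg)) msg else TRUE
})

#' @param pixels,pixelSize,modality,calibration see the corresponding slots.
#' @rdname CalibratedImage-class
#' @export
CalibratedImage <- function(pixels, pixelSize,
                            modality = c("acoustic-impedance", "density"),
                            calibration = NULL) {
  modality <- match.arg(modality)
  new("CalibratedImage", pixels = pixels, pixelSize = pixelSize,
      modality = modality, calibration = calibration)
}

#' Binary masks and contours of one cross-section
#'
#' Holds the tissue, total (whole bone including marrow and pores) and
#' cortical compartment masks of a section, the periosteal and endosteal
#' boundary polygons, and the labeled pore map. Pore pixels are exactly
#' `cortical & !tissue` after exclusion of components touching the marrow,
#' and each pore label is one 8-connected component.
#'
#' @slot tissue,total,cortical logical matrices of identical dimension.
#' @slot poreLabels integer matrix, 0 = non-pore, k = pixels of pore k.
#' @slot periostealContour,endostealContour closed polygons, n x 2 matrices
#'   of 0-based pixel coordinates (x, y).
#' @slot pixelSize mm per pixel.
#' @export
setClass("SectionMasks",
  representation(
    tissue = "matrix",
    total = "matrix",
    cortical = "matrix",
    poreLabels = "matrix",
    periostealContour = "matrix",
    endostealContour = "matrix",
    pixelSize = "numeric"
  )
)

setValidity("SectionMasks", function(object) {
  msg <- character()
  d <- dim(object@tissue)
  if (!identical(d, dim(object@total)) || !identical(d, dim(object@cortical)) ||
      !identical(d, dim(object@poreLabels)))
    msg <- c(msg, "all masks must share one dimension")
  if (any(object@cortical & !object@total))
    msg <- c(msg, "cortical_mask must be contained in total_mask")
  if (any(object@poreLabels > 0 & !object@cortical))
    msg <- c(msg, "pore pixels must lie inside the cortical mask")
  if (any(object@poreLabels > 0 & object@tissue))
    msg <- c(msg, "pore pixels cannot be tissue")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar")
  for (nm in c("periostealContour", "endostealContour")) {
    ct <- slot(object, nm)
    if (ncol(ct) != 2L || nrow(ct) < 3L)
      msg <- c(msg, sprintf("%s must be an n x 2 polygon with n >= 3", nm))
  }
  if (length(msg)) msg else TRUE
})

SectionMasks <- function(tissue, total, cortical, poreLabels,
                         periostealContour, endostealContour, pixelSize) {
  new("SectionMasks",
      tissue = tissue, total = total, cortical = cortical,
      poreLabels = poreLabels,
      periostealContour = periostealContour,
      endostealContour = endostealContour,
      pixelSize = pixelSize)
}

#' Ground truth of a synthetic cross-section
#'
#' Exact description of a generated section: the planted pore list, the true
#' boundary polygons and the morphometric parameters they imply. Pore
#' centers and diameters are in mm relative to the image origin (0-based
#' pixel centers times pixel size).
#'
#' @slot periosteal,endosteal true boundary polygons, n x 2 matrices in mm.
#' @slot pores data.frame with columns `cx_mm`, `cy_mm`, `diam_mm`.
#' @slot ctPo true cortical porosity, percent (rasterized pore pixels over
#'   rasterized cortical pixels).
#' @slot poD true pore density, number per mm2 of cortical compartment.
#' @slot ctTh true modal cortical thickness, mm.
#' @slot relPoN,relCtPo named numeric: true per-threshold prevalence of
#'   large pores (% of pore count) and share of porosity (% of pore area),
#'   thresholds in um as names. `NA` when no pores were planted.
#' @export
setClass("GroundTruth",
  representation(
    periosteal = "matrix",
    endosteal = "matrix",
    pores = "data.frame",
    ctPo = "numeric",
    poD = "numeric",
    ctTh = "numeric",
    relPoN = "numeric",
    relCtPo = "numeric"
  )
)

#' Morphometric parameter set of one section or ROI
#'
#' The full parameter vector measured on one cross-section (or an angular
#' ROI of it): areal quantities, modal cortical thickness, cortical porosity
#' and pore density, the pore-diameter distribution summaries, and every
#' threshold-stratified large-pore metric.
#'
#' @slot values named numeric vector; see [morphometryColumns()] for the
#'   canonical names and order.
#' @slot thresholdsUm pore-diameter thresholds used (um).
#' @slot flags character vector of quality flags (e.g. `"no-pores"` when
#'   ratio metrics are undefined and reported as `NA`).
#' @export
setClass("MorphometrySet",
  representation(
    values = "numeric",
    thresholdsUm = "numeric",
    flags = "character"
  )
)

setValidity("MorphometrySet", function(object) {
  v <- object@values
  pc <- grep("^(Ct\\.Wba|Ct\\.Po|relPo\\.n|relCt\\.Po)", names(v))
  bad <- v[pc][!is.na(v[pc])]
  if (length(bad) && (any(bad < -1e-9) || any(bad > 100 + 1e-9)))
    return("percentage metrics must lie in [0, 100]")
  TRUE
})
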