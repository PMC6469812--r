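#' Accessors for pipeline objects
#'
#' Small accessor layer over the S4 containers: physical pixel size,
#' intensity grid, calibration, the individual masks and contours, and the
#' measured parameter vector. Use these instead of `@` access.
#'
#' @param object a [CalibratedImage-class], [SectionMasks-class],
#'   [GroundTruth-class] or [MorphometrySet-class] object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))
#' @rdname accessors
#' @export
setGeneric("tissueMask", function(object) standardGeneric("tissueMask"))
#' @rdname accessors
#' @export
setGeneric("totalMask", function(object) standardGeneric("totalMask"))
#' @rdname accessors
#' @export
setGeneric("corticalMask", function(object) standardGeneric("corticalMask"))
#' @rdname accessors
#' @export
setGeneric("poreLabels", function(object) standardGeneric("poreLabels"))
#' @rdname accessors
#' @export
setGeneric("periostealContour",
           function(object) standardGeneric("periostealContour"))
#' @rdname accessors
#' @export
setGeneric("endostealContour",
           function(object) standardGeneric("endostealContour"))
#' @rdname accessors
#' @export
setGeneric("metricValues", function(object) standardGeneric("metricValues"))
#' @rdname accessors
#' @export
setGeneric("truePores", function(object) standardGeneric("truePores"))

#' @rdname accessors
setMethod("pixelSize", "CalibratedImage", function(object) object@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "SectionMasks", function(object) object@pixelSize)
#' @rdname accessors
setMethod("intensities", "CalibratedImage", function(object) object@pixels)
#' @rdname accessors
setMethod("modality", "CalibratedImage", function(object) object@modality)
#' @rdname accessors
setMethod("calibration", "CalibratedImage", function(object) object@calibration)
#' @rdname accessors
setMethod("tissueMask", "SectionMasks", function(object) object@tissue)
#' @rdname accessors
setMethod("totalMask", "SectionMasks", function(object) object@total)
#' @rdname accessors
setMethod("corticalMask", "SectionMasks", function(object) object@cortical)
#' @rdname accessors
setMethod("poreLabels", "SectionMasks", function(object) object@poreLabels)
#' @rdname accessors
setMethod("periostealContour", "SectionMasks",
          function(object) object@periostealContour)
#' @rdname accessors
setMethod("endostealContour", "SectionMasks",
          function(object) object@endostealContour)
#' @rdname accessors
setMethod("metricValues", "MorphometrySet", function(object) object@values)
#' @rdname accessors
setMethod("truePores", "GroundTruth", function(object) object@pores)

#' @export
setMethod("show", "CalibratedImage", function(object) {
  cat(sprintf("CalibratedImage: %d x %d px, %.4g mm/px, %s%s\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelSize,
              object@modality,
              if (is.null(object@calibration)) " (uncalibrated)" else
                sprintf(" (slope %.4g, intercept %.4g)",
                        object@calibration[["slope"]],
                        object@calibration[["intercept"]])))
})

#' @export
setMethod("show", "SectionMasks", function(object) {
  np <- length(setdiff(unique(as.vector(object@poreLabels)), 0L))
  cat(sprintf(paste0(
    "SectionMasks: %d x %d px, %.4g mm/px\n",
    "  total %d px | cortical %d px | tissue %d px | %d pores\n"),
    nrow(object@tissue), ncol(object@tissue), object@pixelSize,
    sum(object@total), sum(object@cortical), sum(object@tissue), np))
})

#' @export
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(paste0(
    "GroundTruth: %d planted pores\n",
    "  Ct.Po %.3g %% | Po.D %.3g /mm2 | Ct.Th %.3g mm\n"),
    nrow(object@pores), object@ctPo, object@poD, object@ctTh))
})

#' @export
setMethod("show", "MorphometrySet", function(object) {
  v <- object@values
  cat("MorphometrySet\n")
  hdr <- c("Tt.Ar", "Ct.Ar", "Ct.Th", "Ct.Po", "Po.D", "Po.Dm_mean")
  for (h in intersect(hdr, names(v)))
    cat(sprintf("  %-12s %.4g\n", h, v[[h]]))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @param x a `MorphometrySet`.
#' @param row.names,optional,... passed through (unused).
#' @rdname MorphometrySet-class
#' @export
as.data.frame.MorphometrySet <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  as.data.frame(as.list(x@values), check.names = FALSE)
}

#' @export
setMethod("as.data.frame", "MorphometrySet", as.data.frame.MorphometrySet)
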