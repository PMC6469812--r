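# File formats: 16-bit grayscale TIFF + sidecar YAML for calibrated images,
# 8-bit PNG (0/255) for masks, CSV for contours and tables, JSON for
# provenance records.

#' Write and read a calibrated image (TIFF + sidecar YAML)
#'
#' Images are stored as 16-bit grayscale TIFF; intensities are scaled to
#' the stored 0-1 range and the original range is recorded in the sidecar
#' (`{pixel_size_mm, modality, intensity_range, calibration: {slope,
#' intercept}}`), so a write/read round trip reproduces the physical
#' values to 16-bit quantization.
#'
#' @param img a [CalibratedImage-class].
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
writeCalibratedImage <- function(img, path) {
  stopifnot(is(img, "CalibratedImage"))
  x <- img@pixels
  rng <- range(x)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  # tiff::writeTIFF expects [row, col] = [y, x]
  tiff::writeTIFF(t((x - rng[1]) / diff(rng)), path, bits.per.sample = 16L)
  side <- list(pixel_size_mm = img@pixelSize,
               modality = img@modality,
               intensity_range = as.numeric(rng))
  if (!is.null(img@calibration))
    side$calibration <- list(slope = unname(img@calibration[["slope"]]),
                             intercept = unname(img@calibration[["intercept"]]))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @param path for `readCalibratedImage`, the TIFF written by
#'   [writeCalibratedImage()] (or any grayscale TIFF/PNG with a sidecar).
#' @rdname writeCalibratedImage
#' @export
readCalibratedImage <- function(path) {
  sidePath <- paste0(path, ".yaml")
  if (!file.exists(sidePath))
    stop("missing sidecar YAML: ", sidePath)
  side <- yaml::read_yaml(sidePath)
  if (is.null(side$pixel_size_mm))
    stop("sidecar lacks required field 'pixel_size_mm'")
  raw <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  x <- t(raw)
  rng <- side$intensity_range
  if (!is.null(rng)) x <- x * (rng[2] - rng[1]) + rng[1]
  calib <- NULL
  if (!is.null(side$calibration))
    calib <- c(slope = side$calibration$slope,
               intercept = side$calibration$intercept)
  CalibratedImage(x, side$pixel_size_mm,
                  modality = if (is.null(side$modality))
                    "acoustic-impedance" else side$modality,
                  calibration = calib)
}

#' Mask and contour I/O
#'
#' Masks are 8-bit PNG with foreground 255; contours are two-column CSV
#' (`x_px,y_px`, 0-based pixel coordinates).
#'
#' @param mask logical matrix.
#' @param path file path.
#' @return the read object, or `path` invisibly for writers.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(t(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))),
                path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  t(raw) > 0.5
}

#' @param contour n x 2 matrix of 0-based pixel coordinates.
#' @rdname writeMaskPNG
#' @export
writeContourCSV <- function(contour, path) {
  utils::write.csv(data.frame(x_px = contour[, 1], y_px = contour[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readContourCSV <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, c("x_px", "y_px")])
}

#' Write a provenance record as JSON
#'
#' @param record named list (parameters, thresholds, versions).
#' @param path output path.
#' @export
writeProvenanceJSON <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
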