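# Pipeline orchestration: simulate -> segment -> morph -> stats, with a
# single resolved configuration, per-stage provenance and a hash manifest.

#' Default pipeline configuration
#'
#' Returns the fully resolved default configuration. The segmentation
#' defaults are the constants of the reference processing chain: minimum
#' object area 0.144 mm2, single-pixel pore filling, periosteal closing
#' radius 0.48 mm, Gaussian pre-filter sigma 1.1 px / radius 2 px,
#' pore-diameter thresholds 60/100/160/300/385 um, alpha 0.05.
#'
#' @param ... named overrides of the defaults (nested lists merged).
#' @return nested list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    # Gaussian pre-filtering belongs to the CT-density path; impedance maps
    # are thresholded directly (smoothing erodes near-resolution pores)
    smoothing = list(enabled = FALSE, sigma_px = 1.1, radius_px = 2.0),
    segmentation = list(method = "otsu", window_px = 201, offset_frac = 0.1,
                        min_object_area_mm2 = 0.144,
                        closing_radius_mm = 0.48),
    morphometry = list(podm_thresholds_um = c(60, 100, 160, 300, 385),
                       ctth_bin_width_px = 1),
    roi = list(enabled = FALSE, sector_center_deg = 0, sector_width_deg = 60),
    stats = list(alpha = 0.05, covariate = "aBMD_neck"),
    simulate = list(n_sections = 5, pixel_size_mm = 0.012, noise_sd = 0.1),
    seed = 1L)
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Segment one calibrated image into section masks
#'
#' The fixed stage order smooth -> segment -> clean -> trace -> build,
#' driven by a [pipelineConfig()]. The endosteal boundary is an input
#' (manual delineation), never detected.
#'
#' @param img a [CalibratedImage-class].
#' @param endosteal endosteal boundary polygon (n x 2, 0-based px) or mask.
#' @param config a [pipelineConfig()].
#' @return list with `masks` ([SectionMasks-class]) and `provenance`
#'   (resolved parameters and applied thresholds).
#' @export
segmentSection <- function(img, endosteal, config = pipelineConfig()) {
  sg <- config$segmentation
  sm <- if (isTRUE(config$smoothing$enabled))
    smoothImage(img, config$smoothing$sigma_px, config$smoothing$radius_px)
  else img
  tm <- segmentTissue(sm, method = sg$method, windowPx = sg$window_px,
                      offsetFrac = sg$offset_frac)
  prov <- list(order = c("smooth", "segment", "clean", "trace", "build"),
               smoothing = config$smoothing,
               method = attr(tm, "method"),
               threshold = attr(tm, "threshold"),
               min_object_area_mm2 = sg$min_object_area_mm2,
               closing_radius_mm = sg$closing_radius_mm,
               closing_radius_px = sg$closing_radius_mm / pixelSize(img))
  cl <- cleanTissueMask(tm, pixelSize(img), sg$min_object_area_mm2)
  tr <- tracePeriosteal(cl, pixelSize(img), sg$closing_radius_mm)
  masks <- buildCorticalMask(tr$totalMask, cl, endosteal, pixelSize(img),
                             periostealContour = tr$contour)
  list(masks = masks, provenance = prov)
}

#' Run the full pipeline on synthetic sections
#'
#' Generates `n_sections` seeded synthetic cross-sections, runs the
#' segmentation stage on each noisy image (using the ground-truth
#' endosteal polygon as the manual boundary input), measures the full
#' morphometry, writes per-section artifacts (image TIFF+YAML, mask PNGs,
#' contour CSVs, provenance JSON), a combined morphometry CSV and a
#' manifest with MD5 hashes of every output. Deterministic given
#' config + seed.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created).
#' @param inputs optional real-data inputs: a data.frame (or list) with
#'   columns `image` (TIFF/PNG path with sidecar) and `endosteal` (contour
#'   CSV or mask PNG path). When omitted, `n_sections` synthetic sections
#'   are simulated and their ground-truth endosteal polygons serve as the
#'   manual boundary input.
#' @return path of the manifest JSON, invisibly; the manifest lists every
#'   output file with its MD5.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, inputs = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  simulate <- is.null(inputs)
  if (!simulate) {
    inputs <- as.data.frame(inputs)
    for (f in inputs$image)
      if (!file.exists(f)) stop("stage 'input': missing image file: ", f)
    for (f in inputs$endosteal)
      if (!file.exists(f)) stop("stage 'input': missing endosteal input: ", f)
  }
  n <- if (simulate) config$simulate$n_sections else nrow(inputs)
  rows <- vector("list", n)
  files <- character(0)
  for (i in seq_len(n)) {
    base <- file.path(outDir, sprintf("section_%03d", i))
    if (simulate) {
      spec <- sectionSpec(pixelSize = config$simulate$pixel_size_mm,
                          noiseSD = config$simulate$noise_sd,
                          seed = config$seed + i)
      sec <- generateCrossSection(spec)
      writeCalibratedImage(sec$image, paste0(base, ".tif"))
      # manual endosteal input, as in the intended real-data use
      endoPx <- sec$masks@endostealContour
    } else {
      sec <- list(image = readCalibratedImage(inputs$image[i]))
      ef <- inputs$endosteal[i]
      endoPx <- if (grepl("\\.png$", ef, ignore.case = TRUE))
        readMaskPNG(ef) else readContourCSV(ef)
    }
    res <- tryCatch(
      segmentSection(sec$image, endoPx, config),
      error = function(e) stop("stage 'segment' failed on section ", i, ": ",
                               conditionMessage(e)))
    masks <- res$masks
    if (isTRUE(config$roi$enabled))
      masks <- extractRoiUs(masks, config$roi$sector_center_deg,
                            config$roi$sector_width_deg)
    ms <- computeMorphometry(masks, img = sec$image,
                             thresholdsUm = config$morphometry$podm_thresholds_um,
                             binWidthPx = config$morphometry$ctth_bin_width_px)
    writeMaskPNG(tissueMask(masks), paste0(base, "_tissue.png"))
    writeMaskPNG(totalMask(masks), paste0(base, "_total.png"))
    writeMaskPNG(corticalMask(masks), paste0(base, "_cortical.png"))
    writeContourCSV(periostealContour(masks), paste0(base, "_periosteal.csv"))
    writeContourCSV(endostealContour(masks), paste0(base, "_endosteal.csv"))
    writeProvenanceJSON(res$provenance, paste0(base, "_provenance.json"))
    pores <- poreDiameters(poreLabels(masks), pixelSize(masks),
                           endostealContour = endostealContour(masks))
    utils::write.csv(pores, paste0(base, "_pores.csv"), row.names = FALSE)
    suff <- c("_tissue.png", "_total.png", "_cortical.png",
              "_periosteal.csv", "_endosteal.csv", "_provenance.json",
              "_pores.csv")
    if (simulate) suff <- c(".tif", ".tif.yaml", suff)
    files <- c(files, paste0(base, suff))
    rows[[i]] <- cbind(data.frame(section = i), as.data.frame(ms))
  }
  morph <- do.call(rbind, rows)
  morphPath <- file.path(outDir, "morphometry.csv")
  utils::write.csv(morph, morphPath, row.names = FALSE)
  files <- c(files, morphPath)
  manifest <- list(
    config = unclass(config),
    n_sections = n,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  manifestPath <- file.path(outDir, "manifest.json")
  writeProvenanceJSON(manifest, manifestPath)
  invisible(manifestPath)
}

#' Association analysis of a cohort table
#'
#' Runs the statistics stage on a cohort table: the association table
#' (marginal + partial correlations against every outcome) and, for each
#' outcome, the covariate-only and covariate+large-pore multivariate
#' models.
#'
#' @param cohort data.frame (see [generateCohort()]).
#' @param morphColumns morphometry columns to correlate (default: the key
#'   microstructure set).
#' @param outcomeColumns outcome columns.
#' @param covariate covariate column name.
#' @param largePore name of the large-pore predictor for the two-predictor
#'   models.
#' @param alpha reporting level.
#' @return list with `associations` (data.frame) and `models` (per outcome:
#'   `covariateOnly` and `withLargePore` fits from [fitLinearModel()]).
#' @export
analyzeCohort <- function(cohort,
                          morphColumns = c("Ct.Th", "Ct.Po", "Po.D",
                                           "Po.D_100", "relPo.n_100",
                                           "Po.Dm_mean", "relCt.Po_100"),
                          outcomeColumns = c("hvFE_S_stance", "hvFE_Fu_stance",
                                             "hvFE_S_fall", "hvFE_Fu_fall"),
                          covariate = "aBMD_neck",
                          largePore = "relCt.Po_100",
                          alpha = 0.05) {
  assoc <- buildAssociationTable(cohort, morphColumns, outcomeColumns,
                                 covariate, alpha)
  models <- lapply(stats::setNames(outcomeColumns, outcomeColumns),
    function(oc) {
      list(covariateOnly = fitLinearModel(cohort[[oc]],
                                          cohort[, covariate, drop = FALSE]),
           withLargePore = fitLinearModel(
             cohort[[oc]], cohort[, c(covariate, largePore), drop = FALSE]))
    })
  list(associations = assoc, models = models)
}
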