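# Serialization: PNG for RGB rasters, 16-bit grayscale TIFF for depth
# (integer millimetres as sample values), JSON for detector models and
# YAML for pipeline configuration.

#' Read / write an RGB-D frame
#'
#' RGB rasters are 8-bit PNG; depth rasters are 16-bit single-channel
#' TIFF whose sample values are millimetres (0 = no return).
#'
#' @param rgbPath,depthPath file paths.
#' @param registered is the stored pair pixel-aligned?
#' @param frameId frame identifier; defaults to the RGB file stem.
#' @return [readRGBDFrame()]: an [RGBDFrame-class].
#' @export
readRGBDFrame <- function(rgbPath, depthPath, registered = TRUE,
                          frameId = NULL) {
  rgb <- png::readPNG(rgbPath)
  if (length(dim(rgb)) == 3L && dim(rgb)[3] > 3L)
    rgb <- rgb[, , 1:3, drop = FALSE]
  depth <- tiff::readTIFF(depthPath, as.is = TRUE)
  if (length(dim(depth)) == 3L) depth <- depth[, , 1]
  storage.mode(depth) <- "integer"
  if (is.null(frameId))
    frameId <- sub("\\.[^.]+$", "", basename(rgbPath))
  rgbdFrame(rgb, depth, registered = registered, frameId = frameId)
}

#' @rdname readRGBDFrame
#' @param frame an [RGBDFrame-class].
#' @export
writeRGBDFrame <- function(frame, rgbPath, depthPath) {
  png::writePNG(frame@rgb, rgbPath)
  tiff::writeTIFF(frame@depth / 65535, depthPath, bits.per.sample = 16L)
  invisible(c(rgbPath, depthPath))
}

#' Read / write a detector model
#'
#' Single self-describing JSON file with a versioned header and the full
#' stage parameters.
#'
#' @param path file path.
#' @return [readDetector()]: a [DetectorModel-class].
#' @export
readDetector <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  stopifnot(identical(j$format, "mango-cascade"))
  stages <- lapply(j$stages, function(s) {
    list(threshold = s$threshold,
         stumps = lapply(s$stumps, function(st)
           list(feature = as.integer(st$feature), threshold = st$threshold,
                polarity = st$polarity, alpha = st$alpha, err = st$err)))
  })
  new("DetectorModel",
      windowSize = as.integer(j$windowSize), cellSize = as.integer(j$cellSize),
      nBins = as.integer(j$nBins), blockCells = as.integer(j$blockCells),
      stages = stages, mergeThreshold = as.integer(j$mergeThreshold),
      scaleFactor = j$scaleFactor, objectRange = as.numeric(j$objectRange),
      seed = as.integer(j$seed), version = j$version)
}

#' @rdname readDetector
#' @param model a [DetectorModel-class].
#' @export
writeDetector <- function(model, path) {
  j <- list(format = "mango-cascade", version = model@version,
            windowSize = model@windowSize, cellSize = model@cellSize,
            nBins = model@nBins, blockCells = model@blockCells,
            mergeThreshold = model@mergeThreshold,
            scaleFactor = model@scaleFactor,
            objectRange = model@objectRange, seed = model@seed,
            stages = model@stages)
  writeLines(jsonlite::toJSON(j, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

.intrToList <- function(intr) {
  list(resolution = intr@resolution, pixelPitch = intr@pixelPitch,
       focalX = intr@focalX, focalY = intr@focalY,
       principalPoint = intr@principalPoint,
       radialK1 = intr@radialK1, radialK2 = intr@radialK2)
}

.intrFromList <- function(x) {
  cameraIntrinsics(x$resolution, x$pixelPitch, x$focalX, x$focalY,
                   x$principalPoint, x$radialK1, x$radialK2)
}

#' Read / write a pipeline configuration
#'
#' Human-readable YAML mirroring the calibration-table field names for
#' the camera blocks plus the segmentation, gate and workflow settings.
#'
#' @param path file path.
#' @return [readPipelineConfig()]: a configuration list as from
#'   [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pipelineConfig(
    rgbIntr = .intrFromList(y$rgbCamera),
    depthIntr = if (!is.null(y$depthCamera)) .intrFromList(y$depthCamera),
    ext = if (!is.null(y$extrinsics))
      extrinsics(matrix(unlist(y$extrinsics$rotation), 3, 3, byrow = TRUE),
                 y$extrinsics$translation),
    seg = do.call(segmentationConfig, y$segmentation),
    gate = do.call(gateConfig, y$gate),
    minDepthMm = y$minDepthMm, depthBiasMm = y$depthBiasMm,
    mirror = y$mirror, dedupOverlap = y$dedupOverlap)
}

#' @rdname readPipelineConfig
#' @param config a configuration list from [pipelineConfig()].
#' @export
writePipelineConfig <- function(config, path) {
  y <- list(
    rgbCamera = .intrToList(config$rgbIntr),
    depthCamera = if (!is.null(config$depthIntr))
      .intrToList(config$depthIntr),
    extrinsics = if (!is.null(config$ext))
      list(rotation = apply(config$ext@rotation, 1, as.list),
           translation = config$ext@translation),
    segmentation = config$seg, gate = config$gate,
    minDepthMm = config$minDepthMm, depthBiasMm = config$depthBiasMm,
    mirror = config$mirror, dedupOverlap = config$dedupOverlap)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}
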