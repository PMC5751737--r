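# The end-to-end workflow: crop -> mirror -> detect -> expand -> segment
# -> stalk filter -> gate -> depth lookup -> thin-lens sizing, with every
# candidate accounted for as accepted or rejected.

#' Pipeline configuration
#'
#' @param rgbIntr [CameraIntrinsics-class] of the RGB camera (after any
#'   cropping; used for thin-lens sizing).
#' @param depthIntr,ext depth-camera intrinsics and depth-to-RGB
#'   extrinsics; required only for unregistered frames.
#' @param seg see [segmentationConfig()].
#' @param gate see [gateConfig()].
#' @param minDepthMm near-field exclusion bound, mm.
#' @param depthBiasMm constant device-face-to-sensor depth bias removed
#'   before sizing (19.1 mm for the characterized RGB-D unit; 0 for
#'   synthetic data).
#' @param mirror un-mirror the frame before detection (the Kinect
#'   presents imagery mirrored); synthetic scenes are rendered already
#'   in presentation orientation, so their configs set this `FALSE`.
#' @param dedupOverlap mask-overlap fraction above which two accepted
#'   components from different detection boxes are duplicates.
#' @return Named list of settings.
#' @export
pipelineConfig <- function(rgbIntr = kinectRGBIntrinsics(),
                           depthIntr = NULL, ext = NULL,
                           seg = segmentationConfig(), gate = gateConfig(),
                           minDepthMm = 800, depthBiasMm = 0,
                           mirror = TRUE, dedupOverlap = 0.5) {
  list(rgbIntr = rgbIntr, depthIntr = depthIntr, ext = ext, seg = seg,
       gate = gate, minDepthMm = minDepthMm, depthBiasMm = depthBiasMm,
       mirror = mirror, dedupOverlap = dedupOverlap)
}

#' Configuration matched to the synthetic scene generator
#'
#' @param resolution synthetic sensor size, (columns, rows).
#' @param ... overrides passed to [pipelineConfig()].
#' @return A pipeline configuration list.
#' @export
syntheticPipelineConfig <- function(resolution = c(400L, 320L), ...) {
  pipelineConfig(rgbIntr = syntheticIntrinsics(resolution),
                 mirror = FALSE, ...)
}

.emptyMeasurements <- function() {
  data.frame(frameId = character(0), boxId = integer(0),
             x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
             y1 = numeric(0), depthMm = numeric(0), lengthMm = numeric(0),
             widthMm = numeric(0), epsilon = numeric(0),
             areaRatio = numeric(0), flags = character(0),
             stringsAsFactors = FALSE)
}

#' Size every whole fruit in one RGB-D frame
#'
#' Runs the full workflow on a frame: registration and field-of-view
#' cropping when needed, optional un-mirroring, cascade detection,
#' per-candidate segmentation, stalk removal, ellipse completeness
#' gating, depth lookup and thin-lens sizing. Every gated component is
#' accounted for in the accepted measurements or the rejected list with
#' its first-failure reason ("area-low", "area-high", "ratio-low",
#' "ecc-high", "bbox-major", "otsu-degenerate", "chroma-empty",
#' "degenerate", "boundary" — the component touches the expanded-snip
#' edge so the contour may be crop-clipped —, "depth-missing",
#' "depth-near", "duplicate").
#'
#' @param frame an [RGBDFrame-class].
#' @param config see [pipelineConfig()].
#' @param detector a [DetectorModel-class], or any function
#'   `raster -> data.frame(x0, y0, x1, y1)` (the downstream stages are
#'   detector-agnostic).
#' @return List: `frameId`, `measurements` (data.frame), `rejected`
#'   (data.frame boxId/component/reason), `boxes` (detections),
#'   `skipped` flag with `skipReason`.
#' @export
sizeFrame <- function(frame, config = pipelineConfig(), detector) {
  stopifnot(is(frame, "RGBDFrame"))
  intr <- config$rgbIntr
  if (!frame@registered) {
    if (is.null(config$depthIntr))
      stop("unregistered frame requires depthIntr (and ext) in the config")
    ext <- if (is.null(config$ext)) extrinsics() else config$ext
    cropped <- cropRGBToDepthFOV(frame@rgb, intr, config$depthIntr, ext)
    cb <- attr(cropped, "cropBox")
    intr <- cameraIntrinsics(
      c(cb[["x1"]] - cb[["x0"]], cb[["y1"]] - cb[["y0"]]),
      intr@pixelPitch, intr@focalX, intr@focalY,
      intr@principalPoint - c(cb[["x0"]], cb[["y0"]]),
      intr@radialK1, intr@radialK2)
    frame <- rgbdFrame(cropped, frame@depth, registered = FALSE,
                       frameId = frame@frameId)
    frame <- registerDepthToRGB(frame, config$depthIntr, intr, ext)
  }
  rgb <- frame@rgb
  depth <- frame@depth
  if (isTRUE(config$mirror)) {
    rgb <- mirrorHorizontal(rgb)
    depth <- mirrorHorizontal(depth)
  }
  res <- list(frameId = frame@frameId, measurements = .emptyMeasurements(),
              rejected = data.frame(boxId = integer(0), component = integer(0),
                                    reason = character(0),
                                    stringsAsFactors = FALSE),
              boxes = NULL, skipped = FALSE, skipReason = NULL)
  if (!any(depth > 0L)) {
    res$skipped <- TRUE
    res$skipReason <- "no valid depth"
    return(res)
  }
  boxes <- if (is.function(detector)) detector(toGray(rgb))
           else detectFruit(toGray(rgb), detector)
  res$boxes <- boxes
  if (nrow(boxes) == 0L) return(res)
  H <- nrow(depth); W <- ncol(depth)
  accepted <- list()      # per accepted comp: measurement row + pixel set
  rejected <- NULL
  addReject <- function(boxId, comp, reason) {
    rejected <<- rbind(rejected,
                       data.frame(boxId = boxId, component = comp,
                                  reason = reason, stringsAsFactors = FALSE))
  }
  for (bi in seq_len(nrow(boxes))) {
    eb <- expandBox(unlist(boxes[bi, c("x0", "y0", "x1", "y1")]),
                    config$seg$boxExpandFactor, c(W, H))
    rows <- (eb[["y0"]] + 1L):eb[["y1"]]
    cols <- (eb[["x0"]] + 1L):eb[["x1"]]
    snip <- rgb[rows, cols, , drop = FALSE]
    seg <- segmentCandidate(snip, config$seg)
    if (!is.null(seg$reason)) { addReject(bi, 0L, seg$reason); next }
    lab <- labelComponents(seg$mask, 8L)
    nComp <- max(lab)
    if (nComp == 0L) { addReject(bi, 0L, "area-low"); next }
    for (ci in seq_len(nComp)) {
      comp <- lab == ci
      if (sum(comp) < 5L) { addReject(bi, ci, "degenerate"); next }
      # a component touching the expanded-snip edge may be clipped by
      # the crop, so its contour cannot be judged complete
      if (any(comp[1, ]) || any(comp[nrow(comp), ]) ||
          any(comp[, 1]) || any(comp[, ncol(comp)])) {
        addReject(bi, ci, "boundary"); next
      }
      fit <- tryCatch(fitMomentEllipse(comp), error = function(e) NULL)
      if (is.null(fit)) { addReject(bi, ci, "degenerate"); next }
      gate <- gateComponent(comp, fit, config$gate)
      if (!gate$accepted) { addReject(bi, ci, gate$reason); next }
      # lift the component to frame coordinates
      cidx <- which(comp, arr.ind = TRUE)
      frameIdx <- (cols[cidx[, 2]] - 1L) * H + rows[cidx[, 1]]
      bb <- .box(min(cols[cidx[, 2]]) - 1L, min(rows[cidx[, 1]]) - 1L,
                 max(cols[cidx[, 2]]), max(rows[cidx[, 1]]))
      meas <- measureComponent(NULL, bbox = bb, depth = depth, intr = intr,
                               minDepth = config$minDepthMm,
                               depthBias = config$depthBiasMm,
                               frameId = frame@frameId)
      if (nzchar(meas$flags)) { addReject(bi, ci, meas$flags); next }
      meas$boxId <- bi
      meas$epsilon <- fit@eccentricity
      meas$areaRatio <- fit@areaRatio
      accepted[[length(accepted) + 1L]] <-
        list(meas = meas, pixels = frameIdx, boxId = bi, component = ci)
    }
  }
  # deduplicate components captured through overlapping detection boxes
  if (length(accepted) > 1L) {
    keep <- rep(TRUE, length(accepted))
    for (i in seq_along(accepted)) {
      if (!keep[i]) next
      for (j in seq_along(accepted)) {
        if (i == j || !keep[j] || !keep[i]) next
        ov <- length(intersect(accepted[[i]]$pixels, accepted[[j]]$pixels)) /
          min(length(accepted[[i]]$pixels), length(accepted[[j]]$pixels))
        if (ov > config$dedupOverlap) {
          drop <- if (length(accepted[[i]]$pixels) >=
                      length(accepted[[j]]$pixels)) j else i
          keep[drop] <- FALSE
          addReject(accepted[[drop]]$boxId, accepted[[drop]]$component,
                    "duplicate")
        }
      }
    }
    accepted <- accepted[keep]
  }
  if (length(accepted) > 0L) {
    meas <- do.call(rbind, lapply(accepted, `[[`, "meas"))
    res$measurements <- meas[, c("frameId", "boxId", "x0", "y0", "x1", "y1",
                                 "depthMm", "lengthMm", "widthMm",
                                 "epsilon", "areaRatio", "flags")]
  }
  if (!is.null(rejected)) res$rejected <- rejected
  res
}

#' Size a directory of paired RGB/depth frames
#'
#' Pairs RGB PNGs with depth TIFFs by file stem, runs [sizeFrame()] on
#' each pair in deterministic (sorted) frame order and aggregates the
#' accepted measurements. Unpaired files are reported in the log, not
#' fatal.
#'
#' @param rgbDir,depthDir directories of `<stem>.png` and `<stem>.tif`
#'   files.
#' @param config see [pipelineConfig()].
#' @param detector as in [sizeFrame()].
#' @param out optional path for the aggregate measurements CSV.
#' @param registered are the stored frames already registered?
#' @return Invisibly, a list: `measurements` (data.frame), `frames`
#'   (per-frame results), `log` (data.frame of frame-level records).
#' @export
sizeBatch <- function(rgbDir, depthDir, config = pipelineConfig(), detector,
                      out = NULL, registered = TRUE) {
  rgbs <- list.files(rgbDir, pattern = "\\.png$")
  deps <- list.files(depthDir, pattern = "\\.tiff?$")
  rstem <- sub("\\.png$", "", rgbs)
  dstem <- sub("\\.tiff?$", "", deps)
  stems <- sort(intersect(rstem, dstem))
  log <- NULL
  for (s in setdiff(union(rstem, dstem), stems))
    log <- rbind(log, data.frame(frameId = s, event = "unpaired",
                                 stringsAsFactors = FALSE))
  if (length(stems) == 0L) warning("no paired frames found")
  frames <- list()
  meas <- .emptyMeasurements()
  for (s in stems) {
    fr <- readRGBDFrame(file.path(rgbDir, rgbs[match(s, rstem)]),
                        file.path(depthDir, deps[match(s, dstem)]),
                        registered = registered, frameId = s)
    r <- sizeFrame(fr, config, detector)
    frames[[s]] <- r
    if (r$skipped) {
      log <- rbind(log, data.frame(frameId = s, event = r$skipReason,
                                   stringsAsFactors = FALSE))
    } else if (nrow(r$measurements) > 0L) {
      meas <- rbind(meas, r$measurements)
    }
  }
  if (!is.null(out)) utils::write.csv(meas, out, row.names = FALSE)
  invisible(list(measurements = meas, frames = frames,
                 log = if (is.null(log))
                   data.frame(frameId = character(0), event = character(0))
                 else log))
}
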