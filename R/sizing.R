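# Depth lookup at accepted fruit and thin-lens conversion of bounding-box
# extents to millimetre length and width.
#
# Orientation convention: fruit hang vertically, so the vertical (row)
# extent of the bounding box maps to fruit length through the y-axis
# focal length, and the horizontal (column) extent to width through the
# x-axis focal length.

#' Depth at a bounding-box centre
#'
#' Averages the valid (non-zero) entries of the 2 x 2 pixel block
#' anchored at the centre pixel (the centre, rounded down, plus its
#' right / down neighbours), on a registered depth raster. Depths below
#' `minDepth` are flagged for near-field exclusion (surfaces closer than
#' 0.8 m are outside the sensor's working range).
#'
#' @param depth integer matrix, millimetres, 0 = invalid.
#' @param center numeric(2), (x, y) 0-based pixel coordinates (may be
#'   fractional).
#' @param minDepth near-field exclusion bound, millimetres.
#' @return List: `depth` (mm, NA when the whole block is invalid) and
#'   `flag` (`NULL`, "depth-missing" or "depth-near").
#' @export
centerDepth <- function(depth, center, minDepth = 800) {
  px <- floor(center[1]); py <- floor(center[2])
  rows <- (py + 1L):(py + 2L); cols <- (px + 1L):(px + 2L)
  rows <- rows[rows >= 1L & rows <= nrow(depth)]
  cols <- cols[cols >= 1L & cols <= ncol(depth)]
  if (length(rows) == 0L || length(cols) == 0L)
    return(list(depth = NA_real_, flag = "depth-missing"))
  block <- depth[rows, cols]
  vals <- block[block > 0L]
  if (length(vals) == 0L)
    return(list(depth = NA_real_, flag = "depth-missing"))
  D <- mean(vals)
  list(depth = D, flag = if (D < minDepth) "depth-near" else NULL)
}

#' Measure an accepted component in millimetres
#'
#' Takes the minimal bounding box of the component, looks up the
#' camera-to-fruit distance at the box centre ([centerDepth()]) and
#' converts the vertical extent to length (y-axis focal) and horizontal
#' extent to width (x-axis focal) via [pixelsToMm()]. A constant
#' device-face-to-sensor bias can be removed through `depthBias`.
#'
#' @param mask logical matrix of the component on the frame grid.
#' @param bbox optional precomputed box `c(x0, y0, x1, y1)`; derived from
#'   `mask` when `NULL`.
#' @param depth registered integer depth matrix, millimetres.
#' @param intr [CameraIntrinsics-class] of the RGB camera.
#' @param minDepth near-field exclusion bound, millimetres.
#' @param depthBias constant subtracted from the measured depth, mm.
#' @param frameId identifier copied into the record.
#' @return A one-row data.frame: frameId, x0, y0, x1, y1, depthMm,
#'   lengthMm, widthMm, flags (comma-joined; empty when clean).
#' @export
measureComponent <- function(mask, bbox = NULL, depth, intr,
                             minDepth = 800, depthBias = 0,
                             frameId = "frame") {
  if (is.null(bbox)) bbox <- .maskBBox(mask)
  if (is.null(bbox) || .boxWidth(bbox) <= 0 || .boxHeight(bbox) <= 0)
    stop("component bounding box has zero extent")
  center <- c((bbox[["x0"]] + bbox[["x1"]]) / 2,
              (bbox[["y0"]] + bbox[["y1"]]) / 2)
  cd <- centerDepth(depth, center, minDepth)
  flags <- cd$flag
  if (is.na(cd$depth)) {
    return(data.frame(frameId = frameId, x0 = bbox[["x0"]], y0 = bbox[["y0"]],
                      x1 = bbox[["x1"]], y1 = bbox[["y1"]],
                      depthMm = NA_real_, lengthMm = NA_real_,
                      widthMm = NA_real_, flags = paste(flags, collapse = ","),
                      stringsAsFactors = FALSE))
  }
  D <- cd$depth - depthBias
  data.frame(frameId = frameId, x0 = bbox[["x0"]], y0 = bbox[["y0"]],
             x1 = bbox[["x1"]], y1 = bbox[["y1"]], depthMm = D,
             lengthMm = pixelsToMm(.boxHeight(bbox), D, intr@focalY,
                                   intr@pixelPitch),
             widthMm = pixelsToMm(.boxWidth(bbox), D, intr@focalX,
                                  intr@pixelPitch),
             flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
}
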