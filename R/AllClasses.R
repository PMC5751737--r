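#' @import methods
NULL

#' Camera intrinsic parameters
#'
#' Pinhole optics of one camera: sensor resolution, pixel pitch, per-axis
#' focal lengths, principal point and the two radial distortion
#' coefficients used throughout the thin-lens arithmetic.
#'
#' @slot resolution integer(2), (columns, rows) in pixels.
#' @slot pixelPitch numeric(1), pixel side length in micrometres.
#' @slot focalX,focalY numeric(1), focal lengths along the image x and y
#'   axes, in millimetres.
#' @slot principalPoint numeric(2), principal point (x, y) in pixels,
#'   0-based image coordinates.
#' @slot radialK1,radialK2 numeric(1), radial distortion coefficients of
#'   the two-term model applied in normalized image coordinates.
#'
#' @seealso [cameraIntrinsics()], [kinectRGBIntrinsics()],
#'   [kinectToFIntrinsics()]
#' @export
setClass("CameraIntrinsics",
  representation(
    resolution = "integer",
    pixelPitch = "numeric",
    focalX = "numeric",
    focalY = "numeric",
    principalPoint = "numeric",
    radialK1 = "numeric",
    radialK2 = "numeric"
  )
)

setValidity("CameraIntrinsics", function(object) {
  msg <- character()
  if (length(object@resolution) != 2L || any(object@resolution < 1L))
    msg <- c(msg, "resolution must be two positive integers (columns, rows)")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be > 0")
  if (object@focalX <= 0 || object@focalY <= 0)
    msg <- c(msg, "focal lengths must be > 0")
  pp <- object@principalPoint
  if (length(pp) != 2L ||
      pp[1] < 0 || pp[1] > object@resolution[1] ||
      pp[2] < 0 || pp[2] > object@resolution[2])
    msg <- c(msg, "principal point must lie inside the sensor bounds")
  if (length(msg)) msg else TRUE
})

#' Rigid transform between depth and colour cameras
#'
#' @slot rotation 3x3 orthonormal rotation matrix (determinant +1).
#' @slot translation numeric(3) translation in millimetres.
#'
#' @seealso [extrinsics()]
#' @export
setClass("Extrinsics",
  representation(rotation = "matrix", translation = "numeric")
)

setValidity("Extrinsics", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)))
    return("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-6)
    return("rotation must have determinant +1")
  if (length(object@translation) != 3L)
    return("translation must have length 3")
  TRUE
})

#' Paired RGB and depth rasters
#'
#' RGB raster stored as a numeric array (rows x cols x 3) with values in
#' [0, 1] (8-bit quantization applies only at the PNG boundary); depth as
#' an integer matrix in millimetres with 0 reserved for "no return".
#' When `registered` is `TRUE` the depth raster is pixel-aligned to the
#' RGB raster.
#'
#' @slot rgb numeric array, rows x cols x 3, values in [0, 1].
#' @slot depth integer matrix, millimetres; 0 marks invalid pixels.
#' @slot registered logical(1).
#' @slot frameId character(1) identifier.
#'
#' @seealso [rgbdFrame()], [registerDepthToRGB()]
#' @export
setClass("RGBDFrame",
  representation(
    rgb = "array",
    depth = "matrix",
    registered = "logical",
    frameId = "character"
  )
)

setValidity("RGBDFrame", function(object) {
  msg <- character()
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "rgb must be a rows x cols x 3 array")
  if (any(object@depth < 0, na.rm = TRUE))
    msg <- c(msg, "depth values must be >= 0")
  if (isTRUE(object@registered) &&
      !all(dim(object@depth) == d[1:2]))
    msg <- c(msg, "registered depth must be pixel-aligned to rgb")
  if (length(msg)) msg else TRUE
})

#' Moment-fitted ellipse of a connected component
#'
#' Axes are reported as full lengths (`major` >= `minor`), orientation in
#' radians of the major axis from the image x axis, eccentricity
#' \eqn{\epsilon = \sqrt{1-(b/a)^2}} and the area ratio
#' \eqn{r = 4A/(\pi a b)} of pixel area to fitted-ellipse area.
#'
#' @slot area numeric(1), pixel count A.
#' @slot centroid numeric(2), (x, y) 0-based pixel coordinates.
#' @slot major,minor numeric(1), full axis lengths in pixels.
#' @slot orientation numeric(1), radians.
#' @slot eccentricity numeric(1), in [0, 1).
#' @slot areaRatio numeric(1).
#'
#' @seealso [fitMomentEllipse()], [gateComponent()]
#' @export
setClass("EllipseFit",
  representation(
    area = "numeric",
    centroid = "numeric",
    major = "numeric",
    minor = "numeric",
    orientation = "numeric",
    eccentricity = "numeric",
    areaRatio = "numeric"
  )
)

setValidity("EllipseFit", function(object) {
  msg <- character()
  if (object@minor <= 0 || object@major < object@minor)
    msg <- c(msg, "axes must satisfy major >= minor > 0")
  if (object@eccentricity < 0 || object@eccentricity >= 1)
    msg <- c(msg, "eccentricity must be in [0, 1)")
  if (object@area <= 0) msg <- c(msg, "area must be > 0")
  if (object@areaRatio <= 0) msg <- c(msg, "area ratio must be > 0")
  if (length(msg)) msg else TRUE
})

#' Trained HOG cascade fruit detector
#'
#' A staged-rejection classifier over HOG features: each stage is a
#' boosted ensemble of decision stumps with a pass threshold; a window
#' must pass every stage. Raw window hits are grouped and only groups
#' with at least `mergeThreshold` agreeing windows are reported.
#'
#' @slot windowSize integer(1), square detection window side in pixels.
#' @slot cellSize integer(1), HOG cell side in pixels.
#' @slot nBins integer(1), unsigned orientation bins.
#' @slot blockCells integer(1), block side in cells.
#' @slot stages list of per-stage parameter lists (stumps + threshold).
#' @slot mergeThreshold integer(1), minimum agreeing raw windows.
#' @slot scaleFactor numeric(1), pyramid step between scales.
#' @slot objectRange numeric(2), min/max object extent (px) covered by
#'   the pyramid.
#' @slot seed integer(1), training seed.
#' @slot version character(1), serialization format version.
#'
#' @seealso [trainDetector()], [detectFruit()]
#' @export
setClass("DetectorModel",
  representation(
    windowSize = "integer",
    cellSize = "integer",
    nBins = "integer",
    blockCells = "integer",
    stages = "list",
    mergeThreshold = "integer",
    scaleFactor = "numeric",
    objectRange = "numeric",
    seed = "integer",
    version = "character"
  )
)

setValidity("DetectorModel", function(object) {
  msg <- character()
  if (object@mergeThreshold < 1L) msg <- c(msg, "mergeThreshold must be >= 1")
  if (object@windowSize %% object@cellSize != 0L)
    msg <- c(msg, "windowSize must be a multiple of cellSize")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CameraIntrinsics", function(object) {
  cat("CameraIntrinsics:", object@resolution[1], "x", object@resolution[2],
      "px,", object@pixelPitch, "um pitch\n")
  cat("  focal (x, y):", object@focalX, "/", object@focalY, "mm;",
      "principal point:", paste(round(object@principalPoint, 2), collapse = ", "),
      "\n  radial K1/K2:", object@radialK1, "/", object@radialK2, "\n")
})

setMethod("show", "RGBDFrame", function(object) {
  d <- dim(object@rgb)
  nv <- sum(object@depth > 0L)
  cat("RGBDFrame", sQuote(object@frameId), ":",
      d[2], "x", d[1], "RGB;",
      ncol(object@depth), "x", nrow(object@depth), "depth (",
      nv, "valid px );",
      if (object@registered) "registered" else "unregistered", "\n")
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf(
    "EllipseFit: A=%d px, a=%.1f, b=%.1f px, theta=%.1f deg, eps=%.3f, r=%.3f\n",
    as.integer(object@area), object@major, object@minor,
    object@orientation * 180 / pi, object@eccentricity, object@areaRatio))
})

setMethod("show", "DetectorModel", function(object) {
  cat("DetectorModel:", length(object@stages), "stages,",
      object@windowSize, "px window,", "cell", object@cellSize, "px,",
      "merge threshold", object@mergeThreshold, "\n")
})

# ---- accessors -------------------------------------------------------------

#' Accessors for the core classes
#'
#' @param object a [CameraIntrinsics-class], [RGBDFrame-class] or
#'   [EllipseFit-class] object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
rgbRaster <- function(object) object@rgb

#' @rdname accessors
#' @export
depthRaster <- function(object) object@depth

#' @rdname accessors
#' @export
isRegistered <- function(object) object@registered

#' @rdname accessors
#' @export
frameId <- function(object) object@frameId

#' @rdname accessors
#' @export
resolution <- function(object) object@resolution

#' @rdname accessors
#' @export
pixelPitch <- function(object) object@pixelPitch

#' @rdname accessors
#' @export
focalX <- function(object) object@focalX

#' @rdname accessors
#' @export
focalY <- function(object) object@focalY

#' @rdname accessors
#' @export
principalPoint <- function(object) object@principalPoint

#' @rdname accessors
#' @export
majorAxis <- function(object) object@major

#' @rdname accessors
#' @export
minorAxis <- function(object) object@minor

#' @rdname accessors
#' @export
eccentricity <- function(object) object@eccentricity

#' @rdname accessors
#' @export
areaRatioOf <- function(object) object@areaRatio
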