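# Camera models, registration, cropping and thin-lens arithmetic.
#
# Conventions used package-wide: pixel coordinates are 0-based (x = column,
# y = row) with the origin at the top-left; boxes are half-open
# [x0, x1) x [y0, y1) so that width = x1 - x0. Depth is integer
# millimetres, 0 = no return, and is read as the plane-to-plane distance
# reported by the time-of-flight sensor; the thin-lens D uses that plane
# distance directly.

#' Construct camera intrinsics
#'
#' @param resolution integer(2), (columns, rows) in pixels.
#' @param pixelPitch pixel side length, micrometres.
#' @param focalX,focalY focal lengths, millimetres.
#' @param principalPoint numeric(2), (x, y) pixels; defaults to the
#'   sensor centre.
#' @param radialK1,radialK2 radial distortion coefficients.
#' @return A [CameraIntrinsics-class] object.
#' @examples
#' intr <- cameraIntrinsics(c(640, 480), 3.1, 3.28, 3.52)
#' @export
cameraIntrinsics <- function(resolution, pixelPitch, focalX, focalY,
                             principalPoint = resolution / 2,
                             radialK1 = 0, radialK2 = 0) {
  new("CameraIntrinsics",
      resolution = as.integer(resolution), pixelPitch = pixelPitch,
      focalX = focalX, focalY = focalY,
      principalPoint = as.numeric(principalPoint),
      radialK1 = radialK1, radialK2 = radialK2)
}

#' Kinect V2 factory calibrations
#'
#' Intrinsics of the RGB (1920x1080, 3.1 um) and time-of-flight
#' (512x424, 10 um) cameras of the Kinect V2 unit used for night orchard
#' imaging, as obtained by checkerboard calibration.
#'
#' @return A [CameraIntrinsics-class] object.
#' @examples
#' kinectRGBIntrinsics()
#' @export
kinectRGBIntrinsics <- function() {
  cameraIntrinsics(c(1920L, 1080L), 3.1, 3.2813, 3.5157,
                   c(965.112, 583.268), 9.3792e-5, -7.5342e-8)
}

#' @rdname kinectRGBIntrinsics
#' @export
kinectToFIntrinsics <- function() {
  cameraIntrinsics(c(512L, 424L), 10, 3.6413, 3.9029,
                   c(263.852, 225.717), 9.7968e-5, -1.9084e-7)
}

#' Construct a rigid depth-to-colour transform
#'
#' @param rotation 3x3 orthonormal matrix (default identity).
#' @param translation numeric(3), millimetres.
#' @return An [Extrinsics-class] object.
#' @export
extrinsics <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("Extrinsics", rotation = rotation, translation = as.numeric(translation))
}

#' Construct an RGB-D frame
#'
#' @param rgb numeric rows x cols x 3 array in [0, 1] (a plain matrix is
#'   replicated across channels).
#' @param depth integer matrix, millimetres, 0 = invalid.
#' @param registered logical(1), is `depth` pixel-aligned to `rgb`?
#' @param frameId character(1) identifier.
#' @return An [RGBDFrame-class] object.
#' @export
rgbdFrame <- function(rgb, depth, registered = FALSE, frameId = "frame") {
  if (is.matrix(rgb)) rgb <- array(rgb, c(dim(rgb), 3L))
  storage.mode(depth) <- "integer"
  new("RGBDFrame", rgb = rgb, depth = depth,
      registered = registered, frameId = frameId)
}

# normalized image coordinates: (px - principal point) * pitch / focal
.normalizePts <- function(pts, intr) {
  p <- intr@pixelPitch * 1e-3  # mm
  cbind((pts[, 1] - intr@principalPoint[1]) * p / intr@focalX,
        (pts[, 2] - intr@principalPoint[2]) * p / intr@focalY)
}

.denormalizePts <- function(ptsN, intr) {
  p <- intr@pixelPitch * 1e-3
  cbind(ptsN[, 1] * intr@focalX / p + intr@principalPoint[1],
        ptsN[, 2] * intr@focalY / p + intr@principalPoint[2])
}

#' Apply and invert the two-term radial distortion model
#'
#' `distortPoints` applies the forward radial model
#' \eqn{x_d = x_u (1 + K_1 r^2 + K_2 r^4)} about the principal point in
#' normalized image coordinates; `undistortPoints` inverts it by fixed-point
#' iteration (the model is invertible within the working field).
#'
#' @param points numeric n x 2 matrix of (x, y) pixel coordinates.
#' @param intr [CameraIntrinsics-class] supplying principal point, focal
#'   lengths, pitch and K1/K2.
#' @return n x 2 matrix of pixel coordinates.
#' @examples
#' intr <- kinectRGBIntrinsics()
#' p <- matrix(c(100, 200), 1)
#' undistortPoints(distortPoints(p, intr), intr)
#' @export
distortPoints <- function(points, intr) {
  points <- rbind(points)
  xn <- .normalizePts(points, intr)
  r2 <- rowSums(xn^2)
  f <- 1 + intr@radialK1 * r2 + intr@radialK2 * r2^2
  .denormalizePts(xn * f, intr)
}

#' @rdname distortPoints
#' @param iterations number of fixed-point iterations for the inverse.
#' @export
undistortPoints <- function(points, intr, iterations = 20L) {
  points <- rbind(points)
  xd <- .normalizePts(points, intr)
  xu <- xd
  for (i in seq_len(iterations)) {
    r2 <- rowSums(xu^2)
    f <- 1 + intr@radialK1 * r2 + intr@radialK2 * r2^2
    xu <- xd / f
  }
  .denormalizePts(xu, intr)
}

#' Register a depth raster onto the RGB pixel grid
#'
#' Back-projects every valid depth pixel to 3D camera coordinates (depth
#' read as plane distance Z), applies the rigid depth-to-colour transform
#' and projects into the RGB grid. RGB pixels receiving no depth sample
#' carry 0 (invalid); when two depth pixels land on the same RGB pixel
#' the smaller depth (nearer, occluding surface) wins.
#'
#' Rasters are assumed rectified (distortion already removed); the
#' pinhole model is applied directly.
#'
#' @param frame an unregistered [RGBDFrame-class].
#' @param depthIntr,rgbIntr [CameraIntrinsics-class] of the two cameras.
#' @param ext [Extrinsics-class] mapping depth-camera to RGB-camera
#'   coordinates.
#' @return A registered [RGBDFrame-class] whose depth raster matches the
#'   RGB raster dimensions.
#' @export
registerDepthToRGB <- function(frame, depthIntr, rgbIntr, ext = extrinsics()) {
  stopifnot(is(frame, "RGBDFrame"))
  if (frame@registered) stop("frame is already registered")
  depth <- frame@depth
  d <- dim(frame@rgb)
  out <- matrix(0L, d[1], d[2])
  valid <- which(depth > 0L)
  if (length(valid) == 0L) {
    warning("all depth pixels invalid: empty registration")
    fr <- rgbdFrame(frame@rgb, out, registered = TRUE, frameId = frame@frameId)
    attr(fr@depth, "empty") <- TRUE
    return(fr)
  }
  nr <- nrow(depth)
  v <- (valid - 1L) %% nr          # 0-based row (y)
  u <- (valid - 1L) %/% nr         # 0-based col (x)
  z <- as.numeric(depth[valid])
  pd <- depthIntr@pixelPitch * 1e-3
  X <- (u - depthIntr@principalPoint[1]) * pd * z / depthIntr@focalX
  Y <- (v - depthIntr@principalPoint[2]) * pd * z / depthIntr@focalY
  P <- ext@rotation %*% rbind(X, Y, z) + ext@translation
  keep <- P[3, ] > 0
  pr <- rgbIntr@pixelPitch * 1e-3
  ur <- round(P[1, keep] * rgbIntr@focalX / (pr * P[3, keep]) +
              rgbIntr@principalPoint[1])
  vr <- round(P[2, keep] * rgbIntr@focalY / (pr * P[3, keep]) +
              rgbIntr@principalPoint[2])
  zr <- P[3, keep]
  inb <- ur >= 0 & ur < d[2] & vr >= 0 & vr < d[1]
  ur <- ur[inb]; vr <- vr[inb]; zr <- zr[inb]
  # write far-to-near so the nearest surface wins collisions
  o <- order(zr, decreasing = TRUE)
  out[cbind(vr[o] + 1L, ur[o] + 1L)] <- as.integer(round(zr[o]))
  rgbdFrame(frame@rgb, out, registered = TRUE, frameId = frame@frameId)
}

#' Crop an RGB raster to the depth camera's field of view
#'
#' Computes the axis-aligned rectangle of RGB pixels whose viewing rays
#' fall inside the depth camera's angular field (rays taken from a common
#' origin, i.e. the baseline is neglected relative to working distance)
#' and returns the cropped raster. The crop rectangle is attached as
#' attribute `"cropBox"` (0-based, half-open `c(x0, y0, x1, y1)`).
#'
#' @param rgb numeric rows x cols x 3 array (or matrix).
#' @param rgbIntr,depthIntr [CameraIntrinsics-class] of the two cameras.
#' @param ext [Extrinsics-class]; accepted for interface completeness,
#'   the angular overlap itself is baseline-free.
#' @return The cropped raster with attribute `cropBox`.
#' @export
cropRGBToDepthFOV <- function(rgb, rgbIntr, depthIntr, ext = extrinsics()) {
  pd <- depthIntr@pixelPitch * 1e-3
  pr <- rgbIntr@pixelPitch * 1e-3
  # tangent extents of the depth field, per axis
  txr <- (c(0, depthIntr@resolution[1]) - depthIntr@principalPoint[1]) *
    pd / depthIntr@focalX
  tyr <- (c(0, depthIntr@resolution[2]) - depthIntr@principalPoint[2]) *
    pd / depthIntr@focalY
  x0 <- ceiling(rgbIntr@principalPoint[1] + txr[1] * rgbIntr@focalX / pr)
  x1 <- floor(rgbIntr@principalPoint[1] + txr[2] * rgbIntr@focalX / pr)
  y0 <- ceiling(rgbIntr@principalPoint[2] + tyr[1] * rgbIntr@focalY / pr)
  y1 <- floor(rgbIntr@principalPoint[2] + tyr[2] * rgbIntr@focalY / pr)
  d <- dim(rgb)
  x0 <- max(0L, as.integer(x0)); y0 <- max(0L, as.integer(y0))
  x1 <- min(d[2], as.integer(x1)); y1 <- min(d[1], as.integer(y1))
  if (x1 <= x0 || y1 <= y0)
    stop("RGB and depth fields of view do not overlap")
  out <- if (length(d) == 3L) rgb[(y0 + 1L):y1, (x0 + 1L):x1, , drop = FALSE]
         else rgb[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
  attr(out, "cropBox") <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  out
}

#' Thin-lens conversion of pixel extents to millimetres
#'
#' Applies f / D = image size / real size: an object spanning `nPx`
#' pixels on a sensor of pitch `pitch` (micrometres), imaged from plane
#' distance `D` (mm) through a lens of focal length `focal` (mm), has
#' real extent `nPx * pitch(mm) * D / focal` millimetres.
#'
#' @param nPx pixel extent (>= 0).
#' @param D camera-to-object distance, millimetres (> 0).
#' @param focal focal length, millimetres.
#' @param pitch pixel pitch, micrometres.
#' @return Extent in millimetres.
#' @examples
#' pixelsToMm(1, 2000, 3.5157, 3.1)  # ~1.76 mm per pixel at 2 m
#' @export
pixelsToMm <- function(nPx, D, focal, pitch) {
  if (any(D <= 0)) stop("distance D must be > 0")
  stopifnot(all(nPx >= 0), focal > 0)
  nPx * (pitch * 1e-3) * D / focal
}

#' First-order size error from a depth error
#'
#' Thin-lens sensitivity: an error `depthErr` in the measured distance
#' `D` propagates to an error of `objLen * depthErr / D` in the estimated
#' extent of an object of true extent `objLen`.
#'
#' @param objLen object extent, millimetres.
#' @param D camera-to-object distance, millimetres (> 0).
#' @param depthErr distance error, millimetres.
#' @return Size error, millimetres.
#' @examples
#' sizeErrorFromDepthError(100, 2000, 10)  # 0.5 mm
#' @export
sizeErrorFromDepthError <- function(objLen, D, depthErr) {
  if (any(D <= 0)) stop("distance D must be > 0")
  objLen * depthErr / D
}
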