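intrRGB <- kinectRGBIntrinsics()

test_that("radial distortion is identity for zero coefficients and at the principal point", {
  intr0 <- cameraIntrinsics(c(640L, 480L), 3.1, 3.28, 3.52)
  set.seed(1)
  pts <- cbind(runif(20, 0, 639), runif(20, 0, 479))
  expect_equal(distortPoints(pts, intr0), pts, ignore_attr = TRUE)
  expect_equal(undistortPoints(pts, intr0), pts, ignore_attr = TRUE)
  pp <- rbind(intrRGB@principalPoint)
  expect_equal(distortPoints(pp, intrRGB), pp, ignore_attr = TRUE)
})

test_that("radial model matches a scalar polynomial oracle at normalized radius 0.5", {
  # point at normalized radius 0.5 along x from the principal point
  p <- intrRGB@pixelPitch * 1e-3
  pt <- rbind(c(intrRGB@principalPoint[1] + 0.5 * intrRGB@focalX / p,
                intrRGB@principalPoint[2]))
  out <- distortPoints(pt, intrRGB)
  r2 <- 0.25
  fac <- 1 + intrRGB@radialK1 * r2 + intrRGB@radialK2 * r2^2
  expected <- intrRGB@principalPoint[1] + 0.5 * fac * intrRGB@focalX / p
  expect_lt(abs(out[1, 1] - expected), 1e-9)
  expect_lt(abs(out[1, 2] - intrRGB@principalPoint[2]), 1e-9)
  # invertible within the working field
  back <- undistortPoints(out, intrRGB)
  expect_equal(back, pt, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("registration with identity geometry is the identity on valid pixels", {
  intr <- cameraIntrinsics(c(60L, 40L), 10, 3.64, 3.90)
  set.seed(2)
  depth <- matrix(sample(c(0L, 1500:2500), 40 * 60, replace = TRUE), 40, 60)
  fr <- rgbdFrame(array(0.5, c(40, 60, 3)), depth)
  out <- registerDepthToRGB(fr, intr, intr, extrinsics())
  expect_true(isRegistered(out))
  expect_identical(depthRaster(out), depth)
})

test_that("pure x-translation of a constant plane shifts columns by fx*t/(D*pitch)", {
  intr <- cameraIntrinsics(c(80L, 50L), 3.1, 3.2813, 3.5157)
  D <- 2000
  shift <- 10
  t <- shift * D * intr@pixelPitch * 1e-3 / intr@focalX
  depth <- matrix(D, 50, 80)
  storage.mode(depth) <- "integer"
  fr <- rgbdFrame(array(0.5, c(50, 80, 3)), depth)
  out <- registerDepthToRGB(fr, intr, intr, extrinsics(translation = c(t, 0, 0)))
  d <- depthRaster(out)
  expect_true(all(d[, (shift + 1):80] == D))
  expect_true(all(d[, 1:shift] == 0L))   # unmapped pixels carry invalid depth
})

test_that("invalid depth pixels contribute nothing to registration", {
  intr <- cameraIntrinsics(c(20L, 20L), 10, 3.6, 3.9)
  depth <- matrix(0L, 20, 20)
  depth[5, 5] <- 2000L
  fr <- rgbdFrame(array(0, c(20, 20, 3)), depth)
  out <- registerDepthToRGB(fr, intr, intr)
  expect_equal(sum(depthRaster(out) > 0), 1L)
  fr0 <- rgbdFrame(array(0, c(20, 20, 3)), matrix(0L, 20, 20))
  expect_warning(out0 <- registerDepthToRGB(fr0, intr, intr), "invalid")
  expect_true(all(depthRaster(out0) == 0L))
})

test_that("field-of-view crop returns the full image for identical cameras", {
  intr <- cameraIntrinsics(c(64L, 48L), 3.1, 3.28, 3.52)
  rgb <- array(runif(48 * 64 * 3), c(48, 64, 3))
  out <- cropRGBToDepthFOV(rgb, intr, intr)
  expect_equal(dim(out), dim(rgb))
  expect_equal(unname(attr(out, "cropBox")), c(0, 0, 64, 48))
})

test_that("crop rectangle matches a ray-cast oracle when the RGB field is wider", {
  # RGB: wide horizontal field, narrow vertical; depth the opposite
  rgbI <- cameraIntrinsics(c(200L, 150L), 3.1, 2.0, 3.5)
  depI <- cameraIntrinsics(c(100L, 90L), 10, 3.6, 3.9)
  rgb <- array(0.5, c(150, 200, 3))
  out <- cropRGBToDepthFOV(rgb, rgbI, depI)
  cb <- attr(out, "cropBox")
  # oracle: project every RGB pixel-centre ray into the depth camera
  pr <- rgbI@pixelPitch * 1e-3; pd <- depI@pixelPitch * 1e-3
  inDepth <- function(u, v) {
    tx <- (u - rgbI@principalPoint[1]) * pr / rgbI@focalX
    ty <- (v - rgbI@principalPoint[2]) * pr / rgbI@focalY
    ud <- tx * depI@focalX / pd + depI@principalPoint[1]
    vd <- ty * depI@focalY / pd + depI@principalPoint[2]
    ud >= 0 && ud <= depI@resolution[1] && vd >= 0 && vd <= depI@resolution[2]
  }
  for (u in c(cb[["x0"]], cb[["x1"]] - 1)) expect_true(inDepth(u, 75))
  expect_false(inDepth(cb[["x0"]] - 1, 75))
  expect_false(inDepth(cb[["x1"]] + 1, 75))
  # left/right columns removed; the narrower RGB vertical field is kept whole
  expect_gt(cb[["x0"]], 0); expect_lt(cb[["x1"]], 200)
  expect_equal(unname(cb[c("y0", "y1")]), c(0, 150))
  # axis-aligned, in-bounds contract
  expect_true(cb[["x0"]] >= 0 && cb[["y0"]] >= 0)
  expect_true(cb[["x1"]] <= 200 && cb[["y1"]] <= 150)
  expect_error(cropRGBToDepthFOV(rgb, rgbI,
    cameraIntrinsics(c(10L, 10L), 1, 100, 100, c(5, 5))), "overlap")
})

test_that("thin-lens pixel conversion reproduces the published worked examples", {
  expect_lt(abs(pixelsToMm(1, 2000, 3.5157, 3.1) - 1.76), 0.005)
  expect_equal(pixelsToMm(0, 2000, 3.5157, 3.1), 0)
  expect_lt(abs(pixelsToMm(8, 2000, 3.5157, 3.1) - 14), 0.2)
  expect_error(pixelsToMm(5, 0, 3.5, 3.1), "D")
  expect_error(pixelsToMm(5, -10, 3.5, 3.1), "D")
})

test_that("pixel conversion is linear and round-trips exactly", {
  set.seed(3)
  for (i in 1:20) {
    n <- runif(1, 0, 200); D <- runif(1, 800, 4000)
    f <- runif(1, 3, 30); p <- runif(1, 3, 10)
    mm <- pixelsToMm(n, D, f, p)
    expect_equal(mm * f / (D * p * 1e-3), n, tolerance = 1e-12)
    expect_equal(pixelsToMm(2 * n, D, f, p), 2 * mm, tolerance = 1e-12)
    expect_equal(pixelsToMm(n, 2 * D, f, p), 2 * mm, tolerance = 1e-12)
  }
})

test_that("depth-error propagation reproduces the published sensitivities", {
  expect_equal(sizeErrorFromDepthError(100, 2000, 10), 0.5)
  expect_equal(round(sizeErrorFromDepthError(100, 2000, 155.6), 1), 7.8)
  expect_equal(sizeErrorFromDepthError(100, 2000, 0), 0)
  expect_error(sizeErrorFromDepthError(100, 0, 10), "D")
})

test_that("depth-error propagation agrees with the thin-lens difference to first order", {
  n <- 57; D <- 2000; f <- 3.5157; p <- 3.1
  L <- pixelsToMm(n, D, f, p)
  for (e in c(1, 5, 20)) {
    diff <- pixelsToMm(n, D + e, f, p) - pixelsToMm(n, D, f, p)
    pred <- sizeErrorFromDepthError(L, D, e)
    expect_equal(diff, pred, tolerance = (e / D)^2 + 1e-12)
  }
})
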