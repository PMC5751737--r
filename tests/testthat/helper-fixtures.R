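# Shared fixtures: all built in code at test time.

# draw a filled (optionally rotated) ellipse mask
ellipseMask <- function(halfW, halfH, tilt = 0, H = NULL, W = NULL,
                        cx = NULL, cy = NULL) {
  pad <- ceiling(halfW + halfH) + 6L
  if (is.null(H)) H <- 2L * pad
  if (is.null(W)) W <- 2L * pad
  if (is.null(cx)) cx <- W / 2
  if (is.null(cy)) cy <- H / 2
  px <- MangoSizer:::.ellipsePixels(H, W, cx, cy, halfW, halfH, tilt)
  m <- matrix(FALSE, H, W)
  m[cbind(px[, 1], px[, 2])] <- TRUE
  m
}

# take an elliptical "bite" out of a mask from the given side, covering
# the requested fraction of its pixels (leaf-occlusion geometry)
biteMask <- function(mask, fraction, side = "right") {
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  halfH <- (max(idx[, 1]) - min(idx[, 1])) / 2
  halfW <- (max(idx[, 2]) - min(idx[, 2])) / 2
  dir <- switch(side, left = c(-1, 0), right = c(1, 0), bottom = c(0, 1))
  lo <- 0; hi <- 2 * (halfW * abs(dir[1]) + halfH * abs(dir[2])) + 10
  n <- nrow(idx)
  out <- mask
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    opx <- MangoSizer:::.ellipsePixels(nrow(mask), ncol(mask),
                                       cx + dir[1] * mid, cy + dir[2] * mid,
                                       halfW, halfH, 0)
    om <- matrix(FALSE, nrow(mask), ncol(mask))
    if (!is.null(opx)) om[cbind(opx[, 1], opx[, 2])] <- TRUE
    cov <- sum(mask & om) / n
    if (cov > fraction) lo <- mid else hi <- mid
    out <- mask & !om
  }
  out
}

# build a one-fruit scene spec with fully pinned geometry
pinnedScene <- function(lengthMm, widthMm, distMm, tilt = 0, u = NULL,
                        v = NULL, params = sceneParams(nFruit = 1L),
                        intr = syntheticIntrinsics(), renderSeed = 99L,
                        occlusionFraction = 0, occSide = "right",
                        labL = 78, labA = 5, labB = 15) {
  distMm <- round(distMm)
  pitch <- intr@pixelPitch * 1e-3
  if (is.null(u)) u <- intr@resolution[1] / 2
  if (is.null(v)) v <- intr@resolution[2] / 2
  fruits <- data.frame(
    fruitId = 1L, u = u, v = v,
    centerXmm = (u - intr@principalPoint[1]) * pitch * distMm / intr@focalX,
    centerYmm = (v - intr@principalPoint[2]) * pitch * distMm / intr@focalY,
    trueLengthMm = lengthMm, trueWidthMm = widthMm, distanceMm = distMm,
    tilt = tilt, occlusionFraction = occlusionFraction, occSide = occSide,
    labA = labA, labB = labB, labL = labL)
  list(params = params, intr = intr, fruits = fruits, renderSeed = renderSeed)
}

# the reference synthetic detector, trained once per test run
.fixtures <- new.env(parent = emptyenv())

testDetector <- function() {
  if (is.null(.fixtures$detector)) {
    pos <- sampleSnips(80, "pos", seed = 11)
    neg <- sampleSnips(400, "neg", seed = 12)
    .fixtures$detector <- trainDetector(
      pos, neg, detectorConfig(nStages = 12, maxStumps = 30), seed = 3)
  }
  .fixtures$detector
}

# a pluggable "oracle" detector built from scene truth: returns the
# truth bounding boxes, exercising the detector-agnostic contract
truthDetector <- function(truth) {
  force(truth)
  function(raster) truth[, c("x0", "y0", "x1", "y1")]
}
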