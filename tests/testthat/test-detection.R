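test_that("horizontal mirroring is an involution with the expected index map", {
  set.seed(4)
  m <- matrix(runif(30), 5, 6)
  expect_identical(mirrorHorizontal(mirrorHorizontal(m)), m)
  expect_identical(mirrorHorizontal(m[, 1, drop = FALSE]), m[, 1, drop = FALSE])
  mm <- mirrorHorizontal(m)
  for (c0 in 0:5) expect_identical(mm[, c0 + 1], m[, 6 - c0])
  a <- array(runif(60), c(5, 6, 2))
  expect_identical(mirrorHorizontal(mirrorHorizontal(a)), a)
})

test_that("HOG of a constant snip is all zero and the 48x48 length matches the layout", {
  f <- hogFeatures(matrix(0.4, 48, 48))
  expect_true(all(f == 0))
  # (48/6 - 1)^2 blocks of 2x2 cells x 9 bins
  expect_length(f, 7 * 7 * 2 * 2 * 9)
})

test_that("HOG matches a direct finite-difference oracle on a 12x12 step edge", {
  snip <- matrix(0.1, 12, 12)
  snip[, 7:12] <- 0.9                      # vertical step edge
  f <- hogFeatures(snip)
  # oracle: per-pixel central differences, bilinear orientation votes,
  # 2x2-cell blocks, L2 norm — written independently, plain loops
  cellSize <- 6L; nBins <- 9L
  gx <- matrix(0, 12, 12); gy <- matrix(0, 12, 12)
  for (r in 1:12) for (c in 1:12) {
    cl <- snip[r, max(1, c - 1)]; cr <- snip[r, min(12, c + 1)]
    ct <- snip[max(1, r - 1), c]; cb <- snip[min(12, r + 1), c]
    gx[r, c] <- cr - cl; gy[r, c] <- cb - ct
  }
  cells <- array(0, c(2, 2, nBins))
  for (r in 1:12) for (c in 1:12) {
    mag <- sqrt(gx[r, c]^2 + gy[r, c]^2)
    if (mag == 0) next
    ang <- atan2(gy[r, c], gx[r, c]) %% pi
    pos <- ang / pi * nBins - 0.5
    b0 <- floor(pos); w1 <- pos - b0
    ci <- (r - 1) %/% cellSize + 1; cj <- (c - 1) %/% cellSize + 1
    cells[ci, cj, (b0 %% nBins) + 1] <-
      cells[ci, cj, (b0 %% nBins) + 1] + mag * (1 - w1)
    cells[ci, cj, ((b0 + 1) %% nBins) + 1] <-
      cells[ci, cj, ((b0 + 1) %% nBins) + 1] + mag * w1
  }
  block <- numeric(0)
  for (cj in 1:2) for (ci in 1:2) block <- c(block, cells[ci, cj, ])
  expected <- block / sqrt(sum(block^2))
  expect_equal(as.numeric(f), expected, tolerance = 1e-10)
  # a vertical step has a horizontal gradient: energy sits in the wrap
  # bins around orientation zero
  perBin <- sapply(1:9, function(b) sum(abs(f[seq(b, length(f), by = 9)])))
  expect_true(all(which(perBin > 1e-9) %in% c(1L, 9L)))
})

test_that("training is deterministic, errors without positives, and separates held-out snips", {
  pos <- sampleSnips(50, "pos", seed = 11)
  neg <- sampleSnips(300, "neg", seed = 12)
  d1 <- trainDetector(pos, neg, seed = 5)
  d2 <- trainDetector(pos, neg, seed = 5)
  expect_identical(d1@stages, d2@stages)
  expect_error(trainDetector(list(), neg, seed = 5), "positive")
  classify <- function(s, d) {
    f <- rbind(as.numeric(hogFeatures(s)))
    all(vapply(d@stages, function(st)
      MangoSizer:::.stageScore(f, st) >= st$threshold, logical(1)))
  }
  posH <- sampleSnips(40, "pos", seed = 31)
  negH <- sampleSnips(40, "neg", seed = 32)
  det <- testDetector()
  tp <- sum(vapply(posH, classify, logical(1), d = det))
  fp <- sum(vapply(negH, classify, logical(1), d = det))
  expect_gt(tp, 36)                      # detects held-out fruit snips
  # near-perfect snip-level precision; the zero-false-positive regime is
  # reached at scene level once merging and the ellipse gate apply
  expect_gte(tp / (tp + fp), 0.95)
})

test_that("a blank raster yields no detections", {
  det <- testDetector()
  expect_equal(nrow(detectFruit(matrix(0.5, 200, 200), det)), 0L)
})

test_that("well-separated rendered fruit are each covered by a detection with IoU >= 0.5", {
  det <- testDetector()
  spec <- sampleScene(sceneParams(nFruit = 3, lengthRange = c(95, 140),
                                  distRange = c(1700, 2300)),
                      seed = 71, intr = syntheticIntrinsics(c(420, 340)))
  scn <- renderScene(spec)
  boxes <- detectFruit(toGray(rgbRaster(scn$frame)), det)
  iou <- MangoSizer:::.boxIoUMat(boxes, scn$truth)
  expect_true(all(apply(iou, 2, max) >= 0.5))
})

test_that("raising the merge threshold never increases the number of boxes", {
  det <- testDetector()
  spec <- sampleScene(sceneParams(nFruit = 3, lengthRange = c(90, 140),
                                  distRange = c(1600, 2400)), seed = 72)
  g <- toGray(rgbRaster(renderScene(spec)$frame))
  counts <- vapply(c(1L, 4L, 8L, 16L, 40L), function(th)
    nrow(detectFruit(g, det, mergeThreshold = th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is translation-consistent within window-stride quantization", {
  det <- testDetector()
  spec <- pinnedScene(110, 90, 2000, u = 170, v = 140,
                      intr = syntheticIntrinsics(c(360, 300)),
                      params = sceneParams(nFruit = 1, nLeaves = 6,
                                           nBranches = 1))
  g <- toGray(renderScene(spec)$frame@rgb)
  dx <- 12L; dy <- 6L
  g1 <- g[1:(300 - dy), 1:(360 - dx)]
  g2 <- g[(dy + 1):300, (dx + 1):360]     # scene shifted by (-dx, -dy)
  b1 <- detectFruit(g1, det)
  b2 <- detectFruit(g2, det)
  expect_gt(nrow(b1), 0); expect_gt(nrow(b2), 0)
  # the box covering the fruit must move by the shift, up to the stride
  truth1 <- data.frame(x0 = 170 - 25, y0 = 140 - 30, x1 = 170 + 25,
                       y1 = 140 + 30)
  pick <- function(b, tr) b[which.max(MangoSizer:::.boxIoUMat(b, tr)), ]
  p1 <- pick(b1, truth1)
  truth2 <- truth1; truth2$x0 <- truth2$x0 - dx; truth2$x1 <- truth2$x1 - dx
  truth2$y0 <- truth2$y0 - dy; truth2$y1 <- truth2$y1 - dy
  p2 <- pick(b2, truth2)
  c1 <- c((p1$x0 + p1$x1) / 2, (p1$y0 + p1$y1) / 2)
  c2 <- c((p2$x0 + p2$x1) / 2, (p2$y0 + p2$y1) / 2)
  expect_lt(max(abs(c2 + c(dx, dy) - c1)), 9)
})

test_that("mirroring commutes with detection up to stride quantization", {
  det <- testDetector()
  spec <- pinnedScene(105, 85, 1900, u = 120, v = 150,
                      params = sceneParams(nFruit = 1, nLeaves = 6,
                                           nBranches = 1))
  g <- toGray(renderScene(spec)$frame@rgb)
  b <- detectFruit(g, det)
  bm <- detectFruit(mirrorHorizontal(g), det)
  expect_gt(nrow(b), 0); expect_gt(nrow(bm), 0)
  W <- ncol(g)
  truth <- data.frame(x0 = 120 - 25, y0 = 150 - 30, x1 = 120 + 25,
                      y1 = 150 + 30)
  truthM <- data.frame(x0 = W - truth$x1, y0 = truth$y0,
                       x1 = W - truth$x0, y1 = truth$y1)
  p <- b[which.max(MangoSizer:::.boxIoUMat(b, truth)), ]
  pm <- bm[which.max(MangoSizer:::.boxIoUMat(bm, truthM)), ]
  # mirror of (x0, x1) is (W - x1, W - x0)
  cm <- c((W - pm$x1 + W - pm$x0) / 2, (pm$y0 + pm$y1) / 2)
  cc <- c((p$x0 + p$x1) / 2, (p$y0 + p$y1) / 2)
  # one window stride at the matched pyramid scale (~6 / 0.55 px)
  expect_lt(max(abs(cm - cc)), 15)
})
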