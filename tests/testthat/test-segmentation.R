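test_that("box expansion doubles about the centre and clips without inverting", {
  b <- c(x0 = 10, y0 = 10, x1 = 30, y1 = 40)
  expect_equal(expandBox(b, 2, c(200, 200)),
               c(x0 = 0, y0 = 0, x1 = 40, y1 = 55))
  expect_equal(expandBox(b, 1, c(200, 200)), b)
  corner <- c(x0 = 180, y0 = 170, x1 = 198, y1 = 198)
  e <- expandBox(corner, 2, c(200, 200))
  expect_true(e[["x1"]] <= 200 && e[["y1"]] <= 200)
  expect_true(e[["x1"]] > e[["x0"]] && e[["y1"]] > e[["y0"]])
})

test_that("CIELAB conversion hits the white point, black and the neutral axis", {
  white <- toCielab(array(1, c(1, 1, 3)))
  expect_equal(white[1, 1, 1], 100, tolerance = 1e-6)
  expect_lt(max(abs(white[1, 1, 2:3])), 1e-6)
  black <- toCielab(array(0, c(1, 1, 3)))
  expect_equal(black[1, 1, 1], 0, tolerance = 1e-6)
  gray <- toCielab(array(128 / 255, c(1, 1, 3)))
  expect_lt(max(abs(gray[1, 1, 2:3])), 0.5)
})

test_that("Otsu separates two delta populations exactly and flags constants", {
  ch <- matrix(20, 10, 10); ch[3:7, 2:9] <- 80
  ot <- otsuBinarize(ch)
  expect_false(ot$degenerate)
  expect_identical(ot$mask, ch == 80)
  const <- otsuBinarize(matrix(42, 5, 5))
  expect_true(const$degenerate)
  expect_false(any(const$mask))
})

test_that("Otsu equals exhaustive between-class-variance search on random histograms", {
  set.seed(6)
  for (i in 1:50) {
    # random bimodal-ish channel on the L* scale
    n1 <- sample(50:300, 1); n2 <- sample(50:300, 1)
    v <- c(rnorm(n1, runif(1, 15, 45), runif(1, 2, 12)),
           rnorm(n2, runif(1, 55, 90), runif(1, 2, 12)))
    v <- pmin(pmax(v, 0), 100)
    ch <- matrix(v, nrow = 1)
    ot <- otsuBinarize(ch)
    # oracle: direct loop over all 256 candidate thresholds
    bin <- pmin(floor(v / (100 / 256)), 255)
    counts <- tabulate(bin + 1L, 256)
    mids <- (seq_len(256) - 0.5) * 100 / 256
    bestK <- NA; bestV <- -Inf
    for (k in 1:255) {
      w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
      if (w0 == 0 || w1 == 0) next
      mu0 <- sum(counts[1:k] * mids[1:k]) / w0
      mu1 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / w1
      vb <- w0 / sum(counts) * w1 / sum(counts) * (mu0 - mu1)^2
      if (vb > bestV + 1e-12) { bestV <- vb; bestK <- k }  # ties -> lowest
    }
    expect_equal(ot$threshold, bestK * 100 / 256, tolerance = 1e-9)
  }
})

test_that("the chroma gate keeps in-range pixels with inclusive bounds", {
  mkLab <- function(a, b) array(c(50, a, b), c(1, 1, 3))
  m <- matrix(TRUE, 1, 1)
  expect_true(chromaFilter(mkLab(0, 0), m)[1, 1])
  expect_false(chromaFilter(mkLab(30, 0), m)[1, 1])
  expect_true(chromaFilter(mkLab(25, 35), m)[1, 1])     # boundary kept
  expect_false(chromaFilter(mkLab(-26, 0), m)[1, 1])
  expect_false(chromaFilter(mkLab(0, 35.5), m)[1, 1])
  expect_false(chromaFilter(mkLab(0, -20.5), m)[1, 1])
  # only clears, never adds
  set.seed(7)
  lab <- array(c(runif(100, 0, 100), runif(200, -60, 60)), c(10, 10, 3))
  mask <- matrix(runif(100) > 0.4, 10)
  expect_true(all(chromaFilter(lab, mask) <= mask))
})

test_that("area opening respects the strict 300-pixel rule", {
  m <- matrix(FALSE, 60, 60)
  m[2:14, 2:24] <- TRUE                   # 13 x 23 = 299 px -> removed
  m[30:44, 30:49] <- TRUE                 # 15 x 20 = 300 px -> kept
  out <- morphClean(m)
  expect_false(any(out[2:14, 2:24]))
  expect_true(all(out[30:44, 30:49]))
})

test_that("hole filling fills a 250-px hole and grows the blob by exactly 250", {
  m <- matrix(FALSE, 100, 100)
  m[10:89, 10:79] <- TRUE                 # 80 x 70 blob
  m[30:54, 30:39] <- FALSE                # 25 x 10 = 250-px hole
  before <- sum(m)
  out <- morphClean(m)
  expect_equal(sum(out), before + 250)
  # a 300-px hole stays
  m2 <- matrix(FALSE, 100, 100)
  m2[10:89, 10:79] <- TRUE
  m2[30:59, 30:39] <- FALSE               # 30 x 10 = 300
  expect_equal(sum(morphClean(m2)), sum(m2))
})

test_that("morphClean output never contains small components or small enclosed holes", {
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(FALSE, 90, 90)
    for (k in 1:6) {
      px <- MangoSizer:::.ellipsePixels(90, 90, runif(1, 5, 85),
                                        runif(1, 5, 85), runif(1, 2, 18),
                                        runif(1, 2, 18), runif(1, -1, 1))
      if (!is.null(px)) m[cbind(px[, 1], px[, 2])] <- TRUE
    }
    out <- morphClean(m)
    lab <- labelComponents(out, 8L)
    if (max(lab) > 0) expect_true(all(tabulate(lab[lab > 0]) >= 300))
    bg <- labelComponents(!out, 4L)
    if (max(bg) > 0) {
      border <- unique(c(bg[1, ], bg[90, ], bg[, 1], bg[, 90]))
      inner <- setdiff(seq_len(max(bg)), border)
      if (length(inner)) {
        areas <- tabulate(bg[bg > 0])
        expect_true(all(areas[inner] >= 300))
      }
    }
  }
})

test_that("the 1D run filter removes short runs, keeps long ones, and is idempotent", {
  expect_equal(runFilterLine(c(0, rep(1, 7), 0), 8), rep(0, 9))
  expect_equal(runFilterLine(c(0, rep(1, 8), 0), 8), c(0, rep(1, 8), 0))
  expect_equal(runFilterLine(c(1, 1, 1, rep(0, 6)), 8), rep(0, 9))  # border delimits
  set.seed(9)
  for (i in 1:25) {
    v <- as.numeric(runif(40) > 0.5)
    w <- sample(1:10, 1)
    once <- runFilterLine(v, w)
    expect_equal(runFilterLine(once, w), once)
    r <- rle(once != 0)
    expect_true(all(r$lengths[r$values] >= w))
  }
})

test_that("stalk removal strips a thin stalk but preserves the fruit body", {
  fruit <- ellipseMask(20, 30, H = 120, W = 100, cx = 50, cy = 70)
  stalk <- matrix(FALSE, 120, 100)
  stalk[10:41, 49:51] <- TRUE             # 3-px-wide, 32-px-long stalk
  m <- fruit | stalk
  out <- removeStalks(m)
  dil <- MangoSizer:::.dilateDisk(fruit, 1)
  # stalk gone beyond the dilation band, body preserved up to the tip
  expect_true(all(!out[10:35, 49:51]))
  expect_lt(sum(fruit & !out), 120)       # at most the filtered tip rows
  expect_true(all(!out | dil | m))        # nothing far outside the fruit
})

test_that("a mask with no short runs comes back as its own dilation", {
  m <- matrix(FALSE, 50, 50)
  m[10:40, 10:40] <- TRUE
  expect_identical(removeStalks(m), MangoSizer:::.dilateDisk(m, 1))
  empty <- matrix(FALSE, 30, 30)
  expect_identical(removeStalks(empty), empty)
})

test_that("stalk filtering never creates foreground outside the dilation band", {
  set.seed(10)
  cfg0 <- segmentationConfig(dilationRadius = 0L)
  for (i in 1:8) {
    m <- matrix(runif(2500) > 0.55, 50, 50)
    pre <- removeStalks(m, cfg0)
    post <- removeStalks(m)
    expect_true(all(!post | MangoSizer:::.dilateDisk(pre, 1)))
  }
})

test_that("segmentCandidate recovers a rendered fruit and reports provenance", {
  spec <- pinnedScene(100, 80, 2000)
  scn <- renderScene(spec)
  tb <- scn$truth[1, ]
  eb <- expandBox(c(x0 = tb$x0, y0 = tb$y0, x1 = tb$x1, y1 = tb$y1), 2,
                  c(400, 320))
  snip <- rgbRaster(scn$frame)[(eb[["y0"]] + 1):eb[["y1"]],
                               (eb[["x0"]] + 1):eb[["x1"]], , drop = FALSE]
  seg <- segmentCandidate(snip)
  expect_null(seg$reason)
  expect_true(seg$threshold > 30 && seg$threshold < 70)
  expect_true(all(c("otsu", "chroma", "morph", "stalk") %in%
                  names(seg$stagePixels)))
  # the surviving mask is essentially the fruit
  expect_gt(sum(seg$mask), 0.8 * pi * (tb$x1 - tb$x0) * (tb$y1 - tb$y0) / 4)
})
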