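# HOG features and the cascade fruit detector.
#
# The detector follows the staged-rejection design: each stage is a
# boosted ensemble of decision stumps over HOG features with a pass
# threshold tuned to retain nearly all positives; negatives surviving a
# stage feed the next. At detection time a multiscale sliding window is
# evaluated through the stages and raw hits are grouped, with groups of
# fewer than the merge threshold discarded (high-precision regime: false
# negatives are acceptable, false positives are not).

#' Mirror a raster on the vertical axis
#'
#' Reverses column order (the Kinect presents imagery mirrored for gaming
#' use; the pipeline un-mirrors before detection). Involution:
#' `mirrorHorizontal(mirrorHorizontal(x))` is `x`.
#'
#' @param x matrix or rows x cols x k array.
#' @return Raster of the same dimensions with columns reversed.
#' @export
mirrorHorizontal <- function(x) {
  if (is.matrix(x)) return(x[, rev(seq_len(ncol(x))), drop = FALSE])
  stopifnot(length(dim(x)) == 3L)
  x[, rev(seq_len(ncol(x))), , drop = FALSE]
}

#' Convert an RGB array to luminance
#'
#' Rec. 709 luma weights on linear-free sRGB values in [0, 1].
#'
#' @param rgb rows x cols x 3 numeric array.
#' @return Numeric matrix in [0, 1].
#' @export
toGray <- function(rgb) {
  if (is.matrix(rgb)) return(rgb)
  0.2126 * rgb[, , 1] + 0.7152 * rgb[, , 2] + 0.0722 * rgb[, , 3]
}

# per-cell orientation histograms of a grayscale image whose dimensions
# are multiples of cellSize; returns array [cellRows, cellCols, nBins]
.hogCells <- function(gray, cellSize = 6L, nBins = 9L) {
  nr <- nrow(gray); nc <- ncol(gray)
  # central differences with replicated borders
  gx <- cbind(gray[, 2] - gray[, 1],
              gray[, 3:nc, drop = FALSE] - gray[, 1:(nc - 2), drop = FALSE],
              gray[, nc] - gray[, nc - 1])
  gy <- rbind(gray[2, ] - gray[1, ],
              gray[3:nr, , drop = FALSE] - gray[1:(nr - 2), , drop = FALSE],
              gray[nr, ] - gray[nr - 1, ])
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi                 # unsigned orientation [0, pi)
  pos <- ang / pi * nBins - 0.5              # continuous bin position
  b0 <- floor(pos)
  w1 <- pos - b0                             # weight of the upper bin
  b0 <- b0 %% nBins
  b1 <- (b0 + 1L) %% nBins
  cr <- (row(gray) - 1L) %/% cellSize        # 0-based cell indices
  cc <- (col(gray) - 1L) %/% cellSize
  nCr <- nr %/% cellSize; nCc <- nc %/% cellSize
  cellIdx <- cr + nCr * cc
  idx <- c(cellIdx + nCr * nCc * b0, cellIdx + nCr * nCc * b1) + 1L
  w <- c(mag * (1 - w1), mag * w1)
  hist <- numeric(nCr * nCc * nBins)
  acc <- rowsum(w, idx)
  hist[as.integer(rownames(acc))] <- acc
  array(hist, c(nCr, nCc, nBins))
}

# block-normalized descriptor grid: blocks of blockCells x blockCells
# cells, stride one cell, L2 normalization (zero-safe); returns array
# [blockRows, blockCols, blockCells^2 * nBins]
.hogBlocks <- function(cells, blockCells = 2L) {
  d <- dim(cells)
  nbr <- d[1] - blockCells + 1L
  nbc <- d[2] - blockCells + 1L
  if (nbr < 1L || nbc < 1L) return(NULL)
  k <- blockCells * blockCells * d[3]
  out <- array(0, c(nbr, nbc, k))
  slot <- 0L
  for (cj in seq_len(blockCells)) for (ci in seq_len(blockCells)) {
    for (b in seq_len(d[3])) {
      slot <- slot + 1L
      out[, , slot] <- cells[ci:(ci + nbr - 1L), cj:(cj + nbc - 1L), b]
    }
  }
  nrm <- sqrt(apply(out^2, c(1, 2), sum))
  nrm[nrm == 0] <- 1                          # all-zero gradient guard
  out / array(rep(nrm, k), c(nbr, nbc, k))
}

#' HOG feature vector of an image snip
#'
#' Dense histogram-of-oriented-gradients descriptor: 9 unsigned
#' orientation bins per 6x6-pixel cell, blocks of 2x2 cells with one-cell
#' stride, L2 block normalization. Snips whose dimensions are not
#' multiples of the cell size are resized (bilinear) to the nearest
#' multiples, recorded in attribute `"resized"`. A constant snip yields
#' the all-zero vector (normalization guards the divide).
#'
#' @param snip grayscale matrix (or RGB array, converted by [toGray()]),
#'   values in [0, 1].
#' @param cellSize cell side, pixels.
#' @param nBins unsigned orientation bins.
#' @param blockCells block side, in cells.
#' @return Numeric feature vector; length is
#'   `blockRows * blockCols * blockCells^2 * nBins`.
#' @examples
#' length(hogFeatures(matrix(runif(48 * 48), 48)))  # 1764
#' @export
hogFeatures <- function(snip, cellSize = 6L, nBins = 9L, blockCells = 2L) {
  snip <- toGray(snip)
  nr <- nrow(snip); nc <- ncol(snip)
  tr <- max(cellSize, round(nr / cellSize) * cellSize)
  tc <- max(cellSize, round(nc / cellSize) * cellSize)
  resized <- FALSE
  if (tr != nr || tc != nc) {
    snip <- .resizeGray(snip, tr, tc)
    resized <- TRUE
  }
  cells <- .hogCells(snip, cellSize, nBins)
  blocks <- .hogBlocks(cells, blockCells)
  out <- if (is.null(blocks)) numeric(0) else as.vector(blocks)
  attr(out, "resized") <- resized
  out
}

.resizeGray <- function(gray, nr, nc) {
  out <- EBImage::resize(EBImage::Image(gray), w = nr, h = nc)
  matrix(EBImage::imageData(out), nr, nc)
}

# ---- boosted stump stages --------------------------------------------------

# one round of discrete AdaBoost stump selection; X: n x p features,
# y in {-1, +1}, w weights summing to 1, ord: precomputed per-feature
# sort orders. Deterministic: ties broken by lowest feature index, then
# lowest threshold.
.bestStump <- function(X, y, w, ord) {
  n <- nrow(X); p <- ncol(X)
  best <- list(err = Inf)
  for (j in seq_len(p)) {
    o <- ord[, j]
    xo <- X[o, j]; yo <- y[o]; wo <- w[o]
    # err(theta between i and i+1, polarity +1: predict +1 when x > theta)
    # = sum w[y=+1, x<=theta] + sum w[y=-1, x>theta]
    cumPos <- cumsum(wo * (yo > 0))
    cumNeg <- cumsum(wo * (yo < 0))
    totNeg <- cumNeg[n]
    errPlus <- c(totNeg, cumPos[-n] + (totNeg - cumNeg[-n]))
    errMinus <- 1 - errPlus
    iP <- which.min(errPlus); iM <- which.min(errMinus)
    if (errPlus[iP] < best$err - 1e-12) {
      thr <- if (iP == 1L) xo[1] - 1e-6 else (xo[iP - 1] + xo[iP]) / 2
      best <- list(err = errPlus[iP], feature = j, threshold = thr,
                   polarity = 1)
    }
    if (errMinus[iM] < best$err - 1e-12) {
      thr <- if (iM == 1L) xo[1] - 1e-6 else (xo[iM - 1] + xo[iM]) / 2
      best <- list(err = errMinus[iM], feature = j, threshold = thr,
                   polarity = -1)
    }
  }
  best
}

.stumpPredict <- function(x, stump) {
  ifelse(x > stump$threshold, stump$polarity, -stump$polarity)
}

.stageScore <- function(X, stage) {
  s <- numeric(nrow(X))
  for (st in stage$stumps)
    s <- s + st$alpha * .stumpPredict(X[, st$feature], st)
  s
}

#' Detector training configuration
#'
#' @param nStages maximum cascade stages.
#' @param maxFalseAlarm per-stage false-alarm target on the surviving
#'   negatives.
#' @param minHitRate per-stage minimum true-positive rate.
#' @param maxStumps maximum boosted stumps per stage.
#' @param mergeThreshold neighbor-count merge threshold for detection.
#' @param zeroTrainingFP require zero false positives on the training
#'   negatives after the final stage (tightens the last stage threshold
#'   as far as the hit-rate constraint allows).
#' @param thresholdMargin stage-threshold safety margin as a fraction of
#'   the stage's total vote weight, guarding against thresholds pinned
#'   to the exact score of homogeneous training positives.
#' @param negFloor stop adding stages once fewer surviving negatives
#'   than this remain (later stages would overfit the stragglers).
#' @return A named list of settings.
#' @export
detectorConfig <- function(nStages = 10L, maxFalseAlarm = 0.5,
                           minHitRate = 0.995, maxStumps = 25L,
                           mergeThreshold = 8L, zeroTrainingFP = TRUE,
                           thresholdMargin = 0.1, negFloor = 10L) {
  list(nStages = as.integer(nStages), maxFalseAlarm = maxFalseAlarm,
       minHitRate = minHitRate, maxStumps = as.integer(maxStumps),
       mergeThreshold = as.integer(mergeThreshold),
       zeroTrainingFP = zeroTrainingFP, thresholdMargin = thresholdMargin,
       negFloor = as.integer(negFloor))
}

#' Train the HOG cascade fruit detector
#'
#' Boosted decision stumps over HOG features in staged rejection. Each
#' stage adds stumps until its false-alarm rate on the surviving
#' negatives drops below `maxFalseAlarm` (at a threshold retaining at
#' least `minHitRate` of positives); negatives rejected by a stage are
#' dropped before the next. Every snip also contributes its horizontal
#' mirror, keeping the learned cascade approximately mirror-equivariant
#' (fruit are left-right symmetric; the descriptor is not).
#' Deterministic for a given seed and inputs.
#'
#' @param posSnips,negSnips lists of grayscale matrices (or RGB arrays);
#'   resized to the detection window.
#' @param config see [detectorConfig()].
#' @param seed integer training seed.
#' @param windowSize square detection window, pixels (multiple of the
#'   cell size).
#' @return A [DetectorModel-class].
#' @export
trainDetector <- function(posSnips, negSnips, config = detectorConfig(),
                          seed = 1L, windowSize = 48L) {
  if (length(posSnips) == 0L) stop("at least one positive snip is required")
  if (length(negSnips) == 0L) stop("at least one negative snip is required")
  set.seed(seed)
  featurize <- function(s) {
    s <- toGray(s)
    if (nrow(s) != windowSize || ncol(s) != windowSize)
      s <- .resizeGray(s, windowSize, windowSize)
    as.numeric(hogFeatures(s))
  }
  withMirror <- function(snips)
    c(snips, lapply(snips, function(s) mirrorHorizontal(toGray(s))))
  Xp <- do.call(rbind, lapply(withMirror(posSnips), featurize))
  Xn <- do.call(rbind, lapply(withMirror(negSnips), featurize))
  stages <- list()
  for (s in seq_len(config$nStages)) {
    if (nrow(Xn) < config$negFloor) break
    X <- rbind(Xp, Xn)
    y <- c(rep(1, nrow(Xp)), rep(-1, nrow(Xn)))
    w <- rep(1 / nrow(X), nrow(X))
    ord <- apply(X, 2, order)
    stage <- list(stumps = list(), threshold = 0)
    repeat {
      st <- .bestStump(X, y, w, ord)
      err <- max(st$err, 1e-10)
      if (err >= 0.5) break
      st$alpha <- 0.5 * log((1 - err) / err)
      stage$stumps <- c(stage$stumps, list(st))
      pred <- .stumpPredict(X[, st$feature], st)
      w <- w * exp(-st$alpha * y * pred)
      w <- w / sum(w)
      score <- .stageScore(X, stage)
      posScores <- score[y > 0]
      nKeep <- ceiling(config$minHitRate * length(posScores))
      margin <- config$thresholdMargin *
        sum(vapply(stage$stumps, `[[`, numeric(1), "alpha"))
      thr <- sort(posScores, decreasing = TRUE)[nKeep] - margin - 1e-9
      fa <- mean(score[y < 0] >= thr)
      if (fa <= config$maxFalseAlarm || length(stage$stumps) >= config$maxStumps) {
        stage$threshold <- thr
        break
      }
    }
    if (length(stage$stumps) == 0L) break
    stages[[length(stages) + 1L]] <- stage
    keepNeg <- .stageScore(Xn, stage) >= stage$threshold
    Xn <- Xn[keepNeg, , drop = FALSE]
  }
  if (config$zeroTrainingFP && nrow(Xn) > 0L && length(stages) > 0L) {
    last <- stages[[length(stages)]]
    negS <- .stageScore(Xn, last)
    posS <- .stageScore(Xp, last)
    nKeep <- ceiling(config$minHitRate * length(posS))
    maxThr <- sort(posS, decreasing = TRUE)[nKeep] - 1e-9
    newThr <- min(max(negS) + 1e-9, maxThr)
    stages[[length(stages)]]$threshold <- max(last$threshold, newThr)
  }
  new("DetectorModel",
      windowSize = as.integer(windowSize), cellSize = 6L, nBins = 9L,
      blockCells = 2L, stages = stages,
      mergeThreshold = config$mergeThreshold,
      scaleFactor = 1.2, objectRange = c(40, 160),
      seed = as.integer(seed), version = "1.0")
}

#' Run the cascade detector over a raster
#'
#' Multiscale sliding-window detection: the raster is rescaled through a
#' factor-1.2 pyramid so the fixed window covers objects from
#' `objectRange[1]` to `objectRange[2]` pixels; windows step by one HOG
#' cell and must pass every cascade stage. Raw hits are grouped by
#' overlap (IoU >= 0.3, transitive); groups with fewer than
#' `mergeThreshold` raw hits are discarded and survivors are reported as
#' the member-box mean, clipped to the raster.
#'
#' @param raster grayscale matrix (or RGB array) in [0, 1].
#' @param model a [DetectorModel-class].
#' @param mergeThreshold override of the model's merge threshold.
#' @param boxScale fraction of the window reported as the detection box:
#'   training snips place the fruit at ~0.78 of the window height and
#'   ~0.61 of its width, whose geometric mean is ~0.7 (the cascade box
#'   need not tightly encapsulate the fruit — downstream segmentation
#'   re-expands it anyway).
#' @return data.frame with columns x0, y0, x1, y1 (0-based half-open
#'   pixel boxes) and n (raw hits in the group); zero rows when nothing
#'   is found.
#' @export
detectFruit <- function(raster, model, mergeThreshold = model@mergeThreshold,
                        boxScale = 0.7) {
  gray <- toGray(raster)
  win <- model@windowSize
  cell <- model@cellSize
  wCells <- win %/% cell
  wBlocks <- wCells - model@blockCells + 1L
  k <- model@blockCells^2 * model@nBins
  # image scale factors r: effective object size = win / r
  rs <- c(); r <- win / model@objectRange[1]
  while (win / r <= model@objectRange[2]) {
    rs <- c(rs, r)
    r <- r / model@scaleFactor
  }
  hits <- NULL
  for (r in rs) {
    nr <- round(nrow(gray) * r); nc <- round(ncol(gray) * r)
    if (nr < win || nc < win) next
    g <- if (abs(r - 1) < 1e-9) gray else .resizeGray(gray, nr, nc)
    g <- g[seq_len((nrow(g) %/% cell) * cell),
           seq_len((ncol(g) %/% cell) * cell), drop = FALSE]
    cells <- .hogCells(g, cell, model@nBins)
    B <- .hogBlocks(cells, model@blockCells)
    if (is.null(B)) next
    d <- dim(B)
    nwr <- d[1] - wBlocks + 1L
    nwc <- d[2] - wBlocks + 1L
    if (nwr < 1L || nwc < 1L) next
    act <- cbind(wi = rep(seq_len(nwr), nwc),
                 wj = rep(seq_len(nwc), each = nwr))
    for (stage in model@stages) {
      if (nrow(act) == 0L) break
      score <- numeric(nrow(act))
      for (st in stage$stumps) {
        f <- st$feature - 1L
        kk <- f %/% (wBlocks * wBlocks)
        rem <- f %% (wBlocks * wBlocks)
        dbj <- rem %/% wBlocks
        dbi <- rem %% wBlocks
        vals <- B[cbind(act[, 1] + dbi, act[, 2] + dbj, kk + 1L)]
        score <- score + st$alpha *
          ifelse(vals > st$threshold, st$polarity, -st$polarity)
      }
      act <- act[score >= stage$threshold, , drop = FALSE]
    }
    if (nrow(act) > 0L) {
      x0 <- (act[, 2] - 1L) * cell / r
      y0 <- (act[, 1] - 1L) * cell / r
      hits <- rbind(hits, cbind(x0 = x0, y0 = y0,
                                x1 = x0 + win / r, y1 = y0 + win / r,
                                scale = r))
    }
  }
  empty <- data.frame(x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), n = integer(0))
  if (is.null(hits)) return(empty)
  grp <- .groupBoxes(hits, iou = 0.4)
  keep <- which(tabulate(grp) >= mergeThreshold)
  if (length(keep) == 0L) return(empty)
  out <- do.call(rbind, lapply(keep, function(gid) {
    m <- hits[grp == gid, , drop = FALSE]
    # stride-density compensation: windows at pyramid scale r step by
    # cell/r, so fine scales contribute quadratically more raw hits;
    # weighting by 1/r^2 makes every scale count by covered area
    w <- 1 / m[, "scale"]^2
    c(x0 = stats::weighted.mean(m[, "x0"], w),
      y0 = stats::weighted.mean(m[, "y0"], w),
      x1 = stats::weighted.mean(m[, "x1"], w),
      y1 = stats::weighted.mean(m[, "y1"], w), n = nrow(m))
  }))
  out <- as.data.frame(out)
  # shrink the window box to the trained object fraction
  cx <- (out$x0 + out$x1) / 2; cy <- (out$y0 + out$y1) / 2
  hw <- (out$x1 - out$x0) / 2 * boxScale
  hh <- (out$y1 - out$y0) / 2 * boxScale
  out$x0 <- cx - hw; out$x1 <- cx + hw
  out$y0 <- cy - hh; out$y1 <- cy + hh
  out$x0 <- pmax(0, round(out$x0)); out$y0 <- pmax(0, round(out$y0))
  out$x1 <- pmin(ncol(gray), round(out$x1))
  out$y1 <- pmin(nrow(gray), round(out$y1))
  out[order(out$x0, out$y0), , drop = FALSE]
}

# transitive grouping of boxes by pairwise IoU; returns group ids
.groupBoxes <- function(boxes, iou = 0.3) {
  n <- nrow(boxes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  M <- .boxIoUMat(boxes, boxes)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (M[i, j] >= iou) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
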