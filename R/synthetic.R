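# Synthetic RGB-D canopy scenes with ground truth: the test harness
# standing in for orchard imagery.
#
# What is emulated: bright convex elliptical fruit against darker
# leaf/branch clutter (night LED illumination), thin pendulous stalks,
# partial occlusion by foliage, camera-to-fruit distances of 1-3 m and
# integer-mm time-of-flight depth with Gaussian noise and dropout. Fruit
# chroma is sampled inside the segmentation gate with a margin and
# foliage outside it, so the published fixed thresholds are the correct
# separator by construction; an adversarial mode narrows the margin.

#' Default synthetic camera
#'
#' The published RGB optics (3.1 um pitch, 3.2813 / 3.5157 mm focals,
#' no distortion) behind a smaller sensor so test scenes stay fast;
#' principal point at the centre.
#'
#' @param resolution integer(2), (columns, rows).
#' @return A [CameraIntrinsics-class].
#' @export
syntheticIntrinsics <- function(resolution = c(400L, 320L)) {
  cameraIntrinsics(resolution, 3.1, 3.2813, 3.5157)
}

#' Synthetic scene parameters
#'
#' @param nFruit fruit per scene.
#' @param lengthRange true fruit length range, mm.
#' @param widthRange clip range for true width, mm.
#' @param aspectRange width/length ratio range (mango-like aspect).
#' @param distRange camera-to-fruit distance range, mm.
#' @param tiltRange fruit tilt from vertical, radians.
#' @param pOccluded probability a fruit is partially occluded.
#' @param occlusionRange occlusion fraction range for occluded fruit.
#' @param stalk render pendulous stalks?
#' @param stalkWidthPx stalk width, pixels (thinner than the run filter).
#' @param stalkLengthMm stalk length, mm.
#' @param nLeaves foliage clutter ellipses per scene.
#' @param nBranches branch strips per scene.
#' @param depthNoiseSd depth noise standard deviation, mm (11 mm is the
#'   bias-corrected RMSE measured on fruit for the RGB-D unit).
#' @param dropoutFraction fraction of valid depth pixels zeroed.
#' @param backgroundDepthMm far-canopy depth, mm.
#' @param adversarial narrow the fruit/foliage chroma margin.
#' @return Named list of generator settings.
#' @export
sceneParams <- function(nFruit = 5L, lengthRange = c(60, 160),
                        widthRange = c(50, 130), aspectRange = c(0.75, 0.85),
                        distRange = c(1000, 3000), tiltRange = c(-0.17, 0.17),
                        pOccluded = 0, occlusionRange = c(0.2, 0.5),
                        stalk = TRUE, stalkWidthPx = 3L, stalkLengthMm = 40,
                        nLeaves = 25L, nBranches = 3L,
                        depthNoiseSd = 0, dropoutFraction = 0,
                        backgroundDepthMm = 3800, adversarial = FALSE) {
  stopifnot(lengthRange[1] <= lengthRange[2], distRange[1] <= distRange[2],
            all(occlusionRange >= 0), all(occlusionRange < 1),
            nFruit >= 0)
  as.list(environment())
}

#' Sample a scene specification
#'
#' Draws per-fruit geometry (true length/width, distance, tilt,
#' occlusion state, chroma) and image-plane placement, deterministically
#' from `seed`. Fruit are placed well-separated (centre spacing beyond
#' the sum of their radii) by rejection sampling; fruit that cannot be
#' placed inside the frame are dropped with a warning.
#'
#' @param params see [sceneParams()].
#' @param seed integer seed; all scene randomness flows from it.
#' @param intr [CameraIntrinsics-class] used for placement.
#' @return A scene spec: list with `params`, `intr`, `fruits`
#'   (data.frame), `renderSeed`.
#' @export
sampleScene <- function(params = sceneParams(), seed = 1L,
                        intr = syntheticIntrinsics()) {
  set.seed(seed)
  p <- params
  W <- intr@resolution[1]; H <- intr@resolution[2]
  pitch <- intr@pixelPitch * 1e-3
  fruits <- NULL
  placed <- list()
  nDropped <- 0L
  for (i in seq_len(p$nFruit)) {
    Lmm <- runif(1, p$lengthRange[1], p$lengthRange[2])
    Wmm <- min(max(runif(1, p$aspectRange[1], p$aspectRange[2]) * Lmm,
                   p$widthRange[1]), p$widthRange[2])
    D <- runif(1, p$distRange[1], p$distRange[2])
    halfH <- (Lmm / 2) * intr@focalY / (D * pitch)
    halfW <- (Wmm / 2) * intr@focalX / (D * pitch)
    tilt <- runif(1, p$tiltRange[1], p$tiltRange[2])
    occ <- if (runif(1) < p$pOccluded)
      runif(1, p$occlusionRange[1], p$occlusionRange[2]) else 0
    stalkPx <- if (p$stalk) p$stalkLengthMm * intr@focalY / (D * pitch) else 0
    ok <- FALSE
    marg <- 4 + 0.3 * max(halfH, halfW)  # keep fruit clear of the frame
    for (try in 1:60) {
      u <- runif(1, halfW + marg, W - halfW - marg)
      v <- runif(1, halfH + stalkPx + marg, H - halfH - marg)
      sep <- TRUE
      for (q in placed) {
        if (sqrt((u - q[1])^2 + (v - q[2])^2) <
            1.25 * (max(halfH, halfW) + q[3])) { sep <- FALSE; break }
      }
      if (sep) { ok <- TRUE; break }
    }
    if (!ok) { nDropped <- nDropped + 1L; next }
    placed[[length(placed) + 1L]] <- c(u, v, max(halfH, halfW))
    marg <- if (p$adversarial) c(24, 34) else c(15, 25)
    fruits <- rbind(fruits, data.frame(
      fruitId = length(placed), u = u, v = v,
      centerXmm = (u - intr@principalPoint[1]) * pitch * D / intr@focalX,
      centerYmm = (v - intr@principalPoint[2]) * pitch * D / intr@focalY,
      trueLengthMm = Lmm, trueWidthMm = Wmm, distanceMm = round(D),
      tilt = tilt, occlusionFraction = occ,
      occSide = sample(c("left", "right", "bottom"), 1),
      labA = runif(1, -marg[1], marg[1]), labB = runif(1, 0, marg[2]),
      labL = runif(1, 72, 84)))
  }
  if (nDropped > 0L)
    warning(nDropped, " fruit could not be placed and were dropped")
  list(params = p, intr = intr,
       fruits = if (is.null(fruits))
         data.frame(fruitId = integer(0)) else fruits,
       renderSeed = sample.int(2^30, 1))
}

# pixel set of a rotated filled ellipse; returns logical matrix section
.ellipsePixels <- function(H, W, u, v, halfW, halfH, tilt) {
  x0 <- max(1L, floor(u - halfW - halfH)); x1 <- min(W, ceiling(u + halfW + halfH))
  y0 <- max(1L, floor(v - halfW - halfH)); y1 <- min(H, ceiling(v + halfW + halfH))
  if (x1 < x0 || y1 < y0) return(NULL)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - 1 - u)
  dy <- outer(ys - 1 - v, rep(1, length(xs)))
  ct <- cos(tilt); st <- sin(tilt)
  rx <- dx * ct + dy * st
  ry <- -dx * st + dy * ct
  inside <- (rx / halfW)^2 + (ry / halfH)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  cbind(row = ys[idx[, 1]], col = xs[idx[, 2]])
}

#' Render a scene to an RGB-D frame with ground truth
#'
#' Composes (far to near) an illumination-graded foliage background,
#' leaf and branch clutter, then each fruit as a bright shaded ellipse
#' with an attached thin stalk; partially occluded fruit are overpainted
#' by a foliage band covering the requested pixel fraction. The depth
#' raster carries each surface's true distance (integer mm) plus
#' truncated Gaussian noise and optional dropout. By default the frame
#' is rendered in registered geometry (depth aligned to RGB); supplying
#' `depthIntr` and `ext` instead renders the depth raster through the
#' depth camera to exercise the registration path.
#'
#' @param spec from [sampleScene()].
#' @param depthIntr,ext optional depth-camera intrinsics and
#'   depth-to-RGB extrinsics for unregistered rendering.
#' @return List: `frame` ([RGBDFrame-class]) and `truth` (data.frame,
#'   one row per rendered fruit: bbox of the un-occluded fruit pixels,
#'   true dimensions, distance, occlusion state).
#' @export
renderScene <- function(spec, depthIntr = NULL, ext = NULL) {
  set.seed(spec$renderSeed)
  intr <- spec$intr
  p <- spec$params
  W <- intr@resolution[1]; H <- intr@resolution[2]
  pitch <- intr@pixelPitch * 1e-3
  # background: dark foliage, vertical illumination gradient
  Lc <- matrix(rep(seq(18, 30, length.out = H), W), H) +
    matrix(rnorm(H * W, 0, 1.2), H)
  Ac <- matrix(-35, H, W); Bc <- matrix(20, H, W)
  depth <- matrix(as.integer(round(p$backgroundDepthMm +
                                     rnorm(H * W, 0, 40))), H, W)
  paint <- function(px, L, a, b, d) {
    if (is.null(px)) return(invisible())
    ii <- cbind(px[, 1], px[, 2])
    Lc[ii] <<- L; Ac[ii] <<- a; Bc[ii] <<- b
    depth[ii] <<- as.integer(round(d))
  }
  # leaf clutter: chroma outside the gate (strongly green)
  for (i in seq_len(p$nLeaves)) {
    px <- .ellipsePixels(H, W, runif(1, 1, W), runif(1, 1, H),
                         runif(1, 6, 26), runif(1, 4, 16),
                         runif(1, -pi / 2, pi / 2))
    paint(px, runif(1, 22, 52), runif(1, -50, -30), runif(1, 10, 34),
          runif(1, 2800, 3600))
  }
  # branches: elongated strips, b* above the gate
  for (i in seq_len(p$nBranches)) {
    px <- .ellipsePixels(H, W, runif(1, 1, W), runif(1, 1, H),
                         runif(1, 40, 90), runif(1, 3, 6),
                         runif(1, -pi / 2, pi / 2))
    paint(px, runif(1, 28, 46), runif(1, 5, 15), runif(1, 45, 60),
          runif(1, 2600, 3400))
  }
  truth <- NULL
  fr <- spec$fruits
  for (i in seq_len(nrow(fr))) {
    f <- fr[i, ]
    D <- f$distanceMm
    halfH <- (f$trueLengthMm / 2) * intr@focalY / (D * pitch)
    halfW <- (f$trueWidthMm / 2) * intr@focalX / (D * pitch)
    px <- .ellipsePixels(H, W, f$u, f$v, halfW, halfH, f$tilt)
    if (is.null(px)) {
      warning("fruit ", f$fruitId, " projects outside the frame; dropped")
      next
    }
    # convex shading: brightest at centre, falling toward the rim
    rad2 <- ((px[, 2] - 1 - f$u) / halfW)^2 + ((px[, 1] - 1 - f$v) / halfH)^2
    Lpx <- f$labL - 10 * rad2 + rnorm(nrow(px), 0, 1.2)
    ii <- cbind(px[, 1], px[, 2])
    Lc[ii] <- Lpx; Ac[ii] <- f$labA; Bc[ii] <- f$labB
    depth[ii] <- as.integer(round(D))
    bb <- c(x0 = min(px[, 2]) - 1L, y0 = min(px[, 1]) - 1L,
            x1 = max(px[, 2]), y1 = max(px[, 1]))
    # pendulous stalk above the fruit: thin, chroma inside the gate
    if (p$stalk) {
      stalkLen <- round(p$stalkLengthMm * intr@focalY / (D * pitch))
      sx <- round(f$u) + seq_len(p$stalkWidthPx) - (p$stalkWidthPx + 1L) %/% 2L
      sy <- (round(f$v - halfH) - stalkLen):(round(f$v - halfH) + 2L)
      sx <- sx[sx >= 1L & sx <= W]; sy <- sy[sy >= 1L & sy <= H]
      if (length(sx) && length(sy)) {
        sii <- as.matrix(expand.grid(row = sy, col = sx))
        Lc[sii] <- 66 + rnorm(nrow(sii), 0, 1)
        Ac[sii] <- 12; Bc[sii] <- 30
        depth[sii] <- as.integer(D)
      }
    }
    # partial occlusion: a leaf-sized ellipse in front of the fruit,
    # entering from one side until it covers the requested fraction
    if (f$occlusionFraction > 0) {
      fmask <- matrix(FALSE, H, W); fmask[ii] <- TRUE
      oHalfW <- halfW * runif(1, 0.8, 1.1)
      oHalfH <- halfH * runif(1, 0.8, 1.1)
      dir <- switch(f$occSide, left = c(-1, 0), right = c(1, 0),
                    bottom = c(0, 1))
      lo <- 0; hi <- (halfW + oHalfW) * abs(dir[1]) +
        (halfH + oHalfH) * abs(dir[2])
      opx <- NULL
      for (it in 1:25) {
        mid <- (lo + hi) / 2
        opx <- .ellipsePixels(H, W, f$u + dir[1] * mid, f$v + dir[2] * mid,
                              oHalfW, oHalfH, 0)
        cov <- if (is.null(opx)) 0 else
          sum(fmask[cbind(opx[, 1], opx[, 2])]) / nrow(px)
        if (cov > f$occlusionFraction) lo <- mid else hi <- mid
      }
      if (!is.null(opx)) {
        oii <- cbind(opx[, 1], opx[, 2])
        Lc[oii] <- runif(1, 26, 40); Ac[oii] <- runif(1, -48, -32)
        Bc[oii] <- runif(1, 12, 30)
        depth[oii] <- as.integer(D - 150L)
      }
    }
    truth <- rbind(truth, data.frame(
      fruitId = f$fruitId, x0 = bb[["x0"]], y0 = bb[["y0"]],
      x1 = bb[["x1"]], y1 = bb[["y1"]],
      trueLengthMm = f$trueLengthMm, trueWidthMm = f$trueWidthMm,
      distanceMm = D, occlusionFraction = f$occlusionFraction,
      occluded = f$occlusionFraction > 0))
  }
  rgb <- .fromCielab(array(c(Lc, Ac, Bc), c(H, W, 3L)))
  if (!is.null(depthIntr)) {
    depthOut <- .renderDepthCamera(spec, depthIntr,
                                   if (is.null(ext)) extrinsics() else ext)
    frame <- rgbdFrame(rgb, depthOut, registered = FALSE,
                       frameId = sprintf("scene-%09d", spec$renderSeed))
  } else {
    frame <- rgbdFrame(rgb, depth, registered = TRUE,
                       frameId = sprintf("scene-%09d", spec$renderSeed))
  }
  # depth degradation: truncated Gaussian noise, integer mm, dropout
  if (p$depthNoiseSd > 0 || p$dropoutFraction > 0) {
    d <- frame@depth
    valid <- which(d > 0L)
    if (p$depthNoiseSd > 0) {
      e <- rnorm(length(valid), 0, p$depthNoiseSd)
      s3 <- 3 * p$depthNoiseSd
      e <- pmin(pmax(e, -s3), s3)
      d[valid] <- pmax(1L, as.integer(round(d[valid] + e)))
    }
    if (p$dropoutFraction > 0) {
      drop <- sample(valid, round(p$dropoutFraction * length(valid)))
      d[drop] <- 0L
    }
    frame@depth <- d
  }
  list(frame = frame,
       truth = if (is.null(truth)) data.frame(fruitId = integer(0)) else truth)
}

# depth raster seen by a separate depth camera (translation offset from
# the RGB camera); background plane plus per-fruit ellipses
.renderDepthCamera <- function(spec, depthIntr, ext) {
  intr <- spec$intr
  p <- spec$params
  Hd <- depthIntr@resolution[2]; Wd <- depthIntr@resolution[1]
  pd <- depthIntr@pixelPitch * 1e-3
  depth <- matrix(as.integer(p$backgroundDepthMm), Hd, Wd)
  # world -> depth camera: P_d = R^T (P_rgb - t)
  Rt <- t(ext@rotation); tv <- ext@translation
  fr <- spec$fruits
  for (i in seq_len(nrow(fr))) {
    f <- fr[i, ]
    P <- Rt %*% (c(f$centerXmm, f$centerYmm, f$distanceMm) - tv)
    if (P[3] <= 0) next
    u <- P[1] * depthIntr@focalX / (pd * P[3]) + depthIntr@principalPoint[1]
    v <- P[2] * depthIntr@focalY / (pd * P[3]) + depthIntr@principalPoint[2]
    halfH <- (f$trueLengthMm / 2) * depthIntr@focalY / (P[3] * pd)
    halfW <- (f$trueWidthMm / 2) * depthIntr@focalX / (P[3] * pd)
    px <- .ellipsePixels(Hd, Wd, u, v, halfW, halfH, f$tilt)
    if (!is.null(px))
      depth[cbind(px[, 1], px[, 2])] <- as.integer(round(P[3]))
  }
  depth
}

#' Synthetic training snips for the cascade detector
#'
#' Snips are cropped from miniature scenes produced by the same
#' renderer as the full test imagery, so the training domain matches
#' detection-time content exactly. Positives are windows centred on a
#' rendered fruit whose extent is jittered around 0.7-0.9 of the
#' window (stalk and surrounding clutter included); negatives cycle
#' through fruit-free canopy (foliage clutter, branches, graded
#' background) and hard negatives showing off-centre or off-scale
#' fruit, which teach the cascade to fire only on centred whole fruit.
#' Grayscale, `window` x `window`.
#'
#' @param n snips to generate.
#' @param type "pos" or "neg".
#' @param seed integer seed.
#' @param window snip side, pixels.
#' @return List of numeric matrices in [0, 1].
#' @export
sampleSnips <- function(n, type = c("pos", "neg"), seed = 1L, window = 48L) {
  type <- match.arg(type)
  set.seed(seed)
  side <- window * 2L
  intr <- syntheticIntrinsics(c(side, side))
  pitch <- intr@pixelPitch * 1e-3
  mkFruit <- function(halfH, u, v) {
    Lmm <- runif(1, 60, 160)
    Wmm <- Lmm * runif(1, 0.75, 0.85)
    D <- (Lmm / 2) * intr@focalY / (halfH * pitch)
    data.frame(
      fruitId = 1L, u = u, v = v,
      centerXmm = (u - intr@principalPoint[1]) * pitch * D / intr@focalX,
      centerYmm = (v - intr@principalPoint[2]) * pitch * D / intr@focalY,
      trueLengthMm = Lmm, trueWidthMm = Wmm, distanceMm = round(D),
      tilt = runif(1, -0.15, 0.15), occlusionFraction = 0,
      occSide = "left", labA = runif(1, -15, 15), labB = runif(1, 0, 25),
      labL = runif(1, 72, 84))
  }
  lapply(seq_len(n), function(i) {
    p <- sceneParams(nFruit = 0L, nLeaves = sample(4:10, 1),
                     nBranches = sample(1:3, 1))
    fruits <- data.frame(fruitId = integer(0))
    if (type == "pos") {
      fruits <- mkFruit(runif(1, 16, 21),
                        side / 2 + runif(1, -2, 2),
                        side / 2 + runif(1, -2, 2))
    } else if (i %% 4L == 3L) {
      # hard negative: fruit present but off-centre or off-scale
      if (i %% 2L == 1L) {
        ang <- runif(1, 0, 2 * pi)
        d <- window * runif(1, 0.45, 0.8)
        fruits <- mkFruit(runif(1, 16, 21),
                          side / 2 + cos(ang) * d, side / 2 + sin(ang) * d)
      } else {
        fruits <- mkFruit(runif(1, 34, 46),
                          side / 2 + runif(1, -4, 4),
                          side / 2 + runif(1, -4, 4))
      }
    }
    spec <- list(params = p, intr = intr, fruits = fruits,
                 renderSeed = sample.int(2^30, 1))
    g <- toGray(suppressWarnings(renderScene(spec))$frame@rgb)
    if (type == "pos") {
      r0 <- round(side / 2 - window / 2)
      g[(r0 + 1L):(r0 + window), (r0 + 1L):(r0 + window)]
    } else {
      r0 <- sample.int(side - window, 1); c0 <- sample.int(side - window, 1)
      g[(r0 + 1L):(r0 + window), (c0 + 1L):(c0 + window)]
    }
  })
}
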