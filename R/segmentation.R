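# Pixel-level background removal inside expanded detection boxes and the
# 1D run-length stalk filter.
#
# Stage order within a candidate snip (per the workflow): Otsu on L* ->
# fixed a*/b* chroma gate -> area opening (< minArea removed) -> hole
# filling (< minArea filled) -> stalk filter (rows then columns) ->
# radius-1 disk dilation.

#' Segmentation configuration
#'
#' Defaults are the published operating values: detection boxes doubled,
#' chroma kept inside -25 <= a* <= 25 and -20 <= b* <= 35 (inclusive),
#' connected components under 300 px removed and holes under 300 px
#' filled, stalk run-length threshold w = 8 px (about 14 mm at 2 m),
#' 1 px disk dilation to restore the filtered fruit tip.
#'
#' @param boxExpandFactor detection-box expansion factor.
#' @param aRange,bRange inclusive a*/b* chroma bounds.
#' @param minArea area opening / hole filling threshold, pixels.
#' @param stalkW run-length threshold w, pixels.
#' @param dilationRadius compensation dilation radius, pixels.
#' @return Named list of settings.
#' @export
segmentationConfig <- function(boxExpandFactor = 2, aRange = c(-25, 25),
                               bRange = c(-20, 35), minArea = 300L,
                               stalkW = 8L, dilationRadius = 1L) {
  stopifnot(aRange[1] <= aRange[2], bRange[1] <= bRange[2],
            minArea > 0, stalkW >= 1)
  list(boxExpandFactor = boxExpandFactor, aRange = aRange, bRange = bRange,
       minArea = as.integer(minArea), stalkW = as.integer(stalkW),
       dilationRadius = as.integer(dilationRadius))
}

#' Convert an sRGB snip to CIE L*a*b*
#'
#' Standard sRGB (D65) to CIELAB conversion; L* on [0, 100], a*/b*
#' signed. The published chroma thresholds are stated on this scale.
#'
#' @param rgb rows x cols x 3 numeric array in [0, 1].
#' @return rows x cols x 3 array with channels L*, a*, b*.
#' @export
toCielab <- function(rgb) {
  d <- dim(rgb)
  m <- matrix(rgb, ncol = 3L)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, d)
}

# inverse, for the synthetic renderer
.fromCielab <- function(lab) {
  d <- dim(lab)
  m <- matrix(lab, ncol = 3L)
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  array(rgb, d)
}

#' Otsu binarization on a 256-bin histogram
#'
#' Finds the threshold maximizing between-class variance (equivalently
#' minimizing intra-class variance) over a 256-bin quantization of the
#' channel on `range`. Ties are broken toward the lowest threshold. The
#' returned mask is the bright class (fruit reflect more light than
#' foliage under night LED illumination).
#'
#' @param channel numeric matrix (e.g. the L* plane).
#' @param range quantization range; defaults to the L* scale [0, 100].
#' @param nbins histogram bins.
#' @return List with `threshold` (channel units; NA when degenerate),
#'   `mask` (logical matrix, bright class) and `degenerate` flag
#'   (constant channel).
#' @export
otsuBinarize <- function(channel, range = c(0, 100), nbins = 256L) {
  v <- pmin(pmax(as.numeric(channel), range[1]), range[2])
  bw <- (range[2] - range[1]) / nbins
  bin <- pmin(floor((v - range[1]) / bw), nbins - 1L)  # 0-based bins
  counts <- tabulate(bin + 1L, nbins)
  if (sum(counts > 0L) < 2L) {
    return(list(threshold = NA_real_,
                mask = matrix(FALSE, nrow(channel), ncol(channel)),
                degenerate = TRUE))
  }
  p <- counts / sum(counts)
  mids <- range[1] + (seq_len(nbins) - 0.5) * bw
  w0 <- cumsum(p)[-nbins]
  mu0 <- cumsum(p * mids)[-nbins]
  muT <- sum(p * mids)
  w1 <- 1 - w0
  sigmaB <- (muT * w0 - mu0)^2 / (w0 * w1)
  sigmaB[!is.finite(sigmaB)] <- -Inf
  k <- which.max(sigmaB)                       # which.max takes first tie
  thr <- range[1] + k * bw                     # upper edge of class-0 bins
  list(threshold = thr, mask = matrix(channel > thr, nrow(channel)),
       degenerate = FALSE)
}

#' Fixed chroma gate on a* and b*
#'
#' Clears mask pixels whose chroma falls outside the inclusive bounds
#' (both conditions must hold): remaining bright leaves and branches are
#' removed by colour, keeping the fruit.
#'
#' @param lab rows x cols x 3 L*a*b* array (see [toCielab()]).
#' @param mask logical matrix aligned to `lab`.
#' @param config see [segmentationConfig()].
#' @return Filtered logical mask (only clears pixels, never adds).
#' @export
chromaFilter <- function(lab, mask, config = segmentationConfig()) {
  a <- lab[, , 2]; b <- lab[, , 3]
  mask & a >= config$aRange[1] & a <= config$aRange[2] &
    b >= config$bRange[1] & b <= config$bRange[2]
}

#' Label connected components
#'
#' 8-connectivity for foreground (the package default) is obtained from
#' 4-connected labelling followed by union of labels adjacent across
#' diagonals; 4-connectivity is the dual used for background holes.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of dense labels (0 = background).
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(lab), nrow(mask))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # label pairs adjacent across the two diagonal directions
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]    # up-right
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    n <- max(lab)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(pairs))) {
      ri <- find(pairs[r, 1]); rj <- find(pairs[r, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    dense <- match(roots, sort(unique(roots)))
    lab[lab > 0L] <- dense[lab[lab > 0L]]
  }
  lab
}

#' Area opening and hole filling
#'
#' Removes foreground components (8-connected) with area below
#' `minArea` and fills enclosed background holes (4-connected, not
#' touching the raster border) with area below `minArea`. The stated
#' pixel-count criterion is applied directly rather than via a
#' structuring element.
#'
#' @param mask logical matrix.
#' @param minArea strict threshold: areas `< minArea` are removed/filled.
#' @return Cleaned logical mask.
#' @export
morphClean <- function(mask, minArea = 300L) {
  lab <- labelComponents(mask, 8L)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    mask <- matrix(lab > 0L & areas[pmax(lab, 1L)] >= minArea, nrow(mask))
  }
  # holes: background components not touching the border
  bg <- !mask
  labBg <- labelComponents(bg, 4L)
  if (max(labBg) > 0L) {
    border <- unique(c(labBg[1, ], labBg[nrow(labBg), ],
                       labBg[, 1], labBg[, ncol(labBg)]))
    areas <- tabulate(labBg[labBg > 0L])
    fill <- setdiff(which(areas < minArea & areas > 0L), border)
    if (length(fill) > 0L) mask[labBg %in% fill] <- TRUE
  }
  mask
}

#' 1D run-length filter
#'
#' Zeroes every maximal run of non-zero values shorter than `w`; runs of
#' length `>= w` are untouched. Line ends act as zero delimiters, so a
#' short run touching the border is removed. Idempotent.
#'
#' @param values numeric/logical vector (a raster line).
#' @param w minimum surviving run length, pixels.
#' @return Filtered numeric vector (0/original values).
#' @export
runFilterLine <- function(values, w) {
  stopifnot(w >= 1)
  v <- as.numeric(values)
  r <- rle(v != 0)
  kill <- r$values & r$lengths < w
  if (any(kill)) {
    r$values <- kill
    v[inverse.rle(r)] <- 0
  }
  v
}

#' Remove pendulous stalks with the line filter
#'
#' Applies [runFilterLine()] to every row (removing thin vertical
#' stalks, which hang under the fruit's weight), then to every column of
#' the result (removing thin horizontal attachments), then dilates by a
#' radius-1 disk to restore the fruit tip truncated by the filter.
#'
#' @param mask logical matrix.
#' @param config see [segmentationConfig()]; uses `stalkW` and
#'   `dilationRadius`.
#' @return Filtered logical mask.
#' @export
removeStalks <- function(mask, config = segmentationConfig()) {
  w <- config$stalkW
  m <- t(apply(mask, 1, runFilterLine, w = w))
  m <- apply(m, 2, runFilterLine, w = w)
  m <- matrix(m != 0, nrow(mask))
  if (config$dilationRadius >= 1L) m <- .dilateDisk(m, config$dilationRadius)
  m
}

# binary dilation by a Euclidean disk of the given radius
.dilateDisk <- function(mask, radius = 1L) {
  k <- 2L * radius + 1L
  off <- seq_len(k) - radius - 1L
  kern <- outer(off, off, function(i, j) (i^2 + j^2) <= radius^2) * 1
  out <- EBImage::dilate(EBImage::Image(mask * 1), kern)
  matrix(as.numeric(out) > 0, nrow(mask))
}

#' Segment one expanded candidate snip
#'
#' Runs the full per-candidate chain: CIELAB conversion, Otsu on L*,
#' chroma gate, area opening/hole filling, stalk filter and dilation.
#' Per-stage foreground pixel counts are recorded for provenance.
#'
#' @param snip rows x cols x 3 sRGB array in [0, 1].
#' @param config see [segmentationConfig()].
#' @return List: `mask` (logical), `threshold` (Otsu L* threshold),
#'   `stagePixels` (named counts), `reason` (`NULL`, or
#'   "otsu-degenerate" / "chroma-empty" when the chain empties).
#' @export
segmentCandidate <- function(snip, config = segmentationConfig()) {
  lab <- toCielab(snip)
  ot <- otsuBinarize(lab[, , 1])
  if (ot$degenerate)
    return(list(mask = ot$mask, threshold = NA_real_,
                stagePixels = c(otsu = 0L), reason = "otsu-degenerate"))
  m1 <- ot$mask
  m2 <- chromaFilter(lab, m1, config)
  if (!any(m2))
    return(list(mask = m2, threshold = ot$threshold,
                stagePixels = c(otsu = sum(m1), chroma = 0L),
                reason = "chroma-empty"))
  m3 <- morphClean(m2, config$minArea)
  m4 <- removeStalks(m3, config)
  list(mask = m4, threshold = ot$threshold,
       stagePixels = c(otsu = sum(m1), chroma = sum(m2),
                       morph = sum(m3), stalk = sum(m4)),
       reason = if (!any(m4)) "area-low" else NULL)
}
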