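# Axis-aligned boxes: 0-based, half-open [x0, x1) x [y0, y1).

.box <- function(x0, y0, x1, y1) c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)

.boxWidth <- function(b) unname(b["x1"] - b["x0"])
.boxHeight <- function(b) unname(b["y1"] - b["y0"])

.clipBox <- function(b, width, height) {
  .box(max(0, b[["x0"]]), max(0, b[["y0"]]),
       min(width, b[["x1"]]), min(height, b[["y1"]]))
}

.boxIoU <- function(a, b) {
  ix <- max(0, min(a[["x1"]], b[["x1"]]) - max(a[["x0"]], b[["x0"]]))
  iy <- max(0, min(a[["y1"]], b[["y1"]]) - max(a[["y0"]], b[["y0"]]))
  inter <- ix * iy
  if (inter == 0) return(0)
  areaA <- (a[["x1"]] - a[["x0"]]) * (a[["y1"]] - a[["y0"]])
  areaB <- (b[["x1"]] - b[["x0"]]) * (b[["y1"]] - b[["y0"]])
  inter / (areaA + areaB - inter)
}

# vectorized IoU between rows of two box data.frames / matrices
.boxIoUMat <- function(A, B) {
  A <- as.matrix(A[, c("x0", "y0", "x1", "y1"), drop = FALSE])
  B <- as.matrix(B[, c("x0", "y0", "x1", "y1"), drop = FALSE])
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  for (i in seq_len(n)) {
    ix <- pmax(0, pmin(A[i, 3], B[, 3]) - pmax(A[i, 1], B[, 1]))
    iy <- pmax(0, pmin(A[i, 4], B[, 4]) - pmax(A[i, 2], B[, 2]))
    inter <- ix * iy
    areaA <- (A[i, 3] - A[i, 1]) * (A[i, 4] - A[i, 2])
    out[i, ] <- inter / (areaA + areaB - inter)
  }
  out
}

# minimal bounding box of a logical mask, 0-based half-open; NULL if empty
.maskBBox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  .box(min(idx[, 2]) - 1L, min(idx[, 1]) - 1L, max(idx[, 2]), max(idx[, 1]))
}

#' Expand a bounding box about its centre
#'
#' Scales width and height by `factor` about the box centre, then clips
#' to the raster bounds. Used to double the detector's output box so the
#' expanded snip is guaranteed to cover the entire fruit.
#'
#' @param box numeric named vector `c(x0, y0, x1, y1)`, 0-based half-open.
#' @param factor scale factor, >= 1.
#' @param bounds integer(2) raster size `c(width, height)` in pixels.
#' @return Expanded, clipped box in the same format.
#' @examples
#' expandBox(c(x0 = 10, y0 = 10, x1 = 30, y1 = 40), 2, c(200, 200))
#' @export
expandBox <- function(box, factor = 2, bounds) {
  stopifnot(factor >= 1)
  cx <- (box[["x0"]] + box[["x1"]]) / 2
  cy <- (box[["y0"]] + box[["y1"]]) / 2
  w <- round((box[["x1"]] - box[["x0"]]) * factor)
  h <- round((box[["y1"]] - box[["y0"]]) * factor)
  x0 <- round(cx - w / 2); y0 <- round(cy - h / 2)
  .clipBox(.box(x0, y0, x0 + w, y0 + h), bounds[1], bounds[2])
}
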