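# Agreement metrics between machine-vision measurements and reference
# dimensions (synthetic ground truth or manual calipers).

.agreementMetrics <- function(est, ref) {
  res <- est - ref
  n <- length(res)
  if (n == 0L)
    return(list(n = 0L, rmse = NA_real_, bias = NA_real_,
                rmseBc = NA_real_, r2 = NA_real_))
  bias <- mean(res)
  rmse <- sqrt(mean(res^2))
  rmseBc <- sqrt(mean((res - bias)^2))   # so rmse^2 = bias^2 + rmseBc^2
  r2 <- if (n >= 3L && stats::sd(est) > 0 && stats::sd(ref) > 0)
    stats::cor(est, ref)^2 else NA_real_
  list(n = n, rmse = rmse, bias = bias, rmseBc = rmseBc, r2 = r2)
}

#' Evaluate fruit measurements against a reference
#'
#' Matches measurements to reference records either by a shared
#' `fruitId` column or, failing that, by bounding-box overlap (greedy
#' one-to-one, IoU above `iouMin`, within the same `frameId` when
#' present). Reports RMSE, bias, bias-corrected RMSE (residual spread
#' after removing the mean error, so RMSE^2 = bias^2 + RMSE-bc^2) and
#' R^2 (squared Pearson correlation) for length and width, per-fruit
#' residuals, and detection precision — the fraction of accepted
#' measurements that correspond to an un-occluded reference fruit.
#' Width residuals are taken against the closer of manual width and
#' thickness ([widthReference()]) when the reference supplies
#' `trueThicknessMm`.
#'
#' @param measurements data.frame with `lengthMm`, `widthMm` and either
#'   `fruitId` or box columns `x0, y0, x1, y1` (plus optional `frameId`).
#' @param truth reference data.frame with `trueLengthMm`, `trueWidthMm`,
#'   optional `trueThicknessMm`, `occluded`, and matching id/box columns.
#' @param iouMin minimum IoU for a box match.
#' @return List: `nMatched`, `precision`, `length` and `width` metric
#'   lists (n, rmse, bias, rmseBc, r2), `residuals` data.frame, and
#'   `empty` flag when nothing matched.
#' @export
evaluateMeasurements <- function(measurements, truth, iouMin = 0.5) {
  m <- as.data.frame(measurements)
  tr <- as.data.frame(truth)
  if (!"occluded" %in% names(tr)) tr$occluded <- FALSE
  nAccepted <- nrow(m)
  if (nAccepted == 0L || nrow(tr) == 0L)
    return(list(empty = TRUE, nMatched = 0L, precision = NA_real_,
                length = .agreementMetrics(numeric(0), numeric(0)),
                width = .agreementMetrics(numeric(0), numeric(0)),
                residuals = data.frame()))
  if ("fruitId" %in% names(m) && "fruitId" %in% names(tr)) {
    pairs <- cbind(mi = seq_len(nrow(m)),
                   ti = match(m$fruitId, tr$fruitId))
    pairs <- pairs[!is.na(pairs[, 2]), , drop = FALSE]
  } else {
    frames <- if ("frameId" %in% names(m) && "frameId" %in% names(tr))
      intersect(unique(m$frameId), unique(tr$frameId)) else NA
    pairs <- NULL
    for (fid in frames) {
      mi <- if (is.na(fid[1])) seq_len(nrow(m)) else which(m$frameId == fid)
      ti <- if (is.na(fid[1])) seq_len(nrow(tr)) else which(tr$frameId == fid)
      if (length(mi) == 0L || length(ti) == 0L) next
      iou <- .boxIoUMat(m[mi, ], tr[ti, ])
      while (TRUE) {
        best <- which(iou == max(iou), arr.ind = TRUE)[1, ]
        if (iou[best[1], best[2]] < iouMin) break
        pairs <- rbind(pairs, c(mi = mi[best[1]], ti = ti[best[2]]))
        iou[best[1], ] <- -1; iou[, best[2]] <- -1
      }
    }
  }
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(list(empty = TRUE, nMatched = 0L, precision = 0,
                length = .agreementMetrics(numeric(0), numeric(0)),
                width = .agreementMetrics(numeric(0), numeric(0)),
                residuals = data.frame()))
  mm <- m[pairs[, 1], , drop = FALSE]
  tt <- tr[pairs[, 2], , drop = FALSE]
  widthRef <- if ("trueThicknessMm" %in% names(tt))
    widthReference(tt$trueWidthMm, tt$trueThicknessMm, mm$widthMm)
  else tt$trueWidthMm
  residuals <- data.frame(
    fruitId = if ("fruitId" %in% names(tt)) tt$fruitId else pairs[, 2],
    lengthResid = mm$lengthMm - tt$trueLengthMm,
    widthResid = mm$widthMm - widthRef,
    occluded = tt$occluded)
  trueAccept <- sum(!tt$occluded)
  list(empty = FALSE, nMatched = nrow(pairs),
       precision = trueAccept / nAccepted,
       length = .agreementMetrics(mm$lengthMm, tt$trueLengthMm),
       width = .agreementMetrics(mm$widthMm, widthRef),
       residuals = residuals)
}
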