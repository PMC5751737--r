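# Allometric mass estimation, the width-matching evaluation rule and the
# sample-size calculator.
#
# The pipeline works in millimetres; allometric relations are stated
# with dimensions in centimetres and mass in grams, so these functions
# take centimetres (the CLI converts).

#' Mango mass from length, width and thickness
#'
#' M = k L W T with dimensions in centimetres and mass in grams; the
#' coefficient k is stable across growing conditions at about 0.5
#' (0.49-0.51).
#'
#' @param L,W,T lineal dimensions, centimetres.
#' @param k allometric coefficient.
#' @return Mass in grams.
#' @examples
#' massLWT(10, 8, 7)  # 280 g
#' @export
massLWT <- function(L, W, T = NULL, k = 0.5) {
  if (is.null(T) || anyNA(T))
    stop("thickness T is required; use massLWAvg() or massLW2() without it")
  k * L * W * T
}

#' Mango mass from length and the width/thickness mean
#'
#' The simplified relation M = k L ((W + T) / 2)^2, symmetric in W and
#' T; collapses to k L W^2 when W = T.
#'
#' @inheritParams massLWT
#' @return Mass in grams.
#' @export
massLWAvg <- function(L, W, T = NULL, k = 0.5) {
  if (is.null(T) || anyNA(T)) stop("thickness T is required")
  k * L * ((W + T) / 2)^2
}

#' Mango mass from length and width only
#'
#' The single-view relation M = 0.42 L W^2 (cm in, g out), usable when
#' only the imaged width is available.
#'
#' @param L,W length and width, centimetres.
#' @return Mass in grams.
#' @examples
#' massLW2(10.1, 8.1)  # ~278 g for the average assessed fruit
#' @export
massLW2 <- function(L, W) {
  stopifnot(all(L >= 0), all(W >= 0))
  0.42 * L * W^2
}

#' Reference width for evaluating a single-view width estimate
#'
#' A fruit's imaged width ranges from its true width W to its thickness
#' T depending on orientation, so a machine-vision width estimate is
#' compared against whichever of the manually assessed W and T is
#' closer. Ties resolve to W.
#'
#' @param wManual,tManual manual caliper width and thickness, mm.
#' @param widthMV machine-vision width estimate, mm.
#' @return The closer of `wManual` and `tManual` (mm).
#' @examples
#' widthReference(81, 73, 79)  # 81
#' @export
widthReference <- function(wManual, tManual, widthMV) {
  stopifnot(all(wManual > 0), all(tManual > 0), all(widthMV > 0))
  ifelse(abs(widthMV - wManual) <= abs(widthMV - tManual), wManual, tManual)
}

#' Sample size for estimating mean fruit size
#'
#' n = (1.96 SD / e)^2: the number of fruit to sample so the mean is
#' known to within `e` at 95% confidence, given population standard
#' deviation `SD`. Rounded to the nearest whole fruit by default; a
#' ceiling mode is provided for conservative planning.
#'
#' @param SD population standard deviation, mm.
#' @param e accepted error (e.g. the RMSE of measurement), mm.
#' @param tStat the t statistic (1.96 for 95% confidence).
#' @param mode "nearest" or "ceiling".
#' @return Integer count of fruit.
#' @examples
#' sampleSize(24.4, 4.9)  # 95
#' @export
sampleSize <- function(SD, e, tStat = 1.96, mode = c("nearest", "ceiling")) {
  if (any(e <= 0)) stop("accepted error e must be > 0")
  stopifnot(all(SD > 0))
  mode <- match.arg(mode)
  n <- (tStat * SD / e)^2
  as.integer(if (mode == "nearest") round(n) else ceiling(n))
}
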