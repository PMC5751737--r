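# Moment-based ellipse fitting and the four-criterion completeness gate.

#' Completeness gate configuration
#'
#' The published operating values: component area within [1000, 8000] px
#' (a whole fruit at roughly 2 m), area ratio r > 0.97, eccentricity
#' <= 0.75, and rejection when the bounding-box long side is 4 px or
#' more larger than the fitted major axis (a tell-tale of residual thick
#' stalk ends inflating the apparent length).
#'
#' @param areaMin,areaMax inclusive component-area bounds, pixels.
#' @param rMin area-ratio lower bound (strict: accept when r > rMin).
#' @param eccMax eccentricity upper bound (inclusive: 0.75 passes).
#' @param bboxMajorSlack reject when `longside - major >= bboxMajorSlack`.
#' @return Named list of settings.
#' @export
gateConfig <- function(areaMin = 1000L, areaMax = 8000L, rMin = 0.97,
                       eccMax = 0.75, bboxMajorSlack = 4) {
  stopifnot(areaMin < areaMax, rMin > 0, rMin <= 1, eccMax > 0, eccMax < 1)
  list(areaMin = areaMin, areaMax = areaMax, rMin = rMin,
       eccMax = eccMax, bboxMajorSlack = bboxMajorSlack)
}

#' Area ratio of a component to its fitted ellipse
#'
#' \eqn{r = 4A / (\pi a b)} where A is the component pixel area and a, b
#' the full axis lengths of the fitted ellipse. Near 1 for a whole
#' convex fruit; occlusion or protruding stalks push it away from 1.
#'
#' @param A component area, pixels.
#' @param a,b full axis lengths, pixels (> 0).
#' @return The dimensionless ratio.
#' @examples
#' areaRatio(60, 10, 10)  # 240 / (100 pi)
#' @export
areaRatio <- function(A, a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("axis lengths must be > 0")
  4 * A / (pi * a * b)
}

#' Fit an ellipse to a component by image moments
#'
#' The centroid comes from first moments; axis lengths, orientation and
#' eccentricity from the second central moments — the returned ellipse
#' has the same first and second moments as the pixel set. A per-pixel
#' variance of 1/12 (the pixel's own extent) is added to each axis so
#' that rasterized shapes are recovered without size bias. Axes are full
#' lengths; for a solid ellipse with semi-axes (p, q) the major axis is
#' \eqn{a = 4\sqrt{\lambda_1}} with \eqn{\lambda_1 = p^2/4}.
#'
#' @param mask logical matrix containing a single component (all TRUE
#'   pixels are used).
#' @return An [EllipseFit-class].
#' @export
fitMomentEllipse <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 5L) stop("component has fewer than 5 pixels")
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  mx <- mean(x); my <- mean(y)
  mu20r <- mean((x - mx)^2)
  mu02r <- mean((y - my)^2)
  mu11 <- mean((x - mx) * (y - my))
  # collinearity is judged on the raw moments, before the pixel-extent
  # correction would mask a zero-thickness component
  commonR <- sqrt(((mu20r - mu02r) / 2)^2 + mu11^2)
  if ((mu20r + mu02r) / 2 - commonR <= 1e-9)
    stop("degenerate (collinear) component")
  mu20 <- mu20r + 1 / 12
  mu02 <- mu02r + 1 / 12
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  a <- 4 * sqrt(l1); b <- 4 * sqrt(l2)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  eps <- sqrt(max(0, 1 - (b / a)^2))
  new("EllipseFit", area = n, centroid = c(mx, my),
      major = a, minor = b, orientation = theta,
      eccentricity = eps, areaRatio = areaRatio(n, a, b))
}

#' Four-criterion fruit completeness gate
#'
#' Accepts a component iff (1) its area lies in [areaMin, areaMax],
#' (2) the area ratio exceeds rMin, (3) eccentricity is at most eccMax,
#' and (4) the long side of its axis-aligned bounding box exceeds the
#' fitted major axis by less than `bboxMajorSlack` pixels. The first
#' failed criterion (in that order) is reported as the reason.
#'
#' @param mask logical matrix of the component.
#' @param fit the [EllipseFit-class] produced from `mask`.
#' @param config see [gateConfig()].
#' @return List: `accepted` (logical) and `reason` (`NULL` or one of
#'   "area-low", "area-high", "ratio-low", "ecc-high", "bbox-major").
#' @export
gateComponent <- function(mask, fit, config = gateConfig()) {
  A <- fit@area
  if (A < config$areaMin)
    return(list(accepted = FALSE, reason = "area-low"))
  if (A > config$areaMax)
    return(list(accepted = FALSE, reason = "area-high"))
  if (fit@areaRatio <= config$rMin)
    return(list(accepted = FALSE, reason = "ratio-low"))
  if (fit@eccentricity > config$eccMax)
    return(list(accepted = FALSE, reason = "ecc-high"))
  bb <- .maskBBox(mask)
  longside <- max(.boxWidth(bb), .boxHeight(bb))
  if (longside - fit@major >= config$bboxMajorSlack)
    return(list(accepted = FALSE, reason = "bbox-major"))
  list(accepted = TRUE, reason = NULL)
}
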