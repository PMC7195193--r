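#' Arc length of a traced polyline via cubic-spline quadrature
#'
#' Fits a natural cubic spline through the ordered points (chord-length
#' parameterization) and integrates its speed numerically, refining the
#' sampling until the length converges to a relative tolerance of 1e-4.
#' Two points fall back to the straight-line distance.
#'
#' @param points n x 2 (y, x) ordered points, um.
#' @return arc length in um.
#' @export
arcLength <- function(points) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 2)
  if (nrow(points) == 2)
    return(sqrt(sum((points[2, ] - points[1, ])^2)))
  s <- chordLengths(points)
  fy <- stats::splinefun(s, points[, 1], method = "natural")
  fx <- stats::splinefun(s, points[, 2], method = "natural")
  len <- function(n) {
    t <- seq(0, s[length(s)], length.out = n)
    sum(sqrt(diff(fy(t))^2 + diff(fx(t))^2))
  }
  n <- 64 * nrow(points)
  prev <- len(n)
  repeat {
    n <- n * 2
    cur <- len(n)
    if (abs(cur - prev) <= 1e-4 * cur || n > 1e6) break
    prev <- cur
  }
  cur
}

#' Expansion factor as a post/pre length ratio
#'
#' @param pre,post n x 2 point traces (um, absolute units) of the same
#'   physical feature before and after expansion, or scalars giving the
#'   lengths directly.
#' @return post length / pre length.
#' @export
expansionFactorRatio <- function(pre, post) {
  lp <- if (is.matrix(pre) || is.data.frame(pre)) arcLength(pre) else pre
  lq <- if (is.matrix(post) || is.data.frame(post)) arcLength(post) else post
  stopifnot(lp > 0, lq > 0)
  lq / lp
}

#' Normalized expansion factor (nExF)
#'
#' Worm expansion factor divided by the expansion factor of the embedding
#' hydrogel; removes sample-to-sample variation in gel expansion, so a
#' fully homogenized specimen scores ~1. Values above 1.05 are physically
#' implausible (tracing noise aside) and are flagged with a warning.
#'
#' @param worm worm linear expansion factor (> 0).
#' @param gel hydrogel linear expansion factor (> 0).
#' @return nExF = worm / gel.
#' @export
normalizedExpansion <- function(worm, gel) {
  if (gel <= 0) stop("gel expansion factor must be > 0")
  stopifnot(worm > 0)
  r <- worm / gel
  if (r > 1.05)
    warning(sprintf("nExF = %.3f exceeds 1.05; check the traces", r))
  r
}
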