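#' LineProfile: an ordered intensity trace along a curve
#'
#' @slot intensity ordered intensity samples.
#' @slot spacingUm sample spacing in biological um.
#' @slot source free-text annotation (animal, segment).
#' @exportClass LineProfile
setClass("LineProfile",
  representation(intensity = "numeric", spacingUm = "numeric",
                 source = "character"),
  validity = function(object) {
    if (length(object@intensity) < 5) return("profile needs >= 5 samples")
    if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
      return("intensities must be finite and >= 0")
    TRUE
  })

#' PeakReport: prominence-filtered peaks of a line profile
#'
#' @slot peaks sample indices of retained peaks (1-based).
#' @slot prominences topographic prominence of each retained peak.
#' @slot count number of retained peaks.
#' @slot threshold prominence threshold used.
#' @exportClass PeakReport
setClass("PeakReport",
  representation(peaks = "integer", prominences = "numeric",
                 count = "integer", threshold = "numeric"))

setMethod("show", "LineProfile", function(object) {
  cat(sprintf("LineProfile: %d samples at %.3g um%s\n",
              length(object@intensity), object@spacingUm,
              if (nzchar(object@source)) paste0(" (", object@source, ")") else ""))
})

setMethod("show", "PeakReport", function(object) {
  cat(sprintf("PeakReport: %d peaks (prominence >= %.3g)\n",
              object@count, object@threshold))
})

#' Construct a LineProfile
#' @param intensity numeric samples (>= 5, finite, non-negative).
#' @param spacingUm sample spacing in biological um.
#' @param source annotation.
#' @return A \linkS4class{LineProfile}.
#' @export
lineProfile <- function(intensity, spacingUm = 1, source = "") {
  new("LineProfile", intensity = as.numeric(intensity),
      spacingUm = spacingUm, source = source)
}

#' Extract a line-intensity profile along a polyline
#'
#' Samples the image at one-pixel arc-length steps along the polyline,
#' averaging \code{width} bilinear samples taken perpendicular to the
#' local direction at each step.
#'
#' @param img 2D \linkS4class{ImageField}.
#' @param polyline n x 2 (y, x) points in pixels, ordered.
#' @param width odd perpendicular averaging width in pixels.
#' @param source annotation copied into the profile.
#' @return A \linkS4class{LineProfile}; spacing is one pixel in biological
#'   um.
#' @export
extractProfile <- function(img, polyline, width = 1, source = "") {
  stopifnot(width >= 1, width %% 2 == 1)
  A <- imgData(img)
  if (any(polyline[, 1] < 0) || any(polyline[, 1] > nrow(A) - 1) ||
      any(polyline[, 2] < 0) || any(polyline[, 2] > ncol(A) - 1))
    stop("polyline outside the image")
  ctr <- resampleCurve(polyline, step = 1)
  n <- nrow(ctr)
  tang <- rbind(ctr[2, ] - ctr[1, ],
                (ctr[-(1:2), , drop = FALSE] - ctr[seq_len(n - 2), , drop = FALSE]) / 2,
                ctr[n, ] - ctr[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- cbind(-tang[, 2], tang[, 1])
  half <- (width - 1) / 2
  acc <- numeric(n)
  for (o in (-half):half) {
    pts <- ctr + o * nrm
    acc <- acc + bilinearSample(A, pts[, 1], pts[, 2])
  }
  lineProfile(acc / width, spacingUm = toBiologicalUnits(1, img), source = source)
}

#' Normalize a profile to [0, 1] and smooth with a 3-sample moving window
#'
#' Linear min-max normalization (a constant profile maps to all zeros —
#' a valid "no punctum" observation) followed by a centred moving average
#' whose window shrinks to 2 samples at the ends (no padding).
#'
#' @param profile a \linkS4class{LineProfile}.
#' @param window moving-average window (odd; default 3).
#' @return A normalized, smoothed \linkS4class{LineProfile}.
#' @export
normalizeSmooth <- function(profile, window = 3) {
  x <- profile@intensity
  rng <- range(x)
  x <- if (diff(rng) == 0) rep(0, length(x)) else (x - rng[1]) / diff(rng)
  half <- (window - 1) / 2
  n <- length(x)
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
  new("LineProfile", intensity = sm, spacingUm = profile@spacingUm,
      source = profile@source)
}

## Plateau-aware local maxima of a numeric vector: runs of equal value
## that are strictly higher than both neighbouring runs. Endpoint runs are
## never peaks. Returns the midpoint index of each plateau.
localMaximaRuns <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  isPeak <- logical(k)
  for (i in 2:(k - 1))
    isPeak[i] <- r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1]
  idx <- which(isPeak)
  as.integer(floor((starts[idx] + ends[idx]) / 2))
}

## Topographic prominence of peaks at indices `peaks` of x: height above
## the higher of the two interval minima, where each interval extends to
## the nearest strictly higher point or to the signal end.
peakProminence <- function(x, peaks) {
  vapply(peaks, function(m) {
    h <- x[m]
    left <- x[seq_len(m)]
    hiL <- which(left > h)
    minL <- min(left[(if (length(hiL)) max(hiL) else 1):m])
    right <- x[m:length(x)]
    hiR <- which(right > h)
    minR <- min(right[1:(if (length(hiR)) min(hiR) else length(right))])
    h - max(minL, minR)
  }, numeric(1))
}

#' Count puncta in a normalized profile by topographic prominence
#'
#' Finds all interior local maxima (plateau-aware: a flat top counts once,
#' at its midpoint), computes the topographic prominence of each — the
#' height of the peak above the higher of the two minima separating it
#' from the nearest higher ground, with the signal ends acting as
#' boundaries — and retains peaks with prominence at or above the
#' threshold. Maxima below the threshold are rejected as noise.
#'
#' @param profile a \linkS4class{LineProfile}, already normalized and
#'   smoothed (see \code{\link{normalizeSmooth}}).
#' @param prominenceThreshold retention threshold on the 0-1 scale
#'   (default 0.01; must lie in (0, 1]).
#' @return A \linkS4class{PeakReport}.
#' @export
countPeaks <- function(profile, prominenceThreshold = 0.01) {
  if (prominenceThreshold <= 0 || prominenceThreshold > 1)
    stop("prominence threshold must be in (0, 1]")
  x <- profile@intensity
  cand <- localMaximaRuns(x)
  prom <- peakProminence(x, cand)
  keep <- prom >= prominenceThreshold
  new("PeakReport", peaks = cand[keep], prominences = prom[keep],
      count = sum(keep), threshold = prominenceThreshold)
}

#' Fold change between paired pre/post peak counts
#'
#' Primary statistic: the slope of the through-origin least-squares fit of
#' post counts against pre counts (the "linear fit" of a paired count
#' scatter). The ratio of summed counts is reported as a secondary
#' statistic.
#'
#' @param preCounts,postCounts equal-length paired count vectors (>= 3).
#' @return list with elements \code{slope} and \code{ratioOfSums}.
#' @export
foldChange <- function(preCounts, postCounts) {
  stopifnot(length(preCounts) == length(postCounts), length(preCounts) >= 3)
  if (all(preCounts == 0)) stop("all pre counts are zero; slope undefined")
  list(slope = sum(preCounts * postCounts) / sum(preCounts^2),
       ratioOfSums = sum(postCounts) / sum(preCounts))
}
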