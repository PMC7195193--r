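#' Crop a square region in biological units
#'
#' Crops a side x side um (biological) axis-aligned square centred on a
#' pixel position — the standardized crop (default 50 um) around the nerve
#' ring or upper body used for staining quantification. Crops reaching
#' outside the image are clipped with a warning.
#'
#' @param img 2D \linkS4class{ImageField}.
#' @param center (y, x) centre in pixels.
#' @param side square side in biological um.
#' @return An \linkS4class{ImageField}.
#' @export
cropRegion <- function(img, center, side = 50) {
  A <- imgData(img)
  px <- pixelSize(img)[1]
  halfPx <- round(side * expansionFactor(img) / px / 2)
  r <- round(center[1]) + (-halfPx):(halfPx - 1) + 1
  c_ <- round(center[2]) + (-halfPx):(halfPx - 1) + 1
  if (any(r < 1) || any(r > nrow(A)) || any(c_ < 1) || any(c_ > ncol(A))) {
    warning("crop clipped to the image bounds")
    r <- r[r >= 1 & r <= nrow(A)]
    c_ <- c_[c_ >= 1 & c_ <= ncol(A)]
  }
  imageField(A[r, c_, drop = FALSE], pixelSize(img), expansionFactor(img),
             channelLabel(img))
}

#' Percentile-ranked signal and background masks
#'
#' Signal mask: pixels at or above the \code{pSignal}-th percentile of the
#' signal crop. Background mask: pixels whose intensity falls inside the
#' \code{pBg} percentile band of the background crop. Ties at a boundary
#' are included, so masks are deterministic on integer-valued images and a
#' uniform crop yields a full signal mask.
#'
#' @param signalCrop,backgroundCrop \linkS4class{ImageField}s.
#' @param pSignal signal percentile in (0, 100).
#' @param pBg background percentile band, length 2, lower < upper.
#' @param rankSmoothPx Gaussian smoothing (pixels) applied to the crops
#'   before percentile ranking (only for selecting mask pixels; means are
#'   still taken over raw intensities). Ranking noisy pixels directly
#'   biases the selected upper tail upward; a light smoothing removes
#'   most of that selection bias. 0 ranks raw pixels.
#' @return list of two \linkS4class{Mask}s: signal, background.
#' @export
percentileMasks <- function(signalCrop, backgroundCrop, pSignal = 98,
                            pBg = c(25, 75), rankSmoothPx = 0) {
  stopifnot(pSignal > 0, pSignal < 100, length(pBg) == 2, pBg[1] < pBg[2])
  sA <- imgData(signalCrop)
  bA <- imgData(backgroundCrop)
  if (rankSmoothPx > 0) {
    sA <- smoothArray(sA, rep(rankSmoothPx, 2))
    bA <- smoothArray(bA, rep(rankSmoothPx, 2))
  }
  thr <- orderStatThreshold(sA, pSignal)
  sig <- sA >= thr
  lo <- orderStatThreshold(bA, pBg[1])
  hi <- orderStatThreshold(bA, pBg[2], upper = TRUE)
  bg <- bA >= lo & bA <= hi
  if (!any(sig) || !any(bg)) stop("empty mask after percentile thresholding")
  list(signal = mask(sig, "signal"), background = mask(bg, "background"))
}

## Order-statistic percentile threshold: the value whose rank just exceeds
## p percent of the pixels (upper = TRUE returns the rank at ceiling).
orderStatThreshold <- function(a, p, upper = FALSE) {
  s <- sort(as.vector(a))
  n <- length(s)
  k <- if (upper) min(n, ceiling(n * p / 100)) else min(n, floor(n * p / 100) + 1)
  s[max(k, 1)]
}

#' Signal-to-background ratio from masked crops
#'
#' The ratio of the mean intensity inside the signal mask to the mean
#' inside the background mask — the standard staining-quality metric for
#' immunohistochemistry comparisons.
#'
#' @param signalCrop,backgroundCrop \linkS4class{ImageField}s.
#' @param masks list(signal, background) from
#'   \code{\link{percentileMasks}}; computed with defaults when missing.
#' @return list (SbrResult): meanSignal, meanBackground, sbr, masks. A
#'   zero background mean yields sbr = Inf with a warning.
#' @export
sbr <- function(signalCrop, backgroundCrop, masks = NULL) {
  if (is.null(masks)) masks <- percentileMasks(signalCrop, backgroundCrop)
  ms <- mean(imgData(signalCrop)[imgData(masks$signal)])
  mb <- mean(imgData(backgroundCrop)[imgData(masks$background)])
  if (mb == 0) {
    warning("zero background mean; SBR is infinite")
    ratio <- Inf
  } else ratio <- ms / mb
  list(meanSignal = ms, meanBackground = mb, sbr = ratio, masks = masks)
}
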