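#' RMS length-measurement-error curve from a deformation result
#'
#' Samples random point pairs inside the foreground mask; per pair, the
#' measurement error is the absolute difference between the pair length
#' after applying the residual field and the original length, in
#' biological micrometres (post lengths are already on the biological
#' scale because the rigid scale was divided out during alignment). Errors
#' are binned by separation length and the RMS per bin reported.
#'
#' Sampling is stratified over bins by default (anchor point uniform over
#' the mask, direction uniform, separation uniform within each bin), so
#' every bin receives comparable statistical weight; uniform endpoint
#' pairs are available with \code{method = "uniform"}.
#'
#' @param result a \linkS4class{DeformationResult}.
#' @param nPairs total point pairs (>= 1000).
#' @param bins bin edges in um (default 1-um bins over 0-100 um).
#' @param seed integer seed (recorded in the output).
#' @param method "stratified" or "uniform".
#' @return data.frame: binCenter, rmsError (um), fractionalError,
#'   nPairsInBin. Bins with fewer than 30 pairs are reported as NA with a
#'   warning. Attribute "seed" records the seed.
#' @export
rmsErrorCurve <- function(result, nPairs = 10000, bins = seq(0, 100, by = 1),
                          seed = 1, method = c("stratified", "uniform")) {
  method <- match.arg(method)
  stopifnot(nPairs >= 1000)
  rng <- localRNG(seed)
  m <- imgData(result@mask)
  nr <- nrow(m); nc <- ncol(m)
  pxUm <- result@pixelSize[1]   # absolute um per pre-frame pixel
  ## biological um per pixel: the field is stored in biological um and the
  ## mask lives on the pre grid (E = 1 for pre images)
  idx <- which(m)
  if (length(idx) == 0) stop("empty foreground mask")
  anchor <- function(n) {
    i <- idx[rng$sampleInt(length(idx), n)]
    cbind((i - 1) %% nr, (i - 1) %/% nr) +
      matrix(rng$runif(2 * n, -0.5, 0.5), n, 2)
  }
  inMask <- function(p) {
    r <- round(p[, 1]); c_ <- round(p[, 2])
    ok <- r >= 0 & r <= nr - 1 & c_ >= 0 & c_ <= nc - 1
    ok[ok] <- m[cbind(r[ok] + 1, c_[ok] + 1)]
    ok
  }
  fieldAt <- function(p)
    cbind(bilinearSample(result@fieldY, p[, 1], p[, 2]),
          bilinearSample(result@fieldX, p[, 1], p[, 2]))

  nBins <- length(bins) - 1
  centers <- (bins[-1] + bins[-length(bins)]) / 2
  errs <- vector("list", nBins)
  if (method == "stratified") {
    perBin <- ceiling(nPairs / nBins)
    for (b in seq_len(nBins)) {
      got <- numeric(0)
      for (round_ in 1:6) {
        if (length(got) >= perBin) break
        n <- perBin * 3L
        p <- anchor(n)
        Lu <- rng$runif(n, bins[b], bins[b + 1])
        ang <- rng$runif(n, 0, 2 * pi)
        q <- p + (Lu / pxUm) * cbind(sin(ang), cos(ang))
        ok <- inMask(q)
        if (!any(ok)) next
        p <- p[ok, , drop = FALSE]; q <- q[ok, , drop = FALSE]
        L0 <- sqrt(rowSums((p - q)^2)) * pxUm
        d1 <- (p - q) * pxUm + fieldAt(p) - fieldAt(q)
        L1 <- sqrt(rowSums(d1^2))
        got <- c(got, abs(L1 - L0))
      }
      errs[[b]] <- got[seq_len(min(length(got), perBin))]
    }
  } else {
    p <- anchor(nPairs * 2L)
    q <- anchor(nPairs * 2L)
    ok <- inMask(p) & inMask(q)
    p <- p[ok, , drop = FALSE]; q <- q[ok, , drop = FALSE]
    L0 <- sqrt(rowSums((p - q)^2)) * pxUm
    d1 <- (p - q) * pxUm + fieldAt(p) - fieldAt(q)
    e <- abs(sqrt(rowSums(d1^2)) - L0)
    bi <- findInterval(L0, bins, rightmost.closed = TRUE)
    for (b in seq_len(nBins)) errs[[b]] <- e[bi == b]
  }
  n_ <- vapply(errs, length, integer(1))
  rms <- vapply(errs, function(e) if (length(e) >= 30) sqrt(mean(e^2)) else NA_real_,
                numeric(1))
  if (anyNA(rms))
    warning(sum(is.na(rms)), " bin(s) had fewer than 30 pairs and are NA")
  out <- data.frame(binCenter = centers, rmsError = rms,
                    fractionalError = rms / centers, nPairsInBin = n_)
  attr(out, "seed") <- seed
  out
}

#' Displacement-magnitude percentiles over a region
#'
#' Summarizes local distortion the way tissue displacement is reported:
#' the 5th and 95th percentiles of the residual displacement magnitude
#' over a region of interest.
#'
#' @param result a \linkS4class{DeformationResult}.
#' @param regionMask a \linkS4class{Mask} congruent with the field
#'   (default: the result's foreground mask).
#' @param probs percentile probabilities.
#' @return named numeric vector of displacement magnitudes (um).
#' @export
displacementPercentiles <- function(result, regionMask = NULL,
                                    probs = c(0.05, 0.95)) {
  if (is.null(regionMask)) regionMask <- result@mask
  m <- imgData(regionMask)
  if (!any(m)) stop("empty region mask")
  mag <- sqrt(result@fieldY^2 + result@fieldX^2)[m]
  stats::quantile(mag, probs)
}

#' Aggregate RMS error curves across animals
#'
#' @param curves list of data.frames from \code{\link{rmsErrorCurve}}.
#' @return data.frame with per-bin mean and sd of rmsError and
#'   fractionalError.
#' @export
aggregateRmsCurves <- function(curves) {
  stopifnot(length(curves) >= 1)
  rms <- sapply(curves, `[[`, "rmsError")
  fr <- sapply(curves, `[[`, "fractionalError")
  data.frame(binCenter = curves[[1]]$binCenter,
             rmsMean = rowMeans(rms, na.rm = TRUE),
             rmsSd = apply(rms, 1, stats::sd, na.rm = TRUE),
             fracMean = rowMeans(fr, na.rm = TRUE),
             fracSd = apply(fr, 1, stats::sd, na.rm = TRUE))
}

#' Digitally straighten a worm image along its midline
#'
#' Fits a spline through ordered midline control points, resamples it at
#' uniform one-pixel arc-length steps, and samples the image along the
#' normal at each step, producing a straightened strip (the standard
#' "Straighten" operation used to normalize body posture before
#' registration).
#'
#' @param img 2D \linkS4class{ImageField}.
#' @param controlPoints n x 2 (y, x) points in pixels, ordered along the
#'   body (>= 3).
#' @param halfWidth strip half-width in um (absolute).
#' @return An \linkS4class{ImageField} of size
#'   (2 * halfWidth / pixelSize + 1) x (midline arc length in px).
#' @export
straightenImage <- function(img, controlPoints, halfWidth) {
  stopifnot(nrow(controlPoints) >= 3, halfWidth > 0)
  A <- imgData(img)
  if (any(controlPoints[, 1] < 0) || any(controlPoints[, 1] > nrow(A) - 1) ||
      any(controlPoints[, 2] < 0) || any(controlPoints[, 2] > ncol(A) - 1))
    stop("control points outside the image")
  px <- pixelSize(img)[1]
  ctr <- resampleCurve(controlPoints, step = 1)
  n <- nrow(ctr)
  tang <- rbind(ctr[2, ] - ctr[1, ],
                (ctr[-(1:2), , drop = FALSE] - ctr[seq_len(n - 2), , drop = FALSE]) / 2,
                ctr[n, ] - ctr[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  ## normal oriented so that increasing output row tracks increasing
  ## image row for a left-to-right midline
  nrm <- cbind(tang[, 2], -tang[, 1])
  hwPx <- round(halfWidth / px)
  offs <- (-hwPx):hwPx
  if (hwPx >= 2) {
    ## warn about self-intersecting normals: curvature radius below strip width
    curv <- sqrt(rowSums((rbind(tang[-1, , drop = FALSE], tang[n, ]) -
                            tang)^2))
    if (any(curv > 1 / hwPx))
      warning("midline curvature exceeds the strip half-width; normals overlap")
  }
  out <- matrix(0, length(offs), n)
  for (j in seq_along(offs)) {
    pts <- ctr + offs[j] * nrm
    out[j, ] <- bilinearSample(A, pts[, 1], pts[, 2])
  }
  imageField(out, pixelSize(img), expansionFactor(img), channelLabel(img))
}
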