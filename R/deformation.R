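#' Build a ground-truth deformation (similarity + smooth residual field)
#'
#' The residual field is a Gaussian random field built by smoothing
#' white noise on a coarse grid (node spacing ell/2) with a Gaussian kernel
#' of spatial sd ell/2, mean-subtracting, and rescaling so each displacement
#' component has pointwise standard deviation \code{sigmaD}. Its
#' autocorrelation is approximately exp(-r^2/ell^2). Nodes are interpolated
#' bilinearly, so the field is smooth at the scale of ell.
#'
#' @param extentUm (y, x) extent of the pre-expansion domain in um.
#' @param sigmaD per-component displacement sd (um); 0 gives a zero field.
#' @param ell correlation length (um).
#' @param eTrue global linear scale of the post frame.
#' @param theta rigid rotation (radians).
#' @param translation length-2 (y, x) translation in the post frame (um).
#' @param seed integer seed for the white noise.
#' @param projectPoints optional n x 2 (y, x) points (um) defining the
#'   specimen support over which the similarity component is projected
#'   out; default: the full extent.
#' @return A \linkS4class{GroundTruthDeformation}.
#' @export
makeDeformation <- function(extentUm, sigmaD, ell, eTrue = 1, theta = 0,
                            translation = c(0, 0), seed = 1,
                            projectPoints = NULL) {
  h <- ell / 2
  margin <- 2 * ell
  origin <- c(-margin, -margin)
  ny <- ceiling((extentUm[1] + 2 * margin) / h) + 1
  nx <- ceiling((extentUm[2] + 2 * margin) / h) + 1
  if (sigmaD > 0) {
    rng <- localRNG(seed)
    gy <- matrix(rng$rnorm(ny * nx), ny, nx)
    gx <- matrix(rng$rnorm(ny * nx), ny, nx)
    sm <- ell / 2 / h   # kernel sd in node units
    gy <- smoothArray(gy, c(sm, sm))
    gx <- smoothArray(gx, c(sm, sm))
    ## project out the best-fit global similarity (translation + scale +
    ## rotation) over the interior so the residual field is orthogonal to
    ## the rigid transform it composes with -- otherwise the decomposition
    ## into "rigid" and "residual" is not identifiable
    py <- rep(origin[1] + (0:(ny - 1)) * h, nx)
    px_ <- rep(origin[2] + (0:(nx - 1)) * h, each = ny)
    tmpDef <- function(gy, gx) new("GroundTruthDeformation", eTrue = 1,
      theta = 0, translation = c(0, 0), gridY = gy, gridX = gx,
      gridOrigin = origin, gridSpacing = h, sigmaD = sigmaD, ell = ell)
    if (is.null(projectPoints)) {
      keep <- py >= 0 & py <= extentUm[1] & px_ >= 0 & px_ <= extentUm[2]
      sy <- py[keep]; sx <- px_[keep]
      sampleD <- function(gy, gx) cbind(gy[keep], gx[keep])
    } else {
      sy <- projectPoints[, 1]; sx <- projectPoints[, 2]
      sampleD <- function(gy, gx) evalDeformation(tmpDef(gy, gx), projectPoints)
    }
    ## dy = a1 + alpha*y - beta*x ; dx = a2 + beta*y + alpha*x
    Z <- rbind(cbind(1, 0, sy, -sx), cbind(0, 1, sx, sy))
    qrZ <- qr(Z)
    for (it in 1:2) {
      d <- sampleD(gy, gx)
      beta <- qr.coef(qrZ, c(d[, 1], d[, 2]))
      gy <- gy - matrix(beta[1] + beta[3] * py - beta[4] * px_, ny, nx)
      gx <- gx - matrix(beta[2] + beta[4] * py + beta[3] * px_, ny, nx)
      d <- sampleD(gy, gx)
      s0 <- sqrt((stats::var(d[, 1]) + stats::var(d[, 2])) / 2)
      gy <- gy * sigmaD / s0
      gx <- gx * sigmaD / s0
    }
  } else {
    gy <- matrix(0, ny, nx)
    gx <- matrix(0, ny, nx)
  }
  new("GroundTruthDeformation", eTrue = eTrue, theta = theta,
      translation = as.numeric(translation), gridY = gy, gridX = gx,
      gridOrigin = as.numeric(origin), gridSpacing = h,
      sigmaD = sigmaD, ell = ell)
}

#' Evaluate the residual displacement field at points
#'
#' @param def a \linkS4class{GroundTruthDeformation}.
#' @param points n x 2 matrix of (y, x) positions in pre-frame um.
#' @return n x 2 matrix of displacements (um, biological scale).
#' @export
evalDeformation <- function(def, points) {
  points <- rbind(points)
  r <- (points[, 1] - def@gridOrigin[1]) / def@gridSpacing
  c_ <- (points[, 2] - def@gridOrigin[2]) / def@gridSpacing
  cbind(bilinearSample(def@gridY, r, c_), bilinearSample(def@gridX, r, c_))
}

#' Apply the full forward map of a deformation to pre-frame points
#'
#' T(p) = eTrue * R(theta) (p + d(p)) + t; output in post-frame um.
#'
#' @param def a \linkS4class{GroundTruthDeformation}.
#' @param points n x 2 matrix of (y, x) pre-frame positions (um).
#' @return n x 2 matrix of post-frame positions (um).
#' @export
applyDeformation <- function(def, points) {
  points <- rbind(points)
  p <- points + evalDeformation(def, points)
  R <- rotmat2(def@theta)
  q <- def@eTrue * (p %*% t(R))
  sweep(q, 2, def@translation, "+")
}

## Inverse of the forward map: given post-frame points, recover pre-frame
## positions by undoing the similarity then fixed-point iterating
## p <- y - d(p). Converges fast because |grad d| ~ sigmaD/ell << 1.
invertDeformation <- function(def, postPoints, iter = 4L) {
  q <- sweep(rbind(postPoints), 2, def@translation, "-")
  R <- rotmat2(def@theta)
  y <- (q %*% R) / def@eTrue   # R^T q / s
  p <- y
  for (i in seq_len(iter)) p <- y - evalDeformation(def, p)
  p
}

#' Monte-Carlo RMS pair-length error of a known deformation field
#'
#' The independent oracle for the RMS length-measurement-error statistic:
#' samples random point pairs at separation L inside a region, applies the
#' residual field to both endpoints, and returns the root-mean-square of
#' |post-pair-length - L| on the biological scale. The global similarity is
#' irrelevant here because measurement error is defined after dividing
#' post-expansion lengths by the expansion factor.
#'
#' @param def a \linkS4class{GroundTruthDeformation}.
#' @param L separation length (um), scalar or vector (one estimate per L).
#' @param nMc Monte-Carlo pair count per L (>= 1000).
#' @param seed integer seed.
#' @param regionMask optional \linkS4class{Mask} restricting endpoints;
#'   needs \code{maskPixelSize} (um per mask pixel) to place it in the
#'   pre frame. Default: the rectangle covered by the field's grid interior.
#' @param maskPixelSize um per pixel of \code{regionMask}.
#' @return data.frame with columns L and rmsError (um).
#' @export
expectedPairError <- function(def, L, nMc = 10000, seed = 1,
                              regionMask = NULL, maskPixelSize = NULL) {
  stopifnot(all(L > 0), nMc >= 1000)
  rng <- localRNG(seed)
  if (!is.null(regionMask)) {
    stopifnot(!is.null(maskPixelSize))
    md <- imgData(regionMask)
    idx <- which(md)
    if (length(idx) == 0) stop("empty region mask")
    nr <- nrow(md)
    inMask <- function(p) {
      r <- round(p[, 1] / maskPixelSize) + 1
      c_ <- round(p[, 2] / maskPixelSize) + 1
      ok <- r >= 1 & r <= nr & c_ >= 1 & c_ <= ncol(md)
      ok[ok] <- md[cbind(r[ok], c_[ok])]
      ok
    }
    drawAnchors <- function(n) {
      i <- idx[rng$sampleInt(length(idx), n)]
      cbind((i - 1) %% nr, (i - 1) %/% nr) * maskPixelSize +
        matrix(rng$runif(2 * n, -0.5, 0.5) * maskPixelSize, n, 2)
    }
  } else {
    lo <- def@gridOrigin + 2 * def@gridSpacing
    hi <- def@gridOrigin +
      (dim(def@gridY) - 3) * def@gridSpacing
    inMask <- function(p)
      p[, 1] >= lo[1] & p[, 1] <= hi[1] & p[, 2] >= lo[2] & p[, 2] <= hi[2]
    drawAnchors <- function(n)
      cbind(rng$runif(n, lo[1], hi[1]), rng$runif(n, lo[2], hi[2]))
  }
  out <- vapply(L, function(l) {
    errs <- numeric(0)
    tries <- 0L
    while (length(errs) < nMc && tries < 50L) {
      n <- nMc * 2L
      p <- drawAnchors(n)
      ang <- rng$runif(n, 0, 2 * pi)
      q <- p + l * cbind(sin(ang), cos(ang))
      ok <- inMask(p) & inMask(q)
      if (any(ok)) {
        pp <- p[ok, , drop = FALSE] + evalDeformation(def, p[ok, , drop = FALSE])
        qq <- q[ok, , drop = FALSE] + evalDeformation(def, q[ok, , drop = FALSE])
        d <- sqrt(rowSums((pp - qq)^2))
        errs <- c(errs, abs(d - l))
      }
      tries <- tries + 1L
    }
    if (length(errs) < nMc / 10)
      stop("region too small to host pairs at separation ", l, " um")
    sqrt(mean(errs[seq_len(min(length(errs), nMc))]^2))
  }, numeric(1))
  data.frame(L = L, rmsError = out)
}

## A private RNG that does not disturb the global .Random.seed.
localRNG <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  withState <- function(f) function(...) {
    prev <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(prev)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", prev, globalenv())
    })
    f(...)
  }
  list(
    rnorm = withState(stats::rnorm),
    runif = withState(stats::runif),
    rpois = withState(stats::rpois),
    sampleInt = withState(function(n, size) sample.int(n, size, replace = TRUE))
  )
}
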