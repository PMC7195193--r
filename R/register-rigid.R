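#' Rigid scaled-rotation registration of a pre/post image pair
#'
#' Estimates the similarity transform (isotropic scale, rotation,
#' translation) mapping pre-image positions onto the post image by
#' maximizing normalized cross-correlation, initialized from intensity
#' moments (centroid, principal axes, second-moment scale). Both inputs
#' are 2D max-intensity projections; positions are handled in absolute
#' micrometres, so the recovered scale estimates the raw expansion factor
#' between the two acquisitions.
#'
#' @param pre,post 2D \linkS4class{ImageField}s of the same specimen.
#' @param nSample number of foreground sample points for the metric.
#' @param smoothPx Gaussian pre-smoothing (pixels) applied to both images.
#' @return A \linkS4class{RigidSimilarity}; the map is
#'   q_um = s * R(theta) p_um + t_um with p in the pre frame.
#' @export
registerRigid <- function(pre, post, nSample = 6000, smoothPx = 1.5) {
  stopifnot(length(dim(pre)) == 2, length(dim(post)) == 2)
  A <- smoothArray(imgData(pre), c(smoothPx, smoothPx))
  B <- smoothArray(imgData(post), c(smoothPx, smoothPx))
  pxA <- pixelSize(pre)[1]; pxB <- pixelSize(post)[1]

  momA <- imageMoments(A, pxA)
  momB <- imageMoments(B, pxB)
  s0 <- sqrt(momB$trace / momA$trace)
  ## smooth the post image to the same biological scale as the pre image
  ## (its pixels cover s0-fold less specimen), so the metric compares
  ## like with like
  if (s0 > 1.5) B <- smoothArray(imgData(post), rep(smoothPx * s0, 2))
  ## rotmat2(theta) rotates a point pattern by -theta in standard
  ## orientation, so the angle difference enters with a minus sign
  th0 <- momA$angle - momB$angle

  ## foreground sample points in the pre frame (um), deterministic subsample
  thr <- otsuThreshold(A)
  idx <- which(A > thr)
  if (length(idx) < 50) stop("pre image has too little foreground to register")
  idx <- idx[round(seq(1, length(idx), length.out = min(nSample, length(idx))))]
  nr <- nrow(A)
  P <- cbind((idx - 1) %% nr, (idx - 1) %/% nr) * pxA
  a <- A[idx]
  a <- a - mean(a)

  nrB <- nrow(B); ncB <- ncol(B)
  nccFor <- function(par) {
    s <- exp(par[1]); th <- par[2]; t <- par[3:4]
    R <- rotmat2(th)
    Q <- s * (P %*% t(R))
    Q <- sweep(Q, 2, t, "+") / pxB
    inb <- mean(Q[, 1] >= 0 & Q[, 1] <= nrB - 1 &
                Q[, 2] >= 0 & Q[, 2] <= ncB - 1)
    if (inb < 0.25) return(1)
    b <- bilinearSample(B, Q[, 1], Q[, 2])
    b <- b - mean(b)
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) return(1)
    -(sum(a * b) / den) * min(1, inb / 0.9)
  }

  best <- NULL
  tryStarts <- function(dths, best) {
    for (dth in dths) {
      th <- th0 + dth
      R <- rotmat2(th)
      t0 <- momB$centroid - s0 * as.numeric(R %*% momA$centroid)
      par0 <- c(log(s0), th, t0)
      fit <- stats::optim(par0, nccFor, method = "Nelder-Mead",
                          control = list(maxit = 800, reltol = 1e-10))
      fit <- stats::optim(fit$par, nccFor, method = "Nelder-Mead",
                          control = list(maxit = 800, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    best
  }
  best <- tryStarts(c(0, pi), best)
  ## wide-basin fallback when the two principal-axis starts disagree with
  ## a confident optimum
  if (best$value > -0.6)
    best <- tryStarts(seq(-pi, pi, length.out = 13)[-13], best)
  if (best$value > -0.2)
    stop(sprintf("rigid registration failed to converge (NCC = %.3f)",
                 -best$value))
  new("RigidSimilarity", scale = exp(best$par[1]),
      theta = atan2(sin(best$par[2]), cos(best$par[2])),
      translation = best$par[3:4], metric = -best$value)
}

## Intensity moments of a 2D image: centroid (um), principal-axis angle and
## covariance trace, using background-subtracted weights.
imageMoments <- function(A, px) {
  thr <- otsuThreshold(A)
  W <- pmax(A - thr, 0)
  nr <- nrow(A); nc <- ncol(A)
  y <- (seq_len(nr) - 1) * px
  x <- (seq_len(nc) - 1) * px
  sw <- sum(W)
  cy <- sum(W * y) / sw
  cx <- sum(t(W) * x) / sw
  dy <- y - cy; dx <- x - cx
  syy <- sum(W * dy^2) / sw
  sxx <- sum(t(W) * dx^2) / sw
  sxy <- sum(W * outer(dy, dx)) / sw
  ev <- eigen(matrix(c(syy, sxy, sxy, sxx), 2, 2), symmetric = TRUE)
  v <- ev$vectors[, 1]
  list(centroid = c(cy, cx), trace = syy + sxx, angle = atan2(v[1], v[2]))
}

## Otsu threshold on a numeric matrix (256-bin histogram).
otsuThreshold <- function(A) {
  r <- range(A)
  if (diff(r) == 0) return(r[1])
  sc <- (A - r[1]) / diff(r)
  as.numeric(EBImage::otsu(EBImage::Image(sc), range = c(0, 1))) * diff(r) + r[1]
}

#' Resample a post image into the pre frame using a rigid similarity
#'
#' Inverts the recovered transform so the result is pixelwise comparable
#' with the pre image (same grid, same pixel size); input to non-rigid
#' registration.
#'
#' @param post 2D \linkS4class{ImageField}.
#' @param rigid a \linkS4class{RigidSimilarity} from
#'   \code{\link{registerRigid}}.
#' @param pre the pre \linkS4class{ImageField} defining the target grid.
#' @return An \linkS4class{ImageField} on the pre grid.
#' @export
resampleToPre <- function(post, rigid, pre) {
  dims <- dim(imgData(pre))
  pxA <- pixelSize(pre)[1]; pxB <- pixelSize(post)[1]
  g <- expand.grid(r = seq_len(dims[1]) - 1, c = seq_len(dims[2]) - 1)
  P <- cbind(g$r, g$c) * pxA
  R <- rotmat2(rigid@theta)
  Q <- rigid@scale * (P %*% t(R))
  Q <- sweep(Q, 2, rigid@translation, "+") / pxB
  v <- bilinearSample(imgData(post), Q[, 1], Q[, 2])
  imageField(matrix(v, dims[1], dims[2]), pixelSize(pre),
             expansionFactor(pre), channelLabel(post))
}
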