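#' Non-rigid registration of a rigidly aligned pre/post pair
#'
#' Multi-resolution free-form deformation: the displacement is
#' parameterized on a coarse control mesh (bilinear interpolation between
#' nodes), optimized over three pyramid levels (mesh spacing 4x, 2x, 1x
#' the target) by L-BFGS with an analytic gradient of a normalized
#' sum-of-squares image difference plus a first-difference smoothness
#' penalty on the mesh. The foreground mask is taken by Otsu thresholding
#' of the Gaussian-smoothed (sigma = 2 px) pre image.
#'
#' @param pre 2D \linkS4class{ImageField} (fixed image, E = 1 frame).
#' @param postAligned post image already resampled into the pre frame
#'   (see \code{\link{resampleToPre}}).
#' @param rigid the \linkS4class{RigidSimilarity} used for alignment
#'   (stored in the result; identity if missing).
#' @param gridSpacingUm final control-mesh spacing in biological um.
#' @param lambda smoothness weight.
#' @param maxit L-BFGS iterations per level.
#' @param movingBlurPx extra Gaussian blur (pre-frame pixels) applied to
#'   the moving image to match the fixed image's resolution: a post
#'   image resampled to the pre frame carries E-fold finer biological
#'   detail (the PSF does not expand with the specimen), and matching the
#'   blur removes spurious displacements that would otherwise compensate
#'   the sharpness difference. For a shared absolute PSF sigma_px, use
#'   sigma_px * sqrt(1 - 1/E^2).
#' @param symmetric run the registration both ways (pre fixed, then post
#'   fixed) and average the two fields; estimation artifacts partially
#'   cancel, at twice the cost.
#' @return A \linkS4class{DeformationResult}; the residual field maps a
#'   pre-frame point p (biological um) to its position p + d(p) in the
#'   aligned post frame.
#' @export
registerNonrigid <- function(pre, postAligned, rigid = NULL,
                             gridSpacingUm = 10, lambda = 0.002, maxit = 120,
                             movingBlurPx = 0, symmetric = FALSE) {
  stopifnot(length(dim(pre)) == 2)
  if (!identical(dim(pre), dim(postAligned)))
    stop("postAligned must be on the pre grid")
  px <- pixelSize(pre)[1]
  A <- imgData(pre)
  B <- imgData(postAligned)
  if (movingBlurPx > 0) B <- smoothArray(B, rep(movingBlurPx, 2))
  Asm <- smoothArray(A, c(2, 2))
  thr <- otsuThreshold(Asm)
  fg <- Asm > thr
  if (mean(fg) < 0.01) stop("foreground below 1% of the image; cannot register")

  zs <- function(m) (m - mean(m[fg])) / stats::sd(m[fg])
  hTarget <- gridSpacingUm * expansionFactor(pre) / px
  levels <- hTarget * c(4, 2, 1)

  nr <- nrow(A); nc <- ncol(A)
  pixIdx <- which(fg)
  pr <- (pixIdx - 1) %% nr       # 0-based row
  pc <- (pixIdx - 1) %/% nr      # 0-based col

  runFFD <- function(A, B) {
  uy <- NULL; ux <- NULL; prevMesh <- NULL
  for (h in levels) {
    sm <- min(max(h / 16, 0.8), 2.5)
    Af <- zs(smoothArray(A, c(sm, sm)))
    Bf <- zs(smoothArray(B, c(sm, sm)))
    ## gradient images of the moving image
    gBy <- rbind(Bf[2, , drop = FALSE] - Bf[1, , drop = FALSE],
                 (Bf[-(1:2), ] - Bf[seq_len(nr - 2), ]) / 2,
                 Bf[nr, , drop = FALSE] - Bf[nr - 1, , drop = FALSE])
    gBx <- cbind(Bf[, 2, drop = FALSE] - Bf[, 1, drop = FALSE],
                 (Bf[, -(1:2)] - Bf[, seq_len(nc - 2)]) / 2,
                 Bf[, nc, drop = FALSE] - Bf[, nc - 1, drop = FALSE])

    mny <- max(2L, ceiling((nr - 1) / h) + 1L)
    mnx <- max(2L, ceiling((nc - 1) / h) + 1L)
    hy <- (nr - 1) / (mny - 1); hx <- (nc - 1) / (mnx - 1)
    ## bilinear weights pixel -> 4 surrounding nodes
    fy <- pr / hy; fx <- pc / hx
    iy0 <- pmin(floor(fy), mny - 2); ix0 <- pmin(floor(fx), mnx - 2)
    wy1 <- fy - iy0; wx1 <- fx - ix0
    wy0 <- 1 - wy1; wx0 <- 1 - wx1
    nid <- function(iy, ix) iy + ix * mny + 1L
    n00 <- nid(iy0, ix0); n10 <- nid(iy0 + 1, ix0)
    n01 <- nid(iy0, ix0 + 1); n11 <- nid(iy0 + 1, ix0 + 1)
    w00 <- wy0 * wx0; w10 <- wy1 * wx0; w01 <- wy0 * wx1; w11 <- wy1 * wx1
    nNode <- mny * mnx

    ## initialize from previous level
    if (is.null(uy)) {
      nodeUy <- numeric(nNode); nodeUx <- numeric(nNode)
    } else {
      gy <- rep((0:(mny - 1)) * hy, mnx)
      gx <- rep((0:(mnx - 1)) * hx, each = mny)
      nodeUy <- bilinearSample(prevMesh$uy, gy / prevMesh$hy, gx / prevMesh$hx)
      nodeUx <- bilinearSample(prevMesh$ux, gy / prevMesh$hy, gx / prevMesh$hx)
    }

    accum <- function(v) {
      out <- numeric(nNode)
      for (k in 1:4) {
        idx <- switch(k, n00, n10, n01, n11)
        w <- switch(k, w00, w10, w01, w11)
        rs <- rowsum(w * v, idx)
        out[as.integer(rownames(rs))] <- out[as.integer(rownames(rs))] + rs[, 1]
      }
      out
    }
    interpU <- function(nodes)
      nodes[n00] * w00 + nodes[n10] * w10 + nodes[n01] * w01 + nodes[n11] * w11

    ## smoothness: first differences over the node lattice
    My <- matrix(seq_len(nNode), mny, mnx)
    pairA <- c(My[-mny, ], My[, -mnx])
    pairB <- c(My[-1, ], My[, -1])
    npix <- length(pixIdx)

    fn <- function(par) {
      nuy <- par[seq_len(nNode)]; nux <- par[nNode + seq_len(nNode)]
      yy <- pr + interpU(nuy); xx <- pc + interpU(nux)
      res <- bilinearSample(Bf, yy, xx) - Af[pixIdx]
      dA <- nuy[pairA] - nuy[pairB]; dB <- nux[pairA] - nux[pairB]
      mean(res^2) + lambda * (sum(dA^2) + sum(dB^2)) / length(pairA)
    }
    gr <- function(par) {
      nuy <- par[seq_len(nNode)]; nux <- par[nNode + seq_len(nNode)]
      yy <- pr + interpU(nuy); xx <- pc + interpU(nux)
      res <- bilinearSample(Bf, yy, xx) - Af[pixIdx]
      gy_ <- bilinearSample(gBy, yy, xx)
      gx_ <- bilinearSample(gBx, yy, xx)
      gUy <- accum(2 * res * gy_ / npix)
      gUx <- accum(2 * res * gx_ / npix)
      dA <- nuy[pairA] - nuy[pairB]; dB <- nux[pairA] - nux[pairB]
      regY <- numeric(nNode); regX <- numeric(nNode)
      for (pm in list(list(pairA, 1), list(pairB, -1))) {
        rsY <- rowsum(pm[[2]] * 2 * lambda * dA / length(pairA), pm[[1]])
        rsX <- rowsum(pm[[2]] * 2 * lambda * dB / length(pairA), pm[[1]])
        ii <- as.integer(rownames(rsY))
        regY[ii] <- regY[ii] + rsY[, 1]
        regX[ii] <- regX[ii] + rsX[, 1]
      }
      c(gUy + regY, gUx + regX)
    }
    fit <- stats::optim(c(nodeUy, nodeUx), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e7))
    nodeUy <- fit$par[seq_len(nNode)]
    nodeUx <- fit$par[nNode + seq_len(nNode)]
    prevMesh <- list(uy = matrix(nodeUy, mny, mnx),
                     ux = matrix(nodeUx, mny, mnx), hy = hy, hx = hx)
    uy <- TRUE  # flag: initialized
  }
  prevMesh
  }

  prevMesh <- runFFD(A, B)

  ## dense field (pixels -> biological um)
  gAll <- expand.grid(r = 0:(nr - 1), c = 0:(nc - 1))
  dy <- bilinearSample(prevMesh$uy, gAll$r / prevMesh$hy, gAll$c / prevMesh$hx)
  dx <- bilinearSample(prevMesh$ux, gAll$r / prevMesh$hy, gAll$c / prevMesh$hx)
  if (symmetric) {
    ## compose with the inverse of the backward registration: sample the
    ## backward field at the forward-warped position, then average
    meshB <- runFFD(B, A)
    dyB <- bilinearSample(meshB$uy, (gAll$r + dy) / meshB$hy,
                          (gAll$c + dx) / meshB$hx)
    dxB <- bilinearSample(meshB$ux, (gAll$r + dy) / meshB$hy,
                          (gAll$c + dx) / meshB$hx)
    dy <- (dy - dyB) / 2
    dx <- (dx - dxB) / 2
  }
  dy <- matrix(dy, nr, nc); dx <- matrix(dx, nr, nc)

  ## fold the residual's own similarity component (mean translation,
  ## scale, rotation over the mask) into the rigid transform, mirroring
  ## the identifiability convention: the residual field is orthogonal to
  ## a global similarity
  if (!is.null(rigid)) {
    sy <- pr; sx <- pc
    Z <- rbind(cbind(1, 0, sy, -sx), cbind(0, 1, sx, sy))
    beta <- qr.coef(qr(Z), c(dy[pixIdx], dx[pixIdx]))
    dy <- dy - (beta[1] + beta[3] * (row(dy) - 1) - beta[4] * (col(dy) - 1))
    dx <- dx - (beta[2] + beta[4] * (row(dx) - 1) + beta[3] * (col(dx) - 1))
    ## total map in the aligned frame: x -> (I + B) x + a + residual
    dsc <- sqrt((1 + beta[3])^2 + beta[4]^2)
    dth <- atan2(beta[4], 1 + beta[3])
    R0 <- rotmat2(rigid@theta)
    rigid <- new("RigidSimilarity", scale = rigid@scale * dsc,
                 theta = rigid@theta + dth,
                 translation = rigid@translation +
                   rigid@scale * as.numeric(R0 %*% (beta[1:2] * px)),
                 metric = rigid@metric)
  }
  umScale <- px / expansionFactor(pre)
  fieldY <- dy * umScale
  fieldX <- dx * umScale

  ## metric: NCC inside the mask after warping
  yy <- pr + bilinearSample(prevMesh$uy, pr / prevMesh$hy, pc / prevMesh$hx)
  xx <- pc + bilinearSample(prevMesh$ux, pr / prevMesh$hy, pc / prevMesh$hx)
  wv <- bilinearSample(B, yy, xx)
  av <- A[pixIdx]
  ncc <- stats::cor(av, wv)

  if (is.null(rigid))
    rigid <- new("RigidSimilarity", scale = 1, theta = 0,
                 translation = c(0, 0), metric = NA_real_)
  new("DeformationResult", rigid = rigid, fieldY = fieldY, fieldX = fieldX,
      mask = mask(fg, "foreground"), metric = ncc,
      pixelSize = pixelSize(pre))
}
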