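#' Detect FISH-HCR spots in a 3D stack
#'
#' Band-pass (difference-of-Gaussians, a Laplacian-of-Gaussian-style
#' filter) spot detection: the stack is filtered with matched and 2x-wide
#' anisotropic Gaussians, the difference normalized so an isolated
#' unit-amplitude Gaussian spot of the stated sigmas yields filtered
#' amplitude ~ 1, 26-connected regional maxima located, maxima below the
#' amplitude threshold discarded, and surviving positions refined by an
#' intensity-weighted centroid in a (3 sigma)^3 window.
#'
#' @param img 3D \linkS4class{ImageField} (z, y, x).
#' @param sigmaXy,sigmaZ expected spot sigma in um (absolute). Defaults
#'   reflect the effective size of HCR amplicons at ~3.3x expansion
#'   (~150 nm lateral / ~250 nm axial in biological units) convolved with
#'   a confocal PSF: about 0.2 um lateral and 0.35 um axial.
#' @param threshold minimum normalized filtered amplitude; spots weaker
#'   than this are treated as background noise (the counterpart of the
#'   manually selected intensity threshold in interactive workflows; see
#'   \code{\link{suggestThreshold}} for an automated suggestion).
#' @param kappa band-pass kernel size as a fraction of the spot sigma;
#'   slightly undersized kernels keep close pairs separable.
#' @return data.frame (SpotTable): z, y, x (0-based voxel coordinates,
#'   sub-voxel refined), amplitude (normalized filtered), raw (intensity
#'   at the nearest voxel). Detection parameters stored as attributes.
#' @export
detectSpots <- function(img, sigmaXy = 0.2, sigmaZ = 0.35, threshold = 0.3,
                        kappa = 0.7) {
  a <- imgData(img)
  if (length(dim(a)) != 3) stop("detectSpots needs a 3D stack")
  stopifnot(sigmaXy > 0, sigmaZ > 0, threshold >= 0)
  F <- dogFilter(a, pixelSize(img), sigmaXy, sigmaZ, kappa)
  cand <- regionalMaxima3d(F, max(threshold, 1e-6))
  if (nrow(cand) == 0) {
    out <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      amplitude = numeric(0), raw = numeric(0))
  } else {
    sv <- c(sigmaZ, sigmaXy, sigmaXy) / pixelSize(img)
    ## the >= neighbourhood test lets every voxel of a flat plateau
    ## qualify; keep one representative per group of adjacent equal-valued
    ## candidates and leave genuinely distinct maxima alone
    keep <- rep(TRUE, nrow(cand))
    pts <- as.matrix(cand[, c("z", "y", "x")])
    for (g in split(seq_len(nrow(cand)), cand$value)) {
      if (length(g) < 2) next
      taken <- g[1]
      for (i in g[-1]) {
        d2 <- rowSums(sweep(pts[taken, , drop = FALSE], 2, pts[i, ])^2)
        if (min(d2) <= 3) keep[i] <- FALSE else taken <- c(taken, i)
      }
    }
    cand <- cand[keep, , drop = FALSE]
    ref <- refineCentroids(F, cand, ceiling(1.5 * sv))
    rawIdx <- cbind(pmin(pmax(round(ref[, 1]), 0), dim(a)[1] - 1) + 1,
                    pmin(pmax(round(ref[, 2]), 0), dim(a)[2] - 1) + 1,
                    pmin(pmax(round(ref[, 3]), 0), dim(a)[3] - 1) + 1)
    out <- data.frame(z = ref[, 1], y = ref[, 2], x = ref[, 3],
                      amplitude = cand$value, raw = a[rawIdx])
    out <- out[out$amplitude >= threshold, ]
    rownames(out) <- NULL
  }
  attr(out, "params") <- list(sigmaXy = sigmaXy, sigmaZ = sigmaZ,
                              threshold = threshold)
  out
}

## Normalized difference-of-Gaussians band-pass. The kernel is kappa
## times the expected spot sigma (slightly undersized, which keeps close
## spot pairs separable at a small noise-suppression cost); the response
## of a unit-amplitude Gaussian spot of sd sigma to a Gaussian kernel of
## sd kappa*sigma is prod(1 / sqrt(1 + kappa^2)) per axis, and the
## normalization makes an isolated unit spot filter to ~ 1.
dogFilter <- function(a, voxel, sigmaXy, sigmaZ, kappa = 0.7) {
  sv <- kappa * c(sigmaZ, sigmaXy, sigmaXy) / voxel
  f1 <- smoothArray(a, sv)
  f2 <- smoothArray(a, 2 * sv)
  norm <- (1 + kappa^2)^(-3 / 2) - (1 + 4 * kappa^2)^(-3 / 2)
  (f1 - f2) / norm
}

## 26-connected regional maxima of a 3D array above a floor value.
## Returns a data.frame of 0-based voxel coordinates and values.
regionalMaxima3d <- function(F, floorVal) {
  d <- dim(F)
  ok <- F >= floorVal
  ## exclude one-voxel border to simplify neighbourhood logic
  ok[c(1, d[1]), , ] <- FALSE
  ok[, c(1, d[2]), ] <- FALSE
  ok[, , c(1, d[3])] <- FALSE
  idx <- which(ok)
  if (length(idx) == 0)
    return(data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      value = numeric(0)))
  nz <- d[1]; nzy <- d[1] * d[2]
  v <- F[idx]
  isMax <- rep(TRUE, length(idx))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    off <- dz + dy * nz + dx * nzy
    isMax <- isMax & (v >= F[idx + off])
    }
  idx <- idx[isMax]
  v <- v[isMax]
  z <- (idx - 1) %% nz
  y <- ((idx - 1) %/% nz) %% d[2]
  x <- (idx - 1) %/% nzy
  data.frame(z = z, y = y, x = x, value = v)
}

## Intensity-weighted centroid refinement in a box of half-size `half`
## (voxels per axis) on the filtered image.
refineCentroids <- function(F, cand, half) {
  d <- dim(F)
  out <- matrix(0, nrow(cand), 3)
  for (i in seq_len(nrow(cand))) {
    c0 <- c(cand$z[i], cand$y[i], cand$x[i])
    lo <- pmax(c0 - half, 0); hi <- pmin(c0 + half, d - 1)
    w <- F[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1, drop = FALSE]
    w <- pmax(w, 0)
    sw <- sum(w)
    if (sw == 0) { out[i, ] <- c0; next }
    gz <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gx <- lo[3]:hi[3]
    out[i, 1] <- sum(apply(w, 1, sum) * gz) / sw
    out[i, 2] <- sum(apply(w, 2, sum) * gy) / sw
    out[i, 3] <- sum(apply(w, 3, sum) * gx) / sw
  }
  out
}

#' Suggest a spot amplitude threshold from the count-vs-threshold curve
#'
#' Computes the spot count over a log-spaced threshold grid and returns
#' the threshold at the flattest plateau of the log-log count curve (the
#' regime where the count is insensitive to the threshold, separating
#' signal from noise amplitudes). If no plateau exists (monotone curve),
#' the threshold at the median gradient is returned with a warning flag —
#' an automation aid for what is otherwise a manual per-stack choice.
#'
#' @param img 3D \linkS4class{ImageField}.
#' @param sigmaXy,sigmaZ spot sigmas, um (see \code{\link{detectSpots}}).
#' @param nGrid number of threshold grid points (>= 20).
#' @return list: threshold, curve (data.frame threshold/count/gradient),
#'   flat (TRUE if a plateau was found; FALSE = warning flag).
#' @export
suggestThreshold <- function(img, sigmaXy = 0.2, sigmaZ = 0.35, nGrid = 40) {
  stopifnot(nGrid >= 20)
  a <- imgData(img)
  F <- dogFilter(a, pixelSize(img), sigmaXy, sigmaZ)
  grid <- exp(seq(log(max(F) / 100), log(max(F)), length.out = nGrid))
  cand <- regionalMaxima3d(F, grid[1])
  amps <- sort(cand$value, decreasing = TRUE)
  counts <- vapply(grid, function(t) sum(amps >= t), numeric(1))
  lc <- log(counts + 1)
  lg <- log(grid)
  grad <- abs(c(diff(lc) / diff(lg), NA))
  inner <- which(counts >= 3 & !is.na(grad))
  if (length(inner) == 0) {
    return(list(threshold = grid[ceiling(nGrid / 2)],
                curve = data.frame(threshold = grid, count = counts,
                                   gradient = grad),
                flat = FALSE))
  }
  gmed <- stats::median(grad[inner])
  ## the flattest plateau of the count curve is the widest gap in the
  ## sorted candidate amplitudes (counts are constant across it). A valid
  ## signal plateau leaves at least 3 but at most half of the candidates
  ## above the gap: a noise-only stack offers only gaps in its own tails,
  ## which fail that condition.
  drop <- 3L
  la <- sort(log(amps[amps > 0]), decreasing = TRUE)
  if (length(la) > drop) la <- la[-seq_len(drop)]
  gaps <- -diff(la)
  upperCount <- seq_along(gaps) + drop
  valid <- which(upperCount >= 3 & upperCount <= 0.5 * length(amps) &
                 gaps >= log(1.35))
  flat <- length(valid) > 0
  if (flat) {
    k <- valid[which.max(gaps[valid])]
    threshold <- exp((la[k] + la[k + 1]) / 2)
  } else {
    threshold <- grid[inner[which.min(abs(grad[inner] - gmed))]]
    warning("no plateau in the count-threshold curve; returning the ",
            "median-gradient threshold")
  }
  list(threshold = threshold,
       curve = data.frame(threshold = grid, count = counts, gradient = grad),
       flat = flat)
}

#' Count spots inside 3D ROI boxes
#'
#' Inclusive box containment on the refined spot coordinates; a spot
#' lying exactly on a box face counts as inside. A spot overlapping
#' several ROIs is assigned to the first matching ROI in list order.
#'
#' @param spots SpotTable data.frame from \code{\link{detectSpots}}.
#' @param rois list of \linkS4class{RoiBox3D}.
#' @param img optional \linkS4class{ImageField} for biological box volumes.
#' @return data.frame (CellCountTable): label, count, volumeUm3
#'   (biological; NA without \code{img}).
#' @export
countInRois <- function(spots, rois, img = NULL) {
  counts <- integer(length(rois))
  vol <- rep(NA_real_, length(rois))
  assigned <- rep(FALSE, nrow(spots))
  for (i in seq_along(rois)) {
    b <- rois[[i]]
    if (!is.null(img)) {
      d <- dim(imgData(img))
      if (any(b@minCorner < 0) || any(b@maxCorner > d - 1))
        stop("ROI '", b@label, "' outside image bounds")
      vs <- pixelSize(img) / expansionFactor(img)
      vol[i] <- prod((b@maxCorner - b@minCorner + 1) * vs)
    }
    if (nrow(spots) > 0) {
      inside <- !assigned &
        spots$z >= b@minCorner[1] & spots$z <= b@maxCorner[1] &
        spots$y >= b@minCorner[2] & spots$y <= b@maxCorner[2] &
        spots$x >= b@minCorner[3] & spots$x <= b@maxCorner[3]
      counts[i] <- sum(inside)
      assigned <- assigned | inside
    }
  }
  data.frame(label = vapply(rois, function(b) b@label, character(1)),
             count = counts, volumeUm3 = vol, stringsAsFactors = FALSE)
}

#' Fraction of spots inside a mask
#'
#' A spot is inside if its nearest voxel is TRUE. An empty spot table
#' yields NA (missing), not zero.
#'
#' @param spots SpotTable data.frame.
#' @param msk a \linkS4class{Mask} congruent with the detection stack.
#' @return fraction in [0, 1], or NA for an empty table.
#' @export
fractionInMask <- function(spots, msk) {
  if (nrow(spots) == 0) return(NA_real_)
  m <- imgData(msk)
  d <- dim(m)
  zz <- pmin(pmax(round(spots$z), 0), d[1] - 1) + 1
  yy <- pmin(pmax(round(spots$y), 0), d[2] - 1) + 1
  xx <- pmin(pmax(round(spots$x), 0), d[3] - 1) + 1
  mean(m[cbind(zz, yy, xx)])
}
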