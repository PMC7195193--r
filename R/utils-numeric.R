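## Bilinear sampling of a 2D matrix at (row, col) positions given in
## 0-based pixel-centre coordinates. Positions outside the grid are clamped
## to the border (replicate padding).
bilinearSample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 0), nr - 1)
  c <- pmin(pmax(c, 0), nc - 1)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  v00 <- m[cbind(r0 + 1, c0 + 1)]
  v01 <- m[cbind(r0 + 1, c1 + 1)]
  v10 <- m[cbind(r1 + 1, c0 + 1)]
  v11 <- m[cbind(r1 + 1, c1 + 1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

## Discrete Gaussian kernel, truncated at 4 sigma, normalized to sum 1.
gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## 1D convolution along the first margin of a matrix whose columns are
## independent signals, with edge renormalization (kernel mass falling
## outside the signal is redistributed). Implemented as a dense band
## matrix product so BLAS does the work.
convMatrix1d <- function(n, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - half):(j + half)
    keep <- idx >= 1 & idx <= n
    w <- kernel[keep]
    K[idx[keep], j] <- w / sum(w)
  }
  K
}

## Separable Gaussian smoothing of an nd array (2D or 3D), sigma per axis
## in pixels. sigma of 0 skips an axis.
smoothArray <- function(a, sigma) {
  d <- dim(a)
  nd <- length(d)
  stopifnot(length(sigma) == nd)
  for (ax in seq_len(nd)) {
    if (sigma[ax] <= 0) next
    k <- gaussKernel1d(sigma[ax])
    K <- convMatrix1d(d[ax], k)
    perm <- c(ax, setdiff(seq_len(nd), ax))
    ap <- aperm(a, perm)
    dims <- dim(ap)
    ap <- matrix(ap, nrow = dims[1])
    ap <- crossprod(K, ap)       # t(K) %*% ap; K column j holds weights for output j
    dim(ap) <- dims
    a <- aperm(ap, order(perm))
  }
  a
}

## Smooth step from 0 (t <= -1) to 1 (t >= 1) used for soft object edges.
smoothstep <- function(t) {
  t <- pmin(pmax((t + 1) / 2, 0), 1)
  t * t * (3 - 2 * t)
}

## Cumulative arc length of an n x d matrix of points.
chordLengths <- function(p) {
  d <- diff(p)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

## Resample a polyline (n x 2, columns y,x) at uniform arc-length spacing
## `step` using a cubic spline through the points (chord-length
## parameterization). Returns a matrix of points including both ends.
resampleCurve <- function(points, step, n_dense = 20L) {
  s <- chordLengths(points)
  if (nrow(points) == 2) {
    L <- s[length(s)]
    tt <- seq(0, L, length.out = max(2L, ceiling(L / step) + 1L))
    return(cbind(stats::approx(s, points[, 1], tt)$y,
                 stats::approx(s, points[, 2], tt)$y))
  }
  fy <- stats::splinefun(s, points[, 1], method = "natural")
  fx <- stats::splinefun(s, points[, 2], method = "natural")
  ## dense sampling to recover true arc length of the spline
  td <- seq(0, s[length(s)], length.out = n_dense * length(s))
  dense <- cbind(fy(td), fx(td))
  sd_ <- chordLengths(dense)
  L <- sd_[length(sd_)]
  tt <- seq(0, L, length.out = max(2L, round(L / step) + 1L))
  ## invert arc length -> parameter
  ti <- stats::approx(sd_, td, tt, rule = 2)$y
  cbind(fy(ti), fx(ti))
}

## Rotation matrix (2D, acting on column vectors of (y, x))
rotmat2 <- function(theta) {
  ## coordinates are (y, x); rotation by theta maps (y,x) as in standard
  ## xy-plane rotation applied to (x, y)
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2, byrow = TRUE)
}
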