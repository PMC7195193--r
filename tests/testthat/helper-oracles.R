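## Independent oracles used across the test files.

## Water-level prominence oracle: lower a horizontal level from the peak
## height; the prominence is the drop at which the connected region
## {x >= level} containing the peak first touches a strictly higher
## sample or a signal end on BOTH escape routes. Implemented literally,
## independent of the package's scan-based computation.
waterLevelProminence <- function(x, m) {
  h <- x[m]
  n <- length(x)
  sideRef <- function(idx) {
    ## walk away from the peak; track the running minimum until a value
    ## strictly above h (higher ground) or the signal end stops the walk
    if (length(idx) == 0) return(h)   # peak at the boundary
    runMin <- Inf
    for (i in idx) {
      if (x[i] > h) return(runMin)
      runMin <- min(runMin, x[i])
    }
    runMin                              # reached the end: end is a boundary
  }
  left <- sideRef(rev(seq_len(m - 1)))
  right <- sideRef(seq(m + 1, n, length.out = max(0, n - m)))
  h - max(left, right)
}

## All plateau-aware local maxima (midpoints), endpoints excluded;
## independent re-derivation used to cross-check peak finding.
oracleLocalMaxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    if (j < n && x[i] > x[i - 1] && x[i] > x[j + 1])
      out <- c(out, floor((i + j) / 2))
    i <- j + 1
  }
  out
}

oraclePeakCount <- function(x, thr = 0.01) {
  cand <- oracleLocalMaxima(x)
  if (!length(cand)) return(0L)
  proms <- vapply(cand, function(m) waterLevelProminence(x, m), numeric(1))
  sum(proms >= thr)
}

## Greedy nearest-distance matching of detected vs truth spot coordinates
## (n x 3 matrices, voxel units scaled to um by the caller). Returns the
## number of matched pairs within `radius`.
matchSpots <- function(det, truth, radius) {
  if (nrow(det) == 0 || nrow(truth) == 0) return(0L)
  d2 <- outer(rowSums(det^2), rowSums(truth^2), "+") - 2 * det %*% t(truth)
  d2[d2 < 0] <- 0
  matched <- 0L
  repeat {
    k <- which.min(d2)
    if (!length(k) || d2[k] > radius^2) break
    i <- (k - 1) %% nrow(det) + 1
    j <- (k - 1) %/% nrow(det) + 1
    matched <- matched + 1L
    d2[i, ] <- Inf
    d2[, j] <- Inf
    if (all(is.infinite(d2))) break
  }
  matched
}

## Independent 3D spot-stack renderer (plain dnorm outer products), used
## as the rendering oracle for detection tests.
renderSpotStack <- function(dims, coords, amps, sigmaVox, background = 0,
                            noiseSd = 0, seed = 1) {
  a <- array(background, dims)
  for (i in seq_len(nrow(coords))) {
    gz <- exp(-((0:(dims[1] - 1)) - coords[i, 1])^2 / (2 * sigmaVox[1]^2))
    gy <- exp(-((0:(dims[2] - 1)) - coords[i, 2])^2 / (2 * sigmaVox[2]^2))
    gx <- exp(-((0:(dims[3] - 1)) - coords[i, 3])^2 / (2 * sigmaVox[3]^2))
    a <- a + amps[i] * outer(outer(gz, gy), gx)
  }
  if (noiseSd > 0) {
    set.seed(seed)
    a <- pmax(a + array(rnorm(length(a), sd = noiseSd), dims), 0)
  }
  a
}
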