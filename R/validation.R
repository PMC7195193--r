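#' Isotropy phantom study: registration pipeline vs Monte-Carlo oracle
#'
#' Generates worm phantoms with a known residual deformation, runs the
#' full distortion pipeline (rigid scaled-rotation registration,
#' resampling, symmetric non-rigid registration, RMS error curve) and
#' compares the per-bin curve, averaged across animals, with the
#' Monte-Carlo pair-error oracle evaluated on the true field over the
#' same foreground. The mesh spacing resolves the field's correlation
#' length and the smoothness weight follows a matched prior (stronger for
#' smoother, lower-amplitude fields); see the methods vignette.
#'
#' @param sigmaD,ell,eTrue deformation amplitude (um), correlation length
#'   (um) and expansion factor of the phantoms.
#' @param seeds one phantom (animal) per seed.
#' @param nPairs pairs per RMS curve.
#' @param binMax largest separation bin (um).
#' @param oracleN Monte-Carlo pairs per bin for the oracle.
#' @return list: curve (data.frame binCenter, rms, oracle, relDev),
#'   scaleErrors (per animal, fractional), lambda, gridSpacing.
#' @export
isotropyStudy <- function(sigmaD, ell, eTrue, seeds, nPairs = 20000,
                          binMax = 70, oracleN = 2000) {
  h <- min(ell / 2, 5)
  lambda <- min(max(7.5e-5 * (ell / h)^2 / sigmaD^2, 0.002), 0.03)
  bins <- seq(0, binMax, 1)
  cs <- NULL; os <- NULL
  scaleErr <- numeric(0)
  for (seed in seeds) {
    ph <- generatePhantom(phantomSpec(sigmaD = sigmaD, ell = ell,
                                      eTrue = eTrue, seed = seed))
    rig <- registerRigid(ph$pre, ph$post)
    aligned <- resampleToPre(ph$post, rig, ph$pre)
    res <- registerNonrigid(ph$pre, aligned, rig, gridSpacingUm = h,
                            lambda = lambda, symmetric = TRUE)
    cv <- suppressWarnings(rmsErrorCurve(res, nPairs = nPairs, bins = bins,
                                         seed = seed))
    oa <- expectedPairError(ph$truth@deformation, cv$binCenter,
                            nMc = oracleN, seed = seed + 100,
                            regionMask = ph$truth@foregroundMask,
                            maskPixelSize = pixelSize(ph$pre)[1])
    cs <- cbind(cs, cv$rmsError)
    os <- cbind(os, oa$rmsError)
    scaleErr <- c(scaleErr, abs(res@rigid@scale - eTrue) / eTrue)
  }
  cm <- rowMeans(cs); om <- rowMeans(os)
  centers <- (bins[-1] + bins[-length(bins)]) / 2
  ok <- centers >= 5 & !is.na(cm)
  list(curve = data.frame(binCenter = centers[ok], rms = cm[ok],
                          oracle = om[ok], relDev = cm[ok] / om[ok] - 1),
       scaleErrors = scaleErr, lambda = lambda, gridSpacing = h)
}

#' Per-cell spot-count recovery study on FISH phantoms
#'
#' Simulates a multi-cell FISH stack, detects spots with the band-pass
#' detector, counts per ROI, and scores recall/precision (greedy
#' nearest-match against truth coordinates) and per-cell count bias.
#'
#' @param lambda per-cell Poisson mean (scalar or per-cell vector).
#' @param nCells number of cells.
#' @param snr spot amplitude / noise sd.
#' @param seed integer seed.
#' @param voxelSize (z, y, x) voxel size, um.
#' @param threshold detection amplitude threshold.
#' @param matchRadiusUm truth-match radius (default 2 sigma lateral).
#' @param ... further arguments for \code{\link{generateFishPhantom}}.
#' @return list: recall, precision, bias (mean detected - truth count),
#'   counts (per-cell data.frame with truth).
#' @export
spotRecoveryStudy <- function(lambda, nCells = 50, snr = 5, seed = 1,
                              voxelSize = c(0.4, 0.2, 0.2), threshold = 0.6,
                              matchRadiusUm = 0.4, ...) {
  ph <- generateFishPhantom(nCells = nCells, lambda = lambda,
                            voxelSize = voxelSize, snr = snr, seed = seed, ...)
  spots <- detectSpots(ph$img, threshold = threshold)
  counts <- countInRois(spots, ph$rois, ph$img)
  truthCounts <- ph$cellCounts$count
  det <- cbind(spots$z * voxelSize[1], spots$y * voxelSize[2],
               spots$x * voxelSize[3])
  tru <- as.matrix(ph$spots[, c("z", "y", "x")]) %*% diag(voxelSize)
  matched <- greedyMatch(det, tru, matchRadiusUm)
  list(recall = if (nrow(tru)) matched / nrow(tru) else NA_real_,
       precision = if (nrow(det)) matched / nrow(det) else NA_real_,
       bias = mean(counts$count - truthCounts),
       counts = cbind(counts, truth = truthCounts))
}

## greedy mutual nearest matching within a radius; counts matched pairs
greedyMatch <- function(det, tru, radius) {
  if (nrow(det) == 0 || nrow(tru) == 0) return(0L)
  matched <- 0L
  d2 <- outer(rowSums(det^2), rowSums(tru^2), "+") - 2 * det %*% t(tru)
  repeat {
    k <- which.min(d2)
    if (!length(k) || d2[k] > radius^2) break
    matched <- matched + 1L
    i <- (k - 1) %% nrow(det) + 1
    j <- (k - 1) %/% nrow(det) + 1
    d2[i, ] <- Inf; d2[, j] <- Inf
    if (all(is.infinite(d2))) break
  }
  matched
}

#' Resolution-driven puncta gain study on synthetic nerve cords
#'
#' Simulates line profiles of synaptic puncta whose inter-punctum gaps
#' are a mixture: a fraction f falls below the diffraction-limited
#' resolvable distance at the pre-expansion scale but above it after
#' expansion by eTrue; the rest is resolvable in both. Profiles are
#' rendered at both scales with the same optical PSF, normalized,
#' smoothed, and peak-counted; the paired fold change quantifies the
#' counting gain that expansion produces purely by pulling sub-resolution
#' neighbours apart.
#'
#' @param f fraction of sub-resolution gaps (vectorized over cords).
#' @param nCords number of simulated cord segments.
#' @param punctaPerCord puncta per segment.
#' @param eTrue linear expansion factor.
#' @param psfSigma optical PSF sigma, um (absolute; identical pre/post).
#' @param sampleSpacing profile sample spacing, um (absolute).
#' @param noiseSd additive profile noise before normalization.
#' @param seed integer seed.
#' @return list: foldChange (slope and ratio of sums), preCounts,
#'   postCounts.
#' @export
punctaResolutionStudy <- function(f, nCords = 12, punctaPerCord = 25,
                                  eTrue = 3.3, psfSigma = 0.11,
                                  sampleSpacing = 0.08, noiseSd = 0.02,
                                  seed = 1) {
  rng <- localRNG(seed)
  preC <- integer(nCords); postC <- integer(nCords)
  for (ci in seq_len(nCords)) {
    sub <- rng$runif(punctaPerCord - 1) < f
    gaps <- ifelse(sub,
                   rng$runif(punctaPerCord - 1, 0.8, 1.8) * psfSigma,
                   rng$runif(punctaPerCord - 1, 5, 12) * psfSigma)
    pos <- cumsum(c(2 * psfSigma + 0.5, gaps))
    amps <- rng$runif(punctaPerCord, 0.7, 1.3)
    render <- function(scale) {
      p <- pos * scale
      x <- seq(0, max(p) + 0.5, by = sampleSpacing)
      y <- numeric(length(x))
      for (i in seq_along(p))
        y <- y + amps[i] * exp(-(x - p[i])^2 / (2 * psfSigma^2))
      y <- pmax(y + rng$rnorm(length(y), sd = noiseSd), 0)
      countPeaks(normalizeSmooth(lineProfile(y, sampleSpacing / scale)))@count
    }
    preC[ci] <- render(1)
    postC[ci] <- render(eTrue)
  }
  list(foldChange = foldChange(preC, postC), preCounts = preC,
       postCounts = postC)
}

#' Single-neuron transcript-count study at printed per-neuron abundances
#'
#' Runs the full single-neuron RNA quantification workflow (3D FISH
#' phantom with one soma per neuron, band-pass spot detection, ROI
#' counting) on simulated animals whose per-neuron Poisson means are set
#' to published single-neuron transcript abundances, and recomputes the
#' per-neuron means and their ratio.
#'
#' @param lambdas named per-neuron Poisson means.
#' @param nAnimals simulated animals.
#' @param seed integer seed.
#' @param snr spot amplitude / noise sd.
#' @return list: means (named), ratio (first/last), counts data.frame.
#' @export
transcriptCountStudy <- function(lambdas = c(RIS = 188.3, RMED = 48.7),
                                 nAnimals = 3, seed = 1, snr = 5) {
  rows <- NULL
  for (a in seq_len(nAnimals)) {
    st <- spotRecoveryStudy(lambda = unname(lambdas),
                            nCells = length(lambdas), snr = snr,
                            seed = seed + a,
                            voxelSize = c(0.3, 0.15, 0.15),
                            nucleusRadiusUm = 1.2, shellThicknessUm = 1.3)
    rows <- rbind(rows, data.frame(animal = a, neuron = names(lambdas),
                                   count = st$counts$count))
  }
  means <- tapply(rows$count, rows$neuron, mean)[names(lambdas)]
  list(means = means, ratio = unname(means[1] / means[length(means)]),
       counts = rows)
}
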