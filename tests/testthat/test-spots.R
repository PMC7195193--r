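voxel <- c(0.3, 0.15, 0.15)
sigXy <- 0.2
sigZ <- 0.35
sigVox <- c(sigZ, sigXy, sigXy) / voxel

test_that("an empty stack yields an empty spot table, not an error", {
  img <- imageField(array(0, c(16, 24, 24)), voxel)
  s <- detectSpots(img, sigXy, sigZ, threshold = 0.2)
  expect_equal(nrow(s), 0L)
  expect_error(detectSpots(imageField(matrix(0, 8, 8), 0.2), sigXy, sigZ),
               "3D")
})

test_that("a single rendered spot is found within half a voxel", {
  truth <- matrix(c(8.3, 12.6, 10.2), 1)
  a <- renderSpotStack(c(17, 25, 25), truth, amps = 100, sigVox)
  s <- detectSpots(imageField(a, voxel), sigXy, sigZ, threshold = 10)
  expect_equal(nrow(s), 1L)
  expect_lt(max(abs(c(s$z, s$y, s$x) - truth)), 0.5)
  ## amplitude normalization: a unit spot filters to ~1
  expect_lt(abs(s$amplitude / 100 - 1), 0.2)
})

test_that("detection is translation-equivariant and scale-covariant", {
  set.seed(3)
  truth <- cbind(runif(6, 5, 11), runif(6, 6, 26), runif(6, 6, 26))
  a <- renderSpotStack(c(16, 32, 32), truth, rep(1, 6), sigVox)
  s1 <- detectSpots(imageField(a, voxel), sigXy, sigZ, 0.3)
  ## translate by whole voxels
  b <- array(0, dim(a))
  b[3:16, 4:32, 2:32] <- a[1:14, 1:29, 1:31]
  s2 <- detectSpots(imageField(b, voxel), sigXy, sigZ, 0.3)
  expect_equal(nrow(s1), nrow(s2))
  o1 <- order(s1$x); o2 <- order(s2$x)
  expect_equal(s2$z[o2] - s1$z[o1], rep(2, nrow(s1)), tolerance = 0.1)
  expect_equal(s2$y[o2] - s1$y[o1], rep(3, nrow(s1)), tolerance = 0.1)
  ## multiplying intensities and threshold by the same constant
  s3 <- detectSpots(imageField(a * 50, voxel), sigXy, sigZ, 0.3 * 50)
  expect_equal(nrow(s3), nrow(s1))
  expect_equal(s3$z, s1$z, tolerance = 1e-6)
})

test_that("dense random fields are recovered with high recall and precision", {
  ## ~200 spots with pairwise spacing >= 4 sigma, SNR 5
  set.seed(9)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < 200) {
    cand <- c(runif(1, 4, 60), runif(1, 4, 124), runif(1, 4, 124))
    if (nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - cand)^2 / sigVox^2))) >= 4)
      pts <- rbind(pts, cand)
  }
  amps <- runif(200, 0.9, 1.1)
  a <- renderSpotStack(c(64, 128, 128), pts, amps, sigVox,
                       background = 0.05, noiseSd = 0.2, seed = 10)
  s <- detectSpots(imageField(a, voxel), sigXy, sigZ, threshold = 0.5)
  det <- cbind(s$z * voxel[1], s$y * voxel[2], s$x * voxel[3])
  tru <- cbind(pts[, 1] * voxel[1], pts[, 2] * voxel[2], pts[, 3] * voxel[3])
  matched <- matchSpots(det, tru, radius = 2 * sigXy)
  expect_gte(matched / nrow(tru), 0.95)   # recall
  expect_gte(matched / nrow(det), 0.95)   # precision
})

test_that("threshold suggestion finds the gap between signal and noise", {
  set.seed(21)
  pts <- cbind(runif(40, 4, 28), runif(40, 4, 60), runif(40, 4, 60))
  a <- renderSpotStack(c(32, 64, 64), pts, rep(1, 40), sigVox,
                       background = 0.05, noiseSd = 0.1, seed = 22)
  sug <- suggestThreshold(imageField(a, voxel), sigXy, sigZ)
  expect_true(sug$flat)
  expect_gt(sug$threshold, 0.25)  # above the noise-peak amplitudes
  expect_lt(sug$threshold, 0.9)   # below the signal mode
  ## counts decrease monotonically with threshold
  expect_true(all(diff(sug$curve$count) <= 0))
  ## pure noise: warning flag set
  n <- renderSpotStack(c(24, 32, 32), matrix(numeric(0), 0, 3), numeric(0),
                       sigVox, background = 0.1, noiseSd = 0.1, seed = 5)
  expect_warning(sugN <- suggestThreshold(imageField(n, voxel), sigXy, sigZ),
                 "plateau")
  expect_false(sugN$flat)
})

test_that("ROI counting uses inclusive bounds and first-match overlap", {
  spots <- data.frame(z = c(rep(5, 10), 12), y = c(rep(6, 10), 3),
                      x = c(1:10, 4), amplitude = 1, raw = 1)
  roi <- roiBox3D(c(0, 0, 0), c(10, 10, 10), "A")
  tab <- countInRois(spots, list(roi))
  expect_equal(tab$count, 10L)
  ## a spot exactly on a face counts as inside
  edge <- data.frame(z = 10, y = 5, x = 5, amplitude = 1, raw = 1)
  expect_equal(countInRois(edge, list(roi))$count, 1L)
  ## overlapping ROIs: first in list order wins
  rois <- list(roiBox3D(c(0, 0, 0), c(6, 6, 6), "first"),
               roiBox3D(c(0, 0, 0), c(10, 10, 10), "second"))
  tab2 <- countInRois(data.frame(z = 5, y = 5, x = 5, amplitude = 1, raw = 1),
                      rois)
  expect_equal(tab2$count, c(1L, 0L))
  ## biological box volume
  img <- imageField(array(0, c(20, 20, 20)), c(0.4, 0.2, 0.2), 2)
  v <- countInRois(spots[1, ], list(roiBox3D(c(0, 0, 0), c(9, 9, 9), "A")),
                   img)$volumeUm3
  expect_equal(v, (10 * 0.2) * (10 * 0.1) * (10 * 0.1))
})

test_that("per-cell counts on FISH phantoms recover the truth", {
  ph <- generateFishPhantom(nCells = 12, lambda = 8, voxelSize = voxel,
                            minSpacingUm = 4 * sigXy, snr = Inf, seed = 31)
  s <- detectSpots(ph$img, sigXy, sigZ, threshold = 0.4)
  counts <- countInRois(s, ph$rois, ph$img)
  expect_equal(counts$count, ph$cellCounts$count)
  ## noisy version within Poisson-scale error
  phN <- generateFishPhantom(nCells = 12, lambda = 8, voxelSize = voxel,
                             minSpacingUm = 4 * sigXy, snr = 5, seed = 31)
  sN <- detectSpots(phN$img, sigXy, sigZ, threshold = 0.4)
  cN <- countInRois(sN, phN$rois, phN$img)
  expect_lt(mean(abs(cN$count - phN$cellCounts$count)), 1.5)
})

test_that("mask fractions follow the configured nuclear fraction", {
  ph <- generateFishPhantom(nCells = 30, lambda = 15, voxelSize = voxel,
                            nuclearFraction = 0.1, snr = Inf, seed = 41)
  s <- detectSpots(ph$img, sigXy, sigZ, threshold = 0.4)
  expect_equal(fractionInMask(s[0, ], ph$nucleiMask), NA_real_)
  fSoma <- fractionInMask(s, ph$somaMask)
  expect_gt(fSoma, 0.95)
  fNuc <- fractionInMask(s, ph$nucleiMask)
  nTot <- nrow(s)
  expect_lt(abs(fNuc - 0.1), 0.1 * 3 / sqrt(nTot) + 0.05)
})
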