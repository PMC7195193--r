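fastSpec <- function(...) phantomSpec(canvasUm = c(80, 80), nNuclei = 25, ...)

test_that("identity deformation renders identical pre/post frames", {
  sp <- fastSpec(sigmaD = 0, eTrue = 1, thetaPost = 0,
                 translationPost = c(0, 0), noiseGain = 0,
                 noiseSigmaRead = 0, seed = 2)
  ph <- generatePhantom(sp)
  expect_identical(imgData(ph$pre), imgData(ph$post))
})

test_that("a pure similarity scales every truth pair distance exactly", {
  sp <- fastSpec(sigmaD = 0, eTrue = 3.3, noiseGain = 0, noiseSigmaRead = 0,
                 seed = 5)
  ph <- generatePhantom(sp)
  dpre <- dist(ph$truth@punctaPre)
  dpost <- dist(ph$truth@punctaPost)
  expect_equal(as.numeric(dpost / dpre), rep(3.3, length(dpre)),
               tolerance = 1e-9)
  expect_equal(ph$truth@midlineLengthPost / ph$truth@midlineLengthPre, 3.3,
               tolerance = 1e-3)
  expect_equal(ph$truth@gelContourPost / ph$truth@gelContourPre, 3.3)
})

test_that("post truth coordinates equal the deformation applied to pre truth", {
  sp <- fastSpec(sigmaD = 1.5, ell = 15, seed = 8)
  ph <- generatePhantom(sp)
  mapped <- applyDeformation(ph$truth@deformation, ph$truth@punctaPre)
  expect_equal(mapped, ph$truth@punctaPost, tolerance = 1e-12)
  ## puncta respect the minimum spacing
  expect_gte(min(dist(ph$truth@punctaPre)), sp@punctaMinSpacing)
})

test_that("seeds fully determine output; noise varies at fixed geometry", {
  a <- generatePhantom(fastSpec(seed = 3))
  b <- generatePhantom(fastSpec(seed = 3))
  expect_identical(imgData(a$pre), imgData(b$pre))
  expect_identical(imgData(a$post), imgData(b$post))
  expect_identical(a$truth@punctaPre, b$truth@punctaPre)
  ## a different seed changes the geometry
  c_ <- generatePhantom(fastSpec(seed = 4))
  expect_false(identical(a$truth@punctaPre, c_$truth@punctaPre))
})

test_that("rendered puncta maxima sit on truth coordinates without noise", {
  sp <- fastSpec(sigmaD = 0, eTrue = 1, thetaPost = 0,
                 translationPost = c(0, 0), noiseGain = 0, noiseSigmaRead = 0,
                 nPuncta = 12, punctaMinSpacing = 3,
                 punctaAmplitude = c(3, 4), seed = 6)
  ph <- generatePhantom(sp)
  A <- imgData(ph$pre)
  px <- pixelSize(ph$pre)[1]
  for (i in seq_len(nrow(ph$truth@punctaPre))) {
    v <- round(ph$truth@punctaPre[i, ] / px) + 1
    win <- A[(v[1] - 2):(v[1] + 2), (v[2] - 2):(v[2] + 2)]
    ctr <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(ctr - c(3, 3))), 1)
  }
})

test_that("phantom mask means reproduce the configured contrast at zero noise", {
  ## two-level construction: texture off so plateau levels are exact
  sp <- fastSpec(noiseGain = 0, noiseSigmaRead = 0, textureAmplitude = 0,
                 seed = 4)
  ph <- generatePhantom(sp)
  A <- imgData(ph$pre)
  ms <- mean(A[imgData(ph$truth@signalMask)])
  mb <- mean(A[imgData(ph$truth@backgroundMask)])
  expected <- (sp@backgroundIntensity + sp@nerveRingBrightness *
                 sp@bodyIntensity) /
    (sp@backgroundIntensity + sp@bodyIntensity)
  expect_lt(abs(ms / mb - expected) / expected, 0.02)
})

test_that("FISH phantom cell counts are Poisson draws that sum correctly", {
  ph <- generateFishPhantom(nCells = 20, lambda = 5,
                            voxelSize = c(0.4, 0.2, 0.2), snr = Inf, seed = 12)
  expect_equal(nrow(ph$spots), sum(ph$cellCounts$count))
  expect_lt(abs(mean(ph$cellCounts$count) - 5), 3 * sqrt(5 / 20))
  ## per-cell truth equals the spots assigned to that cell
  tab <- table(factor(ph$spots$cell, levels = ph$cellCounts$label))
  expect_equal(as.integer(tab), ph$cellCounts$count)
})

test_that("the pair-error oracle has the analytic limiting behaviour", {
  ## zero field: no measurement error at any length
  d0 <- makeDeformation(c(100, 100), sigmaD = 0, ell = 15)
  expect_equal(expectedPairError(d0, c(5, 20), 1000, 1)$rmsError, c(0, 0),
               tolerance = 1e-10)
  ## smooth field: error grows with L below the correlation length
  d1 <- makeDeformation(c(200, 200), sigmaD = 1, ell = 15, seed = 7)
  pe <- expectedPairError(d1, c(5, 10, 20), nMc = 4000, seed = 1)
  expect_true(all(diff(pe$rmsError) > 0))
  ## far beyond the correlation length the error plateaus near
  ## sqrt(2) * sigmaD (independent endpoints)
  plateau <- expectedPairError(d1, 150, nMc = 6000, seed = 2)$rmsError
  expect_lt(abs(plateau - sqrt(2)) / sqrt(2), 0.25)
})
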