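test_that("crops are square in biological units and idempotent", {
  img <- imageField(matrix(runif(400 * 400), 400, 400), 0.25)
  cr <- cropRegion(img, c(200, 200), side = 50)
  expect_equal(dim(cr), c(200L, 200L))
  ## at E = 2, the same biological side needs twice the pixels
  img2 <- imageField(matrix(0, 900, 900), 0.25, expansionFactor = 2)
  expect_equal(dim(cropRegion(img2, c(450, 450), 50)), c(400L, 400L))
  ## idempotent: cropping the crop at its own centre changes nothing
  cr2 <- cropRegion(cr, c(100, 100), side = 50)
  expect_equal(imgData(cr2), imgData(cr))
  ## a symmetric image yields a symmetric centred crop
  sym <- outer(abs(-49.5:49.5), abs(-49.5:49.5))
  crS <- cropRegion(imageField(sym, 0.5), c(50, 50), side = 20)
  expect_equal(imgData(crS), imgData(crS)[nrow(crS):1, ])
  expect_warning(cropRegion(img, c(5, 5), 50), "clipped")
})

test_that("percentile masks follow order statistics with inclusive ties", {
  vals <- matrix(sample(seq_len(10000)), 100, 100)  # all distinct
  crop <- imageField(vals, 0.25)
  m <- percentileMasks(crop, crop, pSignal = 98, pBg = c(25, 75))
  expect_equal(sum(imgData(m$signal)), 200L)          # ceiling(2%) by >=
  expect_equal(sum(imgData(m$background)), 5000L)     # middle half
  ## uniform crop: all pixels tie, signal mask covers everything
  u <- imageField(matrix(3, 50, 50), 0.25)
  mu <- percentileMasks(u, u)
  expect_true(all(imgData(mu$signal)))
  ## linear ramp: the band covers the middle half of intensities
  ramp <- imageField(matrix(seq(0, 1, length.out = 400), 20, 20), 0.25)
  mr <- percentileMasks(ramp, ramp, 98, c(25, 75))
  kept <- imgData(ramp)[imgData(mr$background)]
  expect_equal(length(kept), 200L)
  expect_gt(min(kept), 0.24)
  expect_lt(max(kept), 0.76)
  expect_error(percentileMasks(u, u, pSignal = 101), "pSignal|percent")
})

test_that("SBR is the ratio of masked means with expected invariances", {
  sig <- imageField(matrix(c(rep(1000, 50), rep(100, 950)), 25, 40), 0.25)
  bg <- imageField(matrix(100, 25, 40), 0.25)
  masks <- list(signal = mask(imgData(sig) == 1000, "signal"),
                background = mask(imgData(bg) == 100, "background"))
  r <- sbr(sig, bg, masks)
  expect_equal(r$sbr, 10)
  ## identity: same crop, same mask
  rs <- sbr(bg, bg, list(signal = masks$background,
                         background = masks$background))
  expect_equal(rs$sbr, 1)
  ## scale invariance
  sig2 <- imageField(imgData(sig) * 2, 0.25)
  bg2 <- imageField(imgData(bg) * 2, 0.25)
  expect_equal(sbr(sig2, bg2, masks)$sbr, 10)
  ## zero background -> infinity sentinel with a warning
  zb <- imageField(matrix(0, 25, 40), 0.25)
  expect_warning(rz <- sbr(sig, zb, list(signal = masks$signal,
                                         background = masks$background)))
  expect_equal(rz$sbr, Inf)
})

test_that("phantom contrast is recovered through percentile masks", {
  for (contrast in c(5, 20)) {
    sp <- phantomSpec(nerveRingBrightness = contrast, backgroundIntensity = 0,
                      textureAmplitude = 0, nPuncta = 0, nNuclei = 0,
                      noiseGain = 0, noiseSigmaRead = 0.05, seed = 7)
    ph <- generatePhantom(sp)
    sigM <- imgData(ph$truth@signalMask)
    ringPx <- which(sigM, arr.ind = TRUE)
    ringCtr <- colMeans(ringPx) - 1
    ## a deep-interior body point (eroded mask) away from the ring
    er <- EBImage::erode(EBImage::Image(imgData(ph$truth@foregroundMask) * 1),
                         EBImage::makeBrush(25, "disc")) > 0.5
    bodyPx <- which(er & imgData(ph$truth@backgroundMask), arr.ind = TRUE)
    d2 <- rowSums((t(t(bodyPx - 1)) - matrix(ringCtr, nrow(bodyPx), 2,
                                             byrow = TRUE))^2)
    bodyCtr <- bodyPx[which.max(d2), ] - 1
    sigCrop <- cropRegion(ph$pre, ringCtr, side = 10)
    bgCrop <- cropRegion(ph$pre, bodyCtr, side = 8)
    r <- sbr(sigCrop, bgCrop, percentileMasks(sigCrop, bgCrop, 98, c(25, 75), rankSmoothPx = 1))
    expect_lt(abs(r$sbr - contrast) / contrast, 0.1)
  }
})
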