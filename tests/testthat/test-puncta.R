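test_that("profile extraction samples the image along the polyline", {
  img <- imageField(matrix(7, 40, 40), 0.2)
  p <- extractProfile(img, cbind(c(20, 20), c(5, 35)))
  expect_true(all(abs(p@intensity - 7) < 1e-12))
  expect_equal(p@spacingUm, 0.2)

  ## a rendered Gaussian punctum peaks where the line crosses it
  y <- 0:39; x <- 0:39
  g <- exp(-outer((y - 20)^2, rep(1, 40)) / 8) *
    exp(-outer(rep(1, 40), (x - 24)^2) / 8)
  pg <- extractProfile(imageField(g, 0.2), cbind(c(20, 20), c(2, 38)))
  expect_lt(abs(which.max(pg@intensity) - (24 - 2 + 1)), 1.5)

  ## width-3 averaging on a vertical gradient returns the centre row
  grad <- matrix(rep(0:39, 40), 40, 40)   # value = row index
  pw <- extractProfile(imageField(grad, 0.2), cbind(c(15, 15), c(5, 35)),
                       width = 3)
  expect_true(all(abs(pw@intensity - 15) < 1e-9))
  expect_error(extractProfile(img, cbind(c(10, 50), c(0, 0))), "outside")
})

test_that("normalization maps to [0,1] and the moving window shrinks at ends", {
  p <- lineProfile(c(2, 4, 6, 6, 2), spacingUm = 1)
  ns <- normalizeSmooth(p)
  ## hand arithmetic on the first three samples of the normalized profile
  ## [0, .5, 1, 1, 0]: ends average 2 samples, interior 3
  expect_equal(ns@intensity, c(0.25, 0.5, 5 / 6, 2 / 3, 0.5))
  expect_equal(normalizeSmooth(lineProfile(c(2, 4, 6, 8, 10)))@intensity[1:3],
               c(0.125, 0.25, 0.5))
  ## constant profile is a valid no-punctum observation
  expect_equal(normalizeSmooth(lineProfile(rep(5, 6)))@intensity, rep(0, 6))
  ## bounded for arbitrary inputs
  set.seed(1)
  for (i in 1:20) {
    r <- normalizeSmooth(lineProfile(runif(20, 0, 100)))@intensity
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("peak counting follows topographic prominence with end boundaries", {
  ## two unit triangles separated by a zero valley
  x <- c(0, 0.5, 1, 0.5, 0, 0.5, 1, 0.5, 0)
  rep_ <- countPeaks(lineProfile(x))
  expect_equal(rep_@count, 2L)
  expect_equal(rep_@prominences, c(1, 1))
  ## a secondary bump of prominence 0.005 is rejected at the 0.01 threshold
  y <- c(0, 0.5, 1, 0.6, 0.605, 0.6, 0.3, 0)
  expect_equal(waterLevelProminence(y, 5), 0.005)
  expect_equal(countPeaks(lineProfile(y))@count, 1L)
  ## monotone ramp has no interior maxima
  expect_equal(countPeaks(lineProfile(seq(0, 1, length.out = 10)))@count, 0L)
  ## a flat-topped plateau counts once, at its midpoint
  z <- c(0, 1, 1, 1, 0)
  rp <- countPeaks(lineProfile(z))
  expect_equal(rp@count, 1L)
  expect_equal(rp@peaks, 3L)
  expect_error(countPeaks(lineProfile(x), prominenceThreshold = 1.5),
               "threshold")
})

test_that("prominence matches the exhaustive water-level oracle", {
  set.seed(42)
  for (i in 1:400) {
    n <- sample(5:12, 1)
    x <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(countPeaks(lineProfile(x), 0.01)@count, oraclePeakCount(x),
                 info = paste(x, collapse = ","))
    ## per-peak prominences agree too
    cand <- oracleLocalMaxima(x)
    if (length(cand)) {
      promPkg <- wormExM:::peakProminence(x, cand)
      promOra <- vapply(cand, function(m) waterLevelProminence(x, m),
                        numeric(1))
      expect_equal(promPkg, promOra)
    }
  }
})

test_that("peak count is invariant to reversal and pre-normalization shifts", {
  set.seed(11)
  for (i in 1:50) {
    x <- runif(15, 0, 10)
    c0 <- countPeaks(normalizeSmooth(lineProfile(x)))@count
    cR <- countPeaks(normalizeSmooth(lineProfile(rev(x))))@count
    cS <- countPeaks(normalizeSmooth(lineProfile(x + 5)))@count
    expect_equal(c0, cR)
    expect_equal(c0, cS)
  }
})

test_that("fold change is the through-origin slope with a ratio secondary", {
  expect_equal(foldChange(c(1, 2, 3), c(2, 4, 6))$slope, 2)
  ## hand arithmetic: sum(pre*post) = 2 + 8 + 21 = 31, sum(pre^2) = 14
  expect_equal(foldChange(c(1, 2, 3), c(2, 4, 7))$slope, 31 / 14)
  expect_equal(foldChange(c(4, 5, 6), c(4, 5, 6))$slope, 1)
  expect_equal(foldChange(c(1, 2, 3), c(2, 4, 7))$ratioOfSums, 13 / 6)
  expect_error(foldChange(c(0, 0, 0), c(1, 2, 3)), "zero")
})
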