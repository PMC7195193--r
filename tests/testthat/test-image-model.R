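test_that("biological unit conversion divides absolute lengths by E", {
  img <- imageField(matrix(0, 8, 8), pixelSize = 0.2, expansionFactor = 4)
  expect_equal(toBiologicalUnits(100, img), 5)
  expect_equal(toBiologicalUnits(33, imageField(matrix(0, 4, 4), 0.3, 3.3)),
               33 * 0.3 / 3.3)
  ## E = 1 leaves pixel lengths unchanged
  img1 <- imageField(matrix(0, 4, 4), 0.25)
  expect_equal(toBiologicalUnits(17, img1), 17 * 0.25)
  ## linear in the pixel count, inverse in E
  for (E in c(1.5, 2, 3.3)) {
    imgE <- imageField(matrix(0, 4, 4), 0.5, E)
    expect_equal(toBiologicalUnits(c(1, 2, 10), imgE),
                 c(1, 2, 10) * 0.5 / E)
  }
  ## anisotropic voxels use the per-axis size
  st <- imageField(array(0, c(3, 4, 4)), c(0.4, 0.1625, 0.1625), 2)
  expect_equal(toBiologicalUnits(10, st, axis = "z"), 10 * 0.4 / 2)
  expect_equal(toBiologicalUnits(10, st, axis = "x"), 10 * 0.1625 / 2)
})

test_that("TIFF round trips preserve data", {
  td <- withr::local_tempdir()
  ## all-zero 16-bit single page
  z <- imageField(matrix(0, 64, 64), 0.1625)
  f <- file.path(td, "zeros.tif")
  writeImageField(z, f, bitsPerSample = 16)
  rz <- readImageField(f, 0.1625)
  expect_equal(imgData(rz), imgData(z) * 1)
  expect_equal(dim(rz), c(64L, 64L))
  ## random uint16 round trip, bit exact
  set.seed(7)
  u <- matrix(sample.int(65536, 32 * 48, replace = TRUE) - 1, 32, 48)
  f2 <- file.path(td, "u16.tif")
  writeImageField(imageField(u, 0.2), f2, 16)
  expect_equal(imgData(readImageField(f2, 0.2)), u)
  ## float32 within machine precision
  fl <- matrix(runif(16 * 16), 16, 16)
  f3 <- file.path(td, "f32.tif")
  writeImageField(imageField(fl, 0.2), f3, 32)
  expect_equal(imgData(readImageField(f3, 0.2)), fl, tolerance = 1e-6)
  ## multi-page becomes a 3D (z, y, x) stack
  st <- array(sample.int(256, 3 * 32 * 32, replace = TRUE) - 1, c(3, 32, 32))
  f4 <- file.path(td, "stack.tif")
  writeImageField(imageField(st, 0.2), f4, 8)
  r4 <- readImageField(f4, c(0.4, 0.2, 0.2))
  expect_equal(dim(r4), c(3L, 32L, 32L))
  expect_equal(imgData(r4), st)
})

test_that("validity rules reject malformed objects", {
  expect_error(imageField(matrix(-1, 4, 4), 0.2), "intensities")
  expect_error(imageField(matrix(1, 4, 4), -0.2), "pixelSize")
  expect_error(imageField(matrix(1, 4, 4), 0.2, expansionFactor = 0),
               "expansionFactor")
  expect_error(imageField(matrix(NaN, 4, 4), 0.2), "finite")
  expect_error(readImageField("no/such/file.tif", 0.2), "cannot read")
  fOk <- tempfile(fileext = ".tif")
  writeImageField(imageField(matrix(0, 4, 4), 1), fOk, 16)
  expect_error(readImageField(fOk, 0), "positive")
  expect_error(roiBox3D(c(3, 0, 0), c(1, 5, 5)), "minCorner")
  expect_error(mask(matrix(TRUE, 2, 2), parent = imageField(matrix(0, 4, 4), 1)),
               "shape")
})

test_that("ROI tables round trip through CSV", {
  td <- withr::local_tempdir()
  f <- file.path(td, "rois.csv")
  df <- data.frame(label = c("RIS", "RMED"), zmin = c(0, 4), ymin = c(1, 5),
                   xmin = c(2, 6), zmax = c(3, 8), ymax = c(4, 9),
                   xmax = c(5, 10))
  write.csv(df, f, row.names = FALSE)
  rois <- readRoiCsv(f)
  expect_length(rois, 2)
  expect_equal(rois[[1]]@label, "RIS")
  expect_equal(rois[[2]]@minCorner, c(4, 5, 6))
})
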