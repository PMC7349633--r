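test_that("the vegetation index is the NIR minus scaled red difference", {
  nir <- matrix(0.8, 2, 2); red <- matrix(0.1, 2, 2)
  cube <- miniCube(nir, red)
  expect_equal(rasterData(computeMdvi(cube, 2.5))[1, 1], 0.55)
  # degenerate coefficient: the index is the NIR band itself
  expect_equal(rasterData(computeMdvi(cube, 0)), nir)
  # identical bands cancel at alpha = 1
  cube2 <- miniCube(red, red)
  expect_equal(rasterData(computeMdvi(cube2, 1)), matrix(0, 2, 2))
  expect_error(computeMdvi(miniCube(nir, red), 2.5, nir = 900),
               class = "spadspec_BandNotFound")
})

test_that("rescaling to 256 levels is the rounded min-max affine", {
  r <- rescaleToLevels(matrix(c(-1, 0, 1), 1, 3))
  # rounding half-up: 127.5 -> 128
  expect_identical(r$data, matrix(c(0L, 128L, 255L), 1, 3))
  expect_false(r$constant)

  # oracle: direct affine formula per pixel on random data
  set.seed(3)
  img <- matrix(rnorm(64), 8, 8)
  rr <- rescaleToLevels(img)
  oracle <- floor((img - min(img)) / (max(img) - min(img)) * 255 + 0.5)
  expect_equal(rr$data, matrix(as.integer(oracle), 8, 8))

  cst <- rescaleToLevels(matrix(4.2, 3, 3))
  expect_true(cst$constant)
  expect_identical(cst$data, matrix(0L, 3, 3))

  ident <- matrix(c(0, 100, 255), 1, 3)
  expect_identical(rescaleToLevels(ident)$data,
                   matrix(c(0L, 100L, 255L), 1, 3))
})

test_that("Otsu picks the maximal between-class variance threshold", {
  # perfectly bimodal: all 255s in the foreground
  img <- matrix(rep(c(0L, 255L), each = 50), 10, 10)
  t1 <- otsuThreshold(img)
  expect_true(all(img[img > t1] == 255L))
  expect_true(all(img[img <= t1] == 0L))

  # three-level image against the exhaustive scan
  img2 <- c(rep(20L, 10), rep(30L, 10), rep(200L, 10))
  expect_equal(otsuThreshold(img2), bruteOtsu(img2))

  expect_error(otsuThreshold(matrix(5L, 4, 4)),
               class = "spadspec_ConstantImage")
})

test_that("Otsu agrees with the exhaustive oracle on random images", {
  set.seed(99)
  for (i in 1:25) {
    img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    expect_identical(otsuThreshold(img), bruteOtsu(img))
  }
  # clustered images exercise tie regions more than uniform noise
  for (i in 1:10) {
    img <- matrix(sample(c(10:14, 200:210), 256, replace = TRUE), 16, 16)
    expect_identical(otsuThreshold(img), bruteOtsu(img))
  }
})

test_that("binary median filtering matches per-window counting", {
  # isolated foreground pixel disappears
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  expect_equal(sum(rasterData(medianFilterMask(BinaryMask(m)))), 0)

  # constant mask is unchanged
  ones <- BinaryMask(matrix(1L, 4, 4))
  expect_equal(rasterData(medianFilterMask(ones)), matrix(1L, 4, 4))

  # 3x3 solid block in 5x5 zeros: corners eroded, per the explicit count
  blk <- matrix(0L, 5, 5); blk[2:4, 2:4] <- 1L
  got <- rasterData(medianFilterMask(BinaryMask(blk)))
  expect_equal(got, bruteMedianFilter(blk))
  expect_equal(got[2, 2], 0L)  # corner gone
  expect_equal(got[3, 3], 1L)  # center kept

  # random masks against the oracle, including a 5x5 window
  set.seed(12)
  for (i in 1:5) {
    m <- matrix(rbinom(100, 1, 0.5), 10, 10)
    expect_equal(rasterData(medianFilterMask(BinaryMask(m), 3L)),
                 bruteMedianFilter(m, 3L))
    expect_equal(rasterData(medianFilterMask(BinaryMask(m), 5L)),
                 bruteMedianFilter(m, 5L))
  }

  expect_error(medianFilterMask(ones, 4L), class = "spadspec_BadWindow")
  expect_error(medianFilterMask(ones, 1L), class = "spadspec_BadWindow")
})

test_that("the largest connected domain is kept and counted", {
  m <- matrix(0L, 8, 10)
  m[2:4, 2:5] <- 1L           # 12 pixels
  m[6:7, 7:9] <- 1L; m[7, 9] <- 0L  # 5 pixels
  lc <- largestComponent(BinaryMask(m))
  expect_equal(lc$componentCount, 2L)
  expect_equal(sort(lc$componentAreas), c(5, 12))
  expect_equal(lc$largestComponentArea, 12)
  expect_equal(rasterData(lc$mask), bruteLargest(m))

  # single blob: identity
  single <- matrix(0L, 4, 4); single[2:3, 2:3] <- 1L
  expect_equal(rasterData(largestComponent(BinaryMask(single))$mask), single)

  expect_error(largestComponent(BinaryMask(matrix(0L, 3, 3))),
               class = "spadspec_EmptyMask")
})

test_that("connectivity controls diagonal adjacency", {
  m <- matrix(0L, 3, 3); m[1, 1] <- 1L; m[2, 2] <- 1L
  lc8 <- largestComponent(BinaryMask(m), 8L)
  expect_equal(lc8$componentCount, 1L)
  expect_equal(sum(rasterData(lc8$mask)), 2)
  lc4 <- largestComponent(BinaryMask(m), 4L)
  expect_equal(lc4$componentCount, 2L)
  expect_equal(sum(rasterData(lc4$mask)), 1)
  # equal areas: raster-order tie-break keeps the earlier pixel
  expect_equal(rasterData(lc4$mask)[1, 1], 1L)
})

test_that("component labeling agrees with flood fill on random masks", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(rbinom(256, 1, 0.35), 16, 16)
    if (sum(m) == 0) next
    for (conn in c(4L, 8L)) {
      lab <- floodLabel(m, conn)
      sizes <- tabulate(lab[lab > 0])
      lc <- largestComponent(BinaryMask(m), conn)
      expect_equal(lc$componentCount, max(lab))
      expect_equal(sort(lc$componentAreas), sort(as.numeric(sizes)))
      expect_equal(lc$largestComponentArea, max(sizes))
      if (sum(sizes == max(sizes)) == 1L)
        expect_equal(rasterData(lc$mask), bruteLargest(m, conn))
    }
  }
})

test_that("the full chain recovers the ground-truth plant on a clean scene", {
  bundle <- generateScene(sceneSpec(23))
  cal <- fitCalibration(extractBoardReading(bundle$cubeGrayscale,
                                            bundle$boardBoxes))
  refl <- suppressMessages(applyCalibration(bundle$cubeGrayscale, cal))
  seg <- segmentPlant(refl, alpha = 2.5)
  expect_equal(miou(bundle$plantMask, seg@precisionMask), 100)
  expect_identical(rasterData(seg@precisionMask),
                   rasterData(bundle$plantMask))
  # precision mask is one component inside the filtered preliminary mask
  filtered <- medianFilterMask(seg@preliminaryMask)
  expect_true(all(rasterData(seg@precisionMask) <= rasterData(filtered)))
  expect_equal(largestComponent(seg@precisionMask)$componentCount, 1L)
})

test_that("a weed patch larger than the plant wins the area heuristic", {
  spec <- sceneSpec(31, shape = c(80L, 80L),
                    plantCenter = c(0.35, 0.40), plantRadii = c(0.16, 0.15),
                    weedCenter = c(0.80, 0.60), weedRadii = c(0.22, 0.20))
  bundle <- generateScene(spec)
  seg <- segmentPlant(bundle$cubeReflectance, alpha = 2.5)
  # the kept domain is the weed, not the plant
  expect_equal(sum(rasterData(seg@precisionMask) *
                     rasterData(bundle$plantMask)), 0)
  expect_gt(sum(rasterData(seg@precisionMask) * bundle$objectMasks$weed), 0)
})

test_that("intersection-over-union follows the pixel-count definition", {
  a <- BinaryMask(matrix(1L, 2, 2))
  expect_equal(miou(a, a), 100)

  d1 <- BinaryMask(matrix(c(1, 1, 0, 0), 2, 2))
  d2 <- BinaryMask(matrix(c(0, 0, 1, 1), 2, 2))
  expect_equal(miou(d1, d2), 0)

  # 2x3 grid, two 2x2 blocks sharing one column: 2 / 6
  m1 <- matrix(0L, 2, 3); m1[, 1:2] <- 1L
  m2 <- matrix(0L, 2, 3); m2[, 2:3] <- 1L
  expect_equal(miou(BinaryMask(m1), BinaryMask(m2)), 100 * 2 / 6)

  expect_error(miou(BinaryMask(matrix(0L, 2, 2)), BinaryMask(matrix(0L, 2, 3))),
               class = "spadspec_ShapeMismatch")
  z <- BinaryMask(matrix(0L, 2, 2))
  expect_error(miou(z, z), class = "spadspec_EmptyUnion")
})

test_that("the accuracy score is symmetric and bounded", {
  set.seed(5)
  for (i in 1:10) {
    m1 <- matrix(rbinom(48, 1, 0.4), 6, 8)
    m2 <- matrix(rbinom(48, 1, 0.4), 6, 8)
    if (sum(m1 | m2) == 0) next
    a <- miou(BinaryMask(m1), BinaryMask(m2))
    expect_equal(a, miou(BinaryMask(m2), BinaryMask(m1)))
    expect_gte(a, 0); expect_lte(a, 100)
  }
})

test_that("the coefficient sweep reports the arg-max alpha", {
  bundle <- generateScene(sceneSpec(37, noiseSd = 0.02))
  cal <- fitCalibration(extractBoardReading(bundle$cubeGrayscale,
                                            bundle$boardBoxes))
  refl <- suppressMessages(applyCalibration(bundle$cubeGrayscale, cal))
  sweep <- alphaSweep(refl, bundle$plantMask)
  expect_equal(sweep$alpha, c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0))
  best <- attr(sweep, "bestAlpha")
  expect_equal(max(sweep$accuracy), sweep$accuracy[sweep$alpha == best])

  # scoring a mask against the segmentation that produced it is exact
  seg <- segmentPlant(refl, alpha = 2.5)
  sweep2 <- alphaSweep(refl, seg@precisionMask, alphas = 2.5)
  expect_equal(sweep2$accuracy, 100)
})
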