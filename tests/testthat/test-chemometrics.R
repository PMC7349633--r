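test_that("masked mean reflectance averages exactly the plant pixels", {
  set.seed(2)
  nir <- matrix(runif(12), 3, 4); red <- matrix(runif(12), 3, 4)
  cube <- miniCube(nir, red)
  all1 <- BinaryMask(matrix(1L, 3, 4))
  expect_equal(unname(extractMeanReflectance(cube, all1)),
               c(mean(red), mean(nir)))

  single <- matrix(0L, 3, 4); single[2, 3] <- 1L
  expect_equal(unname(extractMeanReflectance(cube, BinaryMask(single))),
               c(red[2, 3], nir[2, 3]))

  expect_error(extractMeanReflectance(cube, BinaryMask(matrix(0L, 3, 4))),
               class = "spadspec_EmptyMask")
  expect_error(extractMeanReflectance(cube, BinaryMask(matrix(1L, 2, 2))),
               class = "spadspec_ShapeMismatch")

  # reference profile: one entry per band, named by nm
  bundle <- generateScene(sceneSpec(41))
  v <- extractMeanReflectance(bundle$cubeReflectance, bundle$plantMask)
  expect_length(v, 25)
  expect_equal(names(v), as.character(wavelengths(defaultSensorProfile())))
})

test_that("SPXY splits at the prescribed calibration fraction", {
  tbl <- generateSpectraDataset(100, seed = 8)
  sp <- spxySplit(tbl)
  expect_length(sp$calibration, 67)
  expect_length(sp$validation, 33)
  expect_setequal(c(sp$calibration, sp$validation), 1:100)

  sp3 <- spxySplit(matrix(c(0, 1, 2), 3, 1), y = c(0, 1, 2))
  expect_length(sp3$calibration, 2)
  expect_length(sp3$validation, 1)

  expect_error(spxySplit(matrix(0, 2, 1), y = c(0, 1)),
               class = "spadspec_TooFewSamples")
})

test_that("SPXY selection is driven by the joint distances, not the row order", {
  set.seed(31)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  sp <- spxySplit(X, y)
  perm <- sample(20)
  spPerm <- spxySplit(X[perm, , drop = FALSE], y[perm])
  # same physical points selected, different row labels
  sel1 <- X[sp$calibration, ]
  sel2 <- X[perm[spPerm$calibration], ]
  expect_equal(sel1[order(sel1[, 1]), ], sel2[order(sel2[, 1]), ])

  # duplicating every sample leaves the covered X-range unchanged
  Xd <- rbind(X, X); yd <- c(y, y)
  spd <- spxySplit(Xd, yd)
  expect_equal(apply(Xd[spd$calibration, ], 2, range),
               apply(X[sp$calibration, ], 2, range))
})

test_that("full-rank PLS reproduces least squares", {
  # oracle: normal-equations regression
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(10:30, 1); p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
    bOls <- solve(crossprod(Xc), crossprod(Xc, yc))
    olsPred <- mean(y) + drop(Xc %*% bOls)
    model <- plsFit(X, y, nComponents = p)
    expect_equal(predict(model, X), olsPred, tolerance = 1e-8)
  }
})

test_that("a single latent factor is captured by one component", {
  set.seed(15)
  n <- 40; p <- 8
  t <- rnorm(n)
  w <- rnorm(p)
  X <- tcrossprod(t, w) + matrix(rnorm(n * p, sd = 1e-8), n, p)
  y <- 3 * t
  model <- plsFit(X, y, 1)
  expect_lt(sqrt(mean((predict(model, X) - y)^2)), 1e-6)

  sel <- plsSelectComponents(X, y, maxComponents = 5)
  expect_equal(sel$bestK, 1L)
  expect_lte(sel$rmsecv[sel$bestK], sel$rmsecv[length(sel$rmsecv)])
})

test_that("degenerate PLS inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(plsFit(X, rep(1, 10), 1), class = "spadspec_DegenerateTarget")
  expect_error(plsFit(X, rnorm(10), 0), class = "spadspec_BadComponents")
  expect_error(plsFit(X, rnorm(10), 5), class = "spadspec_BadComponents")
})

test_that("the reliability index separates informative from noise bands", {
  # threshold 0 keeps everything
  tbl <- generateSpectraDataset(50, seed = 61, nLatent = 0)
  X <- spectraMatrix(tbl); wl <- tableWavelengths(tbl)
  uve0 <- uveSelect(X, tbl$spad, 3, threshold = 0, wavelengths = wl)
  expect_setequal(uve0@selectedWavelengths, wl)

  # strong three-band signal among pure-noise bands, default threshold 1.0
  for (s in 1:3) {
    tbl <- generateSpectraDataset(200, seed = 70 + s, nLatent = 0)
    X <- spectraMatrix(tbl)
    uve <- uveSelect(X, tbl$spad, 5, wavelengths = tableWavelengths(tbl))
    inf <- attr(tbl, "informativeBands")
    expect_true(all(inf %in% uve@selectedWavelengths))
    noise <- setdiff(tableWavelengths(tbl), inf)
    expect_lte(sum(uve@selectedWavelengths %in% noise) / length(noise), 0.2)
  }
})

test_that("noise-augmented selection derives its cutoff from the noise block", {
  tbl <- generateSpectraDataset(120, seed = 81, nLatent = 0)
  X <- spectraMatrix(tbl)
  set.seed(1)
  uve <- uveSelect(X, tbl$spad, 5, noiseAugment = TRUE,
                   wavelengths = tableWavelengths(tbl))
  expect_gt(uve@threshold, 0)
  expect_true(all(attr(tbl, "informativeBands") %in%
                    uve@selectedWavelengths))
})

test_that("metrics follow the summation definitions", {
  # hand arithmetic: SSE = 16, SST = 5 -> R2 = -2.2; RMSE = sqrt(16/4) = 2
  m <- evaluateModel(c(1, 2, 3, 4), c(1, 2, 3, 8))
  expect_equal(m@r2, 1 - 16 / 5)
  expect_equal(m@rmse, 2.0)
  expect_equal(m@rpd, sd(c(1, 2, 3, 4)) / 2.0)

  # predicting the mean everywhere: R2 = 0
  y <- c(2, 4, 6, 8)
  m0 <- evaluateModel(y, rep(mean(y), 4))
  expect_equal(m0@r2, 0)

  # perfect prediction: RPD undefined
  expect_error(evaluateModel(y, y), class = "spadspec_DegenerateMetric")
  expect_error(evaluateModel(rep(3, 4), c(1, 2, 3, 4)),
               class = "spadspec_DegenerateTarget")
  expect_error(evaluateModel(1:3, 1:2), class = "spadspec_BadInput")
})

test_that("the RPD grade bands are respected at their boundaries", {
  y <- c(1, 2, 3, 4)
  p <- c(1.1, 2.1, 2.9, 3.9)
  rmse <- sqrt(mean((y - p)^2))
  expect_equal(evaluateModel(y, p, referenceStd = 2.5 * rmse)@grade, "good")
  expect_equal(evaluateModel(y, p, referenceStd = 2.0 * rmse)@grade, "middle")
  expect_equal(evaluateModel(y, p, referenceStd = 1.4 * rmse)@grade, "middle")
  expect_equal(evaluateModel(y, p, referenceStd = 1.0 * rmse)@grade, "poor")
})

test_that("metrics are invariant under a common shift of both vectors", {
  set.seed(44)
  y <- rnorm(20, 40, 8); p <- y + rnorm(20)
  m1 <- evaluateModel(y, p)
  m2 <- evaluateModel(y + 100, p + 100)
  expect_equal(m1@rmse, m2@rmse)
  expect_equal(m1@r2, m2@r2)
  expect_lte(m1@r2, 1)
})

test_that("spectra tables round trip through CSV", {
  tbl <- generateSpectraDataset(10, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectraTable(tbl, path)
  back <- readSpectraTable(path)
  expect_equal(back$sample_id, tbl$sample_id)
  expect_equal(spectraMatrix(back), spectraMatrix(tbl), tolerance = 1e-12)
  expect_equal(tableWavelengths(back), wavelengths(defaultSensorProfile()))
})
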