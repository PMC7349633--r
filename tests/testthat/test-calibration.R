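# closed-form two-parameter OLS, independent of the fitting code
olsLine <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  a <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = a, intercept = mean(y) - a * mean(x))
}

boardCube <- function(grays, h = 4, w = 12) {
  # four constant panels of width w/4 in a single 2-band cube
  arr <- array(0, dim = c(h, w, 2))
  pw <- w / 4
  for (k in 1:4)
    arr[, ((k - 1) * pw + 1):(k * pw), ] <- grays[k]
  SpectralCube(arr, c(681, 888))
}

boardBoxes4 <- function(h = 4, w = 12) {
  pw <- w / 4
  lapply(0:3, function(k) list(row = 1L, col = k * pw + 1L,
                               height = h, width = pw))
}

test_that("board readings average the selected rectangles per band", {
  cube <- boardCube(c(800, 600, 400, 0))
  reading <- extractBoardReading(cube, boardBoxes4())
  expect_equal(reading@meanGray[, 1], c(800, 600, 400, 0))
  expect_equal(reading@meanGray[, 2], c(800, 600, 400, 0))

  # non-constant patch: plain arithmetic mean (100+200+300+400)/4 = 250
  arr <- array(0, dim = c(2, 4, 1))
  arr[, 1:2, 1] <- matrix(c(100, 200, 300, 400), 2, 2)
  c2 <- SpectralCube(arr, 681)
  r2 <- extractBoardReading(
    c2, list(list(row = 1, col = 1, height = 2, width = 2),
             list(row = 1, col = 3, height = 2, width = 2)),
    nominal = c(1, 0))
  expect_equal(r2@meanGray[, 1], c(250, 0))
})

test_that("degenerate rectangles are rejected", {
  cube <- boardCube(c(800, 600, 400, 0))
  bad <- boardBoxes4()
  bad[[2]]$width <- -1
  expect_error(extractBoardReading(cube, bad), class = "spadspec_BadRegion")
  bad2 <- boardBoxes4()
  bad2[[1]]$col <- 100
  expect_error(extractBoardReading(cube, bad2), class = "spadspec_BadRegion")
})

test_that("calibration matches the closed-form OLS on the four panels", {
  cube <- boardCube(c(800, 600, 400, 0))
  reading <- extractBoardReading(cube, boardBoxes4())
  model <- fitCalibration(reading)
  # collinear points: a = 0.00125, b = 0 exactly
  oracle <- olsLine(c(800, 600, 400, 0), c(1.0, 0.75, 0.5, 0))
  expect_equal(model@slope[1], oracle[["slope"]], tolerance = 1e-12)
  expect_equal(model@slope[1], 0.00125, tolerance = 1e-12)
  expect_equal(model@intercept[1], 0, tolerance = 1e-12)
  expect_equal(model@r2, c(1, 1), tolerance = 1e-12)

  # non-collinear grays: still the OLS line
  cube2 <- boardCube(c(900, 500, 380, 10))
  m2 <- fitCalibration(extractBoardReading(cube2, boardBoxes4()))
  o2 <- olsLine(c(900, 500, 380, 10), c(1.0, 0.75, 0.5, 0))
  expect_equal(m2@slope[2], o2[["slope"]], tolerance = 1e-12)
  expect_equal(m2@intercept[2], o2[["intercept"]], tolerance = 1e-12)
})

test_that("a flat board panel set cannot be calibrated", {
  cube <- boardCube(c(500, 500, 500, 500))
  reading <- extractBoardReading(cube, boardBoxes4())
  expect_error(fitCalibration(reading),
               class = "spadspec_DegenerateCalibration")
})

test_that("applying the calibration is the per-band affine map", {
  model <- new("CalibrationModel", wavelengths = c(681, 888),
               slope = c(0.00125, 0.002), intercept = c(0, -0.1),
               r2 = c(1, 1))
  cube <- SpectralCube(array(400, dim = c(2, 2, 2)), c(681, 888))
  out <- suppressMessages(applyCalibration(cube, model))
  expect_equal(valueKind(out), "reflectance")
  expect_equal(out@data[, , 1], matrix(0.5, 2, 2))
  expect_equal(out@data[, , 2], matrix(0.7, 2, 2))

  # identity calibration returns the input values
  ident <- new("CalibrationModel", wavelengths = c(681, 888),
               slope = c(1, 1), intercept = c(0, 0), r2 = c(1, 1))
  expect_equal(applyCalibration(cube, ident)@data, cube@data)

  wrong <- new("CalibrationModel", wavelengths = c(666, 888),
               slope = c(1, 1), intercept = c(0, 0), r2 = c(1, 1))
  expect_error(applyCalibration(cube, wrong),
               class = "spadspec_ModelCubeMismatch")
})

test_that("calibration composes with an affine transform of the grays", {
  # calibrating c*G + d equals the composed affine map (a*c)G + (a*d + b)
  model <- new("CalibrationModel", wavelengths = 681, slope = 0.002,
               intercept = 0.05, r2 = 1)
  g <- matrix(c(10, 200, 340, 990), 2, 2)
  cube <- SpectralCube(array(g, dim = c(2, 2, 1)), 681)
  cube2 <- SpectralCube(array(0.5 * g + 20, dim = c(2, 2, 1)), 681)
  r1 <- applyCalibration(cube2, model)@data[, , 1]
  expect_equal(r1, (0.002 * 0.5) * g + (0.002 * 20 + 0.05), tolerance = 1e-12)
})

test_that("fit on a noise-free synthetic board recovers the nominal levels", {
  bundle <- generateScene(sceneSpec(19))
  reading <- extractBoardReading(bundle$cubeGrayscale, bundle$boardBoxes)
  model <- fitCalibration(reading)
  for (k in 1:4) {
    recovered <- model@slope * reading@meanGray[k, ] + model@intercept
    expect_equal(recovered, rep(bundle$boardNominal[k], 25),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("negative reflectances are preserved and counted", {
  model <- new("CalibrationModel", wavelengths = 681, slope = 0.001,
               intercept = -0.5, r2 = 1)
  cube <- SpectralCube(array(c(100, 900), dim = c(1, 2, 1)), 681)
  expect_message(out <- applyCalibration(cube, model), "1 negative")
  expect_equal(out@data[1, , 1], c(-0.4, 0.4))
})

test_that("calibration models round trip through JSON", {
  model <- new("CalibrationModel", wavelengths = c(681, 888),
               slope = c(0.00125, 0.002), intercept = c(0, -0.1),
               r2 = c(1, 0.998))
  path <- withr::local_tempfile(fileext = ".json")
  writeCalibrationModel(model, path)
  back <- readCalibrationModel(path)
  expect_equal(back@wavelengths, model@wavelengths)
  expect_equal(back@slope, model@slope)
  expect_equal(back@intercept, model@intercept)
  expect_equal(back@r2, model@r2)
})
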