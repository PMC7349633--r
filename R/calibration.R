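#' Average the standard-board panels
#'
#' Computes, per band and per board level, the arithmetic mean grayscale
#' inside the supplied rectangles. The reference board carries four panels
#' of nominal reflectance 1.0, 0.75, 0.5 and 0 (high to low); readings are
#' taken from a rectangle well inside each panel.
#'
#' @param cube a grayscale [SpectralCube-class] containing the board.
#' @param regionBoxes list of rectangles, one per level, each a list/vector
#'   with elements `row`, `col` (1-based top-left corner), `height`,
#'   `width`.
#' @param nominal numeric nominal reflectances, one per rectangle
#'   (default the reference board levels, high to low).
#' @return a [BoardReading-class].
#' @export
extractBoardReading <- function(cube, regionBoxes,
                                nominal = c(1.0, 0.75, 0.5, 0)) {
  if (length(regionBoxes) != length(nominal))
    .stopInput("BadRegion", "one rectangle per nominal level is required")
  d <- dim(cube@data)
  means <- matrix(0, nrow = length(nominal), ncol = d[3L])
  for (k in seq_along(regionBoxes)) {
    bx <- as.list(regionBoxes[[k]])
    r0 <- bx$row; c0 <- bx$col; h <- bx$height; w <- bx$width
    if (is.null(r0) || is.null(c0) || is.null(h) || is.null(w) ||
        h < 1 || w < 1)
      .stopInput("BadRegion", "rectangle must have positive height and width")
    if (r0 < 1 || c0 < 1 || r0 + h - 1 > d[1L] || c0 + w - 1 > d[2L])
      .stopInput("BadRegion", "rectangle lies outside the image")
    sub <- cube@data[r0:(r0 + h - 1), c0:(c0 + w - 1), , drop = FALSE]
    means[k, ] <- apply(sub, 3L, mean)
  }
  new("BoardReading", nominal = as.numeric(nominal), meanGray = means,
      boxes = lapply(regionBoxes, as.list), wavelengths = cube@wavelengths)
}

#' Fit the per-wavelength grayscale-to-reflectance calibration
#'
#' Ordinary least squares of nominal panel reflectance on mean panel
#' grayscale, independently for every band: `R = a * G + b`. With the
#' four-level board and a linear sensor the four points are collinear and
#' the fit is exact.
#'
#' @param reading a [BoardReading-class].
#' @return a [CalibrationModel-class].
#' @export
fitCalibration <- function(reading) {
  B <- ncol(reading@meanGray)
  a <- b <- r2 <- numeric(B)
  for (j in seq_len(B)) {
    g <- reading@meanGray[, j]
    if (length(unique(g)) < 2L)
      .stopDegenerate("DegenerateCalibration",
                      sprintf("all board levels share one grayscale in band %s nm",
                              reading@wavelengths[j]),
                      band = reading@wavelengths[j])
    fit <- lm(reading@nominal ~ g)
    a[j] <- coef(fit)[[2L]]
    b[j] <- coef(fit)[[1L]]
    sst <- sum((reading@nominal - mean(reading@nominal))^2)
    r2[j] <- if (sst > 0) max(0, min(1, 1 - sum(fit$residuals^2) / sst)) else 1
  }
  new("CalibrationModel", wavelengths = reading@wavelengths, slope = a,
      intercept = b, r2 = r2)
}

#' @describeIn fitCalibration wavelengths accessor for the model.
#' @param x a `CalibrationModel`.
#' @export
setMethod("wavelengths", "CalibrationModel", function(x) x@wavelengths)

#' Calibration coefficients as a data frame
#' @param model a [CalibrationModel-class].
#' @return data.frame with columns `wavelength`, `slope`, `intercept`, `r2`.
#' @export
calibrationTable <- function(model) {
  data.frame(wavelength = model@wavelengths, slope = model@slope,
             intercept = model@intercept, r2 = model@r2)
}

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: %d bands, slope %.3g-%.3g, min r2 %.4f\n",
              length(object@wavelengths), min(object@slope),
              max(object@slope), min(object@r2)))
})

#' Convert a grayscale cube to reflectance
#'
#' Applies the per-band affine calibration `R = a * G + b` pixel-wise.
#' Negative reflectances are preserved (clipping would bias masked means)
#' but counted and reported via a message.
#'
#' @param cube a grayscale [SpectralCube-class].
#' @param model a [CalibrationModel-class] whose wavelength set equals the
#'   cube's.
#' @return a reflectance [SpectralCube-class].
#' @export
applyCalibration <- function(cube, model) {
  if (!identical(as.numeric(cube@wavelengths),
                 as.numeric(model@wavelengths)))
    .stopInput("ModelCubeMismatch",
               "calibration model and cube wavelength sets differ")
  d <- dim(cube@data)
  out <- cube@data
  for (j in seq_len(d[3L]))
    out[, , j] <- model@slope[j] * cube@data[, , j] + model@intercept[j]
  neg <- sum(out < 0)
  if (neg > 0)
    message(sprintf("applyCalibration: %d negative reflectance values preserved",
                    neg))
  SpectralCube(out, cube@wavelengths, "reflectance", cube@bitDepth)
}

#' Read / write a calibration model as JSON
#'
#' Serialized as `{"<wavelength>": {"a": .., "b": .., "r2": ..}, ...}`.
#'
#' @param path JSON file path.
#' @return [readCalibrationModel()] returns a [CalibrationModel-class];
#'   [writeCalibrationModel()] returns `path` invisibly.
#' @export
readCalibrationModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  wl <- as.numeric(names(obj))
  o <- order(wl)
  new("CalibrationModel", wavelengths = wl[o],
      slope = unname(vapply(obj, function(e) e$a, numeric(1L))[o]),
      intercept = unname(vapply(obj, function(e) e$b, numeric(1L))[o]),
      r2 = unname(vapply(obj, function(e) e$r2, numeric(1L))[o]))
}

#' @rdname readCalibrationModel
#' @param model a [CalibrationModel-class].
#' @export
writeCalibrationModel <- function(model, path) {
  obj <- lapply(seq_along(model@wavelengths), function(j)
    list(a = model@slope[j], b = model@intercept[j], r2 = model@r2[j]))
  names(obj) <- as.character(model@wavelengths)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
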