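#' The published ten-term UVE-PLS SPAD model
#'
#' Linear SPAD model over ten selected wavelengths:
#' `Y = -8.651 R681 + 1.287 R816 - 0.687 R827 + 0.251 R837 + 0.089 R849`
#' `    - 2.010 R859 + 1.977 R869 - 0.795 R888 + 0.366 R910 + 6.190 R935`
#' `    + 43.828`.
#' Shipped exactly as printed. (The companion report of selected
#' wavelengths lists 706 nm instead of 827 nm; the shipped model follows
#' the regression equation verbatim and the discrepancy is preserved, not
#' resolved.)
#'
#' @return a [SpadModel-class] with 10 spectral terms.
#' @examples
#' m <- publishedSpadModel()
#' predictPixel(m, setNames(rep(0, 10), spadModelWavelengths(m)))  # 43.828
#' @export
publishedSpadModel <- function() {
  new("SpadModel",
      wavelengths = c(681, 816, 827, 837, 849, 859, 869, 888, 910, 935),
      coefficients = c(-8.651, 1.287, -0.687, 0.251, 0.089,
                       -2.010, 1.977, -0.795, 0.366, 6.190),
      intercept = 43.828,
      provenance = "published UVE-PLS potato SPAD model")
}

#' Build a SpadModel from a fitted PLS model
#'
#' Collapses a [PlsModel-class] into explicit per-wavelength terms on raw
#' reflectance: `coefficients` unchanged,
#' `intercept = yMean - sum(xMean * coefficients)`.
#'
#' @param plsModel a [PlsModel-class].
#' @param provenance free-text origin tag.
#' @return a [SpadModel-class].
#' @export
asSpadModel <- function(plsModel, provenance = "fitted UVE-PLS model") {
  new("SpadModel", wavelengths = plsModel@trainingWavelengths,
      coefficients = plsModel@coefficients,
      intercept = plsModel@yMean -
        sum(plsModel@xMean * plsModel@coefficients),
      provenance = provenance)
}

#' @describeIn publishedSpadModel wavelengths of a SpadModel.
#' @param model a [SpadModel-class].
#' @export
spadModelWavelengths <- function(model) model@wavelengths

#' @describeIn publishedSpadModel coefficients of a SpadModel (named by nm).
#' @export
spadModelCoefficients <- function(model) {
  stats::setNames(model@coefficients, as.character(model@wavelengths))
}

#' @describeIn publishedSpadModel intercept of a SpadModel.
#' @export
spadModelIntercept <- function(model) model@intercept

setMethod("show", "SpadModel", function(object) {
  cat(sprintf("SpadModel: %d spectral terms + intercept %.3f (%s)\n",
              length(object@wavelengths), object@intercept,
              object@provenance))
})

#' Predict the SPAD value of one reflectance spectrum
#'
#' `Y = sum(coefficient_lambda * R_lambda) + intercept`. The reflectance
#' vector must cover every model wavelength; it may be named by nm (any
#' superset of the model bands) or given unnamed in model-band order.
#'
#' @param model a [SpadModel-class].
#' @param reflectance named numeric vector (names = nm) or unnamed vector
#'   of length equal to the model's term count.
#' @return numeric SPAD value.
#' @export
predictPixel <- function(model, reflectance) {
  if (!is.null(names(reflectance))) {
    have <- suppressWarnings(as.numeric(names(reflectance)))
    idx <- match(model@wavelengths, have)
    if (anyNA(idx))
      .stopInput("ModelCubeMismatch",
                 sprintf("reflectance lacks model wavelengths: %s",
                         paste(model@wavelengths[is.na(idx)], collapse = ", ")))
    reflectance <- reflectance[idx]
  } else if (length(reflectance) != length(model@wavelengths)) {
    .stopInput("ModelCubeMismatch",
               "unnamed reflectance must match the model term count")
  }
  sum(model@coefficients * as.numeric(reflectance)) + model@intercept
}

#' Per-pixel SPAD map inside a plant mask
#'
#' Applies the linear SPAD model to every masked pixel of a reflectance
#' cube; pixels outside the mask are set to 0 (rendered as the blue
#' background). Because the model is linear, the masked mean of the map
#' equals the prediction of the masked mean spectrum exactly.
#'
#' @param cube a reflectance [SpectralCube-class] containing every model
#'   wavelength.
#' @param mask a [BinaryMask-class] with at least one foreground pixel.
#' @param model a [SpadModel-class].
#' @param colorRange numeric `(low, high)` SPAD rendering range recorded
#'   on the map (default `c(0, 60)`).
#' @return a [SpadMap-class].
#' @export
predictMap <- function(cube, mask, model, colorRange = c(0, 60)) {
  m <- if (is(mask, "BinaryMask")) mask else BinaryMask(mask)
  d <- dim(cube@data)
  if (!all(dim(m@data) == d[1:2]))
    .stopInput("ShapeMismatch", "mask and cube differ in shape")
  if (sum(m@data) == 0L)
    .stopDegenerate("EmptyMask", "mask has no foreground pixels")
  missing <- setdiff(model@wavelengths, cube@wavelengths)
  if (length(missing))
    .stopInput("ModelCubeMismatch",
               sprintf("cube lacks model wavelengths: %s",
                       paste(missing, collapse = ", ")))
  vals <- matrix(model@intercept, d[1L], d[2L])
  for (j in seq_along(model@wavelengths))
    vals <- vals + model@coefficients[j] *
      getBand(cube, model@wavelengths[j])
  vals[m@data == 0L] <- 0
  new("SpadMap", values = vals, mask = m,
      meanSpad = mean(vals[m@data == 1L]),
      colorRange = as.numeric(colorRange))
}

#' @describeIn predictMap SPAD raster accessor.
#' @param x a `SpadMap`.
#' @export
setMethod("rasterData", "SpadMap", function(x) x@values)

#' @describeIn predictMap masked mean SPAD.
#' @export
meanSpad <- function(x) x@meanSpad

setMethod("show", "SpadMap", function(object) {
  cat(sprintf("SpadMap: %d x %d, %d plant pixels, mean SPAD %.3f\n",
              nrow(object@values), ncol(object@values),
              sum(object@mask@data), object@meanSpad))
})

# fixed 256-entry blue -> green -> yellow lookup, rows = RGB in [0,1]
.spadRamp <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      f <- colorRamp(c("blue", "green", "yellow"))
      lut <<- f(seq(0, 1, length.out = 256L)) / 255
    }
    lut
  }
})

#' Render a SPAD map as a pseudo-color image
#'
#' Fixed 256-entry blue-green-yellow lookup: low SPAD renders blue,
#' high renders yellow; values are clamped to `range` for display only
#' (predictions themselves are never clamped). Background pixels (mask 0,
#' stored as SPAD 0) always take the blue endpoint.
#'
#' @param map a [SpadMap-class].
#' @param range numeric `(low, high)` SPAD display range; defaults to the
#'   map's recorded `colorRange`.
#' @return `H x W x 3` numeric array (RGB in `[0, 1]`).
#' @export
renderPseudocolor <- function(map, range = NULL) {
  if (is.null(range)) range <- map@colorRange
  if (range[1L] >= range[2L])
    .stopInput("BadRange", "range must satisfy low < high")
  lut <- .spadRamp()
  v <- pmin(pmax(map@values, range[1L]), range[2L])
  idx <- as.integer(floor((v - range[1L]) / (range[2L] - range[1L]) * 255)) + 1L
  idx[map@mask@data == 0L] <- 1L
  d <- dim(map@values)
  out <- array(0, dim = c(d, 3L))
  for (ch in 1:3)
    out[, , ch] <- matrix(lut[idx, ch], d[1L], d[2L])
  out
}

#' Write the SPAD raster, rendering and summary of a map
#'
#' The raster goes to a 16-bit normalized TIFF with a JSON sidecar
#' holding the affine (see [writeCube()] for the convention), the
#' rendering to PNG, and the summary (`mean_spad`, `min`, `max`,
#' `n_pixels`) to JSON.
#'
#' @param map a [SpadMap-class].
#' @param rasterPath,renderPath,summaryPath output paths; any may be
#'   `NULL` to skip that artifact.
#' @param range display range forwarded to [renderPseudocolor()].
#' @return invisible list of written paths.
#' @export
writeSpadMap <- function(map, rasterPath = NULL, renderPath = NULL,
                         summaryPath = NULL, range = NULL) {
  written <- list()
  if (!is.null(rasterPath)) {
    lo <- min(map@values); hi <- max(map@values)
    scale <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((map@values - lo) / scale, rasterPath,
                    bits.per.sample = 16L, compression = "none")
    jsonlite::write_json(list(value_kind = "spad", offset = lo,
                              scale = scale),
                         paste0(rasterPath, ".json"), auto_unbox = TRUE,
                         digits = NA)
    written$raster <- rasterPath
  }
  if (!is.null(renderPath)) {
    png::writePNG(renderPseudocolor(map, range), renderPath)
    written$render <- renderPath
  }
  if (!is.null(summaryPath)) {
    inMask <- map@values[map@mask@data == 1L]
    jsonlite::write_json(list(mean_spad = map@meanSpad,
                              min = min(inMask), max = max(inMask),
                              n_pixels = sum(map@mask@data)),
                         summaryPath, auto_unbox = TRUE, digits = NA)
    written$summary <- summaryPath
  }
  invisible(written)
}

#' Read / write a SpadModel as JSON
#'
#' Layout: `{"schema_version": 1, "intercept": .., "provenance": ..,
#' "terms": {"<nm>": coefficient, ...}}`.
#'
#' @param path JSON file path.
#' @return [readSpadModel()] returns a [SpadModel-class];
#'   [writeSpadModel()] returns `path` invisibly.
#' @export
readSpadModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  wl <- as.numeric(names(obj$terms))
  o <- order(wl)
  new("SpadModel", wavelengths = wl[o],
      coefficients = as.numeric(unlist(obj$terms))[o],
      intercept = obj$intercept,
      provenance = if (is.null(obj$provenance)) "unspecified"
                   else obj$provenance)
}

#' @rdname readSpadModel
#' @param model a [SpadModel-class].
#' @export
writeSpadModel <- function(model, path) {
  terms <- as.list(model@coefficients)
  names(terms) <- as.character(model@wavelengths)
  jsonlite::write_json(list(schema_version = 1L, intercept = model@intercept,
                            provenance = model@provenance, terms = terms),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
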