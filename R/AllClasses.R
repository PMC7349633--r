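#' Sensor profile for a snapshot-mosaic spectral imager
#'
#' Describes the band set of a multispectral sensor: band center wavelengths
#' (nm, strictly increasing), their full widths at half maximum (FWHM, nm),
#' the mosaic tile edge (pixels per tile side; the reference sensor carries
#' a 5x5 filter mosaic, one spectral filter per pixel) and the layout of
#' bands within a tile.
#'
#' @slot wavelengths numeric, band centers in nm, strictly increasing.
#' @slot fwhm numeric, FWHM in nm, same length as `wavelengths`.
#' @slot mosaicPeriod integer, tile edge `p`; `p^2` must equal the band
#'   count when mosaic decoding is used.
#' @slot bandLayout integer `p x p` matrix; entry `[r, c]` is the band index
#'   (1-based, in wavelength order) sensed at tile position `(r, c)`. Must
#'   be a bijection onto `1..B`.
#' @exportClass SensorProfile
setClass("SensorProfile",
  representation(wavelengths = "numeric", fwhm = "numeric",
                 mosaicPeriod = "integer", bandLayout = "matrix"),
  validity = function(object) {
    wl <- object@wavelengths
    if (length(wl) < 1L) return("profile needs at least one wavelength")
    if (any(diff(wl) <= 0)) return("wavelengths must be strictly increasing")
    if (length(object@fwhm) != length(wl))
      return("fwhm must have one entry per wavelength")
    p <- object@mosaicPeriod
    if (length(p) != 1L || is.na(p) || p < 1L)
      return("mosaicPeriod must be a positive integer")
    bl <- object@bandLayout
    if (!all(dim(bl) == c(p, p)))
      return("bandLayout must be a mosaicPeriod x mosaicPeriod matrix")
    if (p * p == length(wl) && !identical(sort(as.integer(bl)),
                                          seq_along(wl)))
      return("bandLayout must be a bijection onto 1..B")
    TRUE
  })

#' Spectral image cube
#'
#' An `H x W x B` raster of grayscale counts or calibrated reflectance with
#' the band center wavelengths attached. Grayscale cubes respect the sensor
#' bit depth (10 bits for the reference sensor, so counts in 0..1023);
#' reflectance cubes are real-valued and may contain small negatives
#' produced by the affine calibration.
#'
#' @slot data numeric array `H x W x B`.
#' @slot wavelengths numeric, nm, one per band, strictly increasing.
#' @slot valueKind `"grayscale"` or `"reflectance"`.
#' @slot bitDepth integer, grayscale quantization depth.
#' @exportClass SpectralCube
setClass("SpectralCube",
  representation(data = "array", wavelengths = "numeric",
                 valueKind = "character", bitDepth = "integer"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be an H x W x B array")
    if (d[3L] != length(object@wavelengths))
      return("number of bands must match number of wavelengths")
    if (any(diff(object@wavelengths) <= 0))
      return("wavelengths must be strictly increasing")
    if (!object@valueKind %in% c("grayscale", "reflectance"))
      return("valueKind must be 'grayscale' or 'reflectance'")
    if (object@valueKind == "grayscale") {
      mx <- 2^object@bitDepth - 1
      rng <- range(object@data)
      if (rng[1L] < 0 || rng[2L] > mx)
        return(sprintf("grayscale values must lie in [0, %d]", mx))
    }
    TRUE
  })

#' Binary plant/background mask
#'
#' An `H x W` raster over \{0, 1\} with a provenance tag recording the
#' pipeline stage that produced it (`"preliminary"`, `"precision"`,
#' `"reference"`, ...).
#'
#' @slot data integer matrix of 0/1.
#' @slot provenance character stage tag.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(data = "matrix", provenance = "character"),
  validity = function(object) {
    if (!all(object@data %in% c(0L, 1L))) return("mask values must be 0 or 1")
    TRUE
  })

#' Per-wavelength grayscale-to-reflectance calibration
#'
#' Slope and intercept of the per-band affine map `R = a * G + b` fitted by
#' ordinary least squares on the four-level standard board, together with
#' the per-band coefficient of determination of the fit.
#'
#' @slot wavelengths numeric, nm.
#' @slot slope numeric `a` per band (reflectance per grayscale count).
#' @slot intercept numeric `b` per band (reflectance).
#' @slot r2 numeric fit quality per band, in `[0, 1]`.
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(wavelengths = "numeric", slope = "numeric",
                 intercept = "numeric", r2 = "numeric"),
  validity = function(object) {
    n <- length(object@wavelengths)
    if (length(object@slope) != n || length(object@intercept) != n ||
        length(object@r2) != n)
      return("slope, intercept and r2 must have one entry per wavelength")
    if (any(!is.finite(object@slope))) return("slopes must be finite")
    if (any(object@r2 < -1e-9 | object@r2 > 1 + 1e-9, na.rm = TRUE))
      return("r2 must lie in [0, 1]")
    TRUE
  })

#' Mean grayscale of the standard-board panels
#'
#' Per-band mean grayscale of each of the four board panels (nominal
#' reflectances 1.0, 0.75, 0.5, 0) plus the pixel rectangles averaged over.
#'
#' @slot nominal numeric nominal panel reflectances.
#' @slot meanGray matrix, levels x bands, mean grayscale per panel and band.
#' @slot boxes list of rectangles (`list(row, col, height, width)`).
#' @slot wavelengths numeric, nm.
#' @exportClass BoardReading
setClass("BoardReading",
  representation(nominal = "numeric", meanGray = "matrix", boxes = "list",
                 wavelengths = "numeric"),
  validity = function(object) {
    if (nrow(object@meanGray) != length(object@nominal))
      return("one row of meanGray per nominal level")
    if (ncol(object@meanGray) != length(object@wavelengths))
      return("one column of meanGray per wavelength")
    if (length(object@nominal) < 2L)
      return("at least two board levels are required")
    TRUE
  })

#' Modified difference vegetation index image
#'
#' `MDVI(alpha) = I_nir - alpha * I_red`, by default the 888 nm and 681 nm
#' bands. Real-valued; may be negative.
#'
#' @slot data numeric `H x W` matrix.
#' @slot alpha numeric modified coefficient.
#' @slot sourceWavelengths numeric `(nir_nm, red_nm)`.
#' @exportClass MdviImage
setClass("MdviImage",
  representation(data = "matrix", alpha = "numeric",
                 sourceWavelengths = "numeric"))

#' Result of the two-stage plant segmentation
#'
#' Holds the preliminary mask (MDVI + Otsu), the precision mask after
#' median filtering and connected-domain labeling, the Otsu threshold on
#' the 0..255 rescaled index, and connected-component statistics.
#'
#' @slot preliminaryMask,precisionMask [BinaryMask-class] rasters.
#' @slot otsuThreshold integer threshold on the rescaled MDVI.
#' @slot componentCount integer number of connected domains found.
#' @slot componentAreas numeric areas (pixels) of all components.
#' @slot largestComponentArea numeric area of the retained component.
#' @slot alpha numeric modified coefficient used.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(preliminaryMask = "BinaryMask", precisionMask = "BinaryMask",
                 otsuThreshold = "integer", componentCount = "integer",
                 componentAreas = "numeric", largestComponentArea = "numeric",
                 alpha = "numeric"),
  validity = function(object) {
    if (length(object@componentAreas) &&
        object@largestComponentArea < max(object@componentAreas))
      return("largestComponentArea must be maximal among componentAreas")
    TRUE
  })

#' Partial least squares (PLS1) regression model
#'
#' Mean-centered NIPALS PLS1 collapsed to a single coefficient vector:
#' `prediction = yMean + (x - xMean) %*% coefficients`.
#'
#' @slot nComponents integer latent components retained.
#' @slot xMean numeric predictor means.
#' @slot yMean numeric response mean.
#' @slot coefficients numeric collapsed coefficient vector.
#' @slot trainingWavelengths numeric nm per predictor column.
#' @slot rmsecv numeric leave-one-out RMSECV per component count (possibly
#'   empty when component selection was not run).
#' @exportClass PlsModel
setClass("PlsModel",
  representation(nComponents = "integer", xMean = "numeric", yMean = "numeric",
                 coefficients = "numeric", trainingWavelengths = "numeric",
                 rmsecv = "numeric"),
  validity = function(object) {
    if (object@nComponents < 1L) return("nComponents must be >= 1")
    if (length(object@coefficients) != length(object@xMean))
      return("coefficients and xMean must have the same length")
    TRUE
  })

#' Uninformative-variable-elimination result
#'
#' Reliability index (RI) per wavelength from the jackknife over
#' leave-one-out PLS coefficient vectors, the cutoff applied, and the
#' selected wavelengths (`|RI| >= threshold`).
#'
#' @slot reliabilityIndex numeric RI per wavelength (named by nm).
#' @slot threshold numeric cutoff applied.
#' @slot selectedWavelengths numeric nm of the retained variables.
#' @exportClass UveResult
setClass("UveResult",
  representation(reliabilityIndex = "numeric", threshold = "numeric",
                 selectedWavelengths = "numeric"))

#' Regression metrics for a SPAD model
#'
#' Determination coefficient `R2 = 1 - SSE/SST`, root mean square error
#' `RMSE = sqrt(SSE/n)`, ratio of performance to deviation
#' `RPD = Std / RMSE`, and the conventional RPD grade: good (> 2), middle
#' (1.4 to 2), poor (< 1.4).
#'
#' @slot r2,rmse,rpd numeric scalars.
#' @slot n integer sample count.
#' @slot grade character, one of `"good"`, `"middle"`, `"poor"`.
#' @exportClass ModelMetrics
setClass("ModelMetrics",
  representation(r2 = "numeric", rmse = "numeric", rpd = "numeric",
                 n = "integer", grade = "character"),
  validity = function(object) {
    if (object@rmse < 0) return("rmse must be non-negative")
    if (!object@grade %in% c("good", "middle", "poor"))
      return("grade must be good, middle or poor")
    TRUE
  })

#' Linear SPAD prediction model over selected wavelengths
#'
#' `SPAD = sum(coefficient_lambda * R_lambda) + intercept`. Houses both the
#' shipped published ten-term model ([publishedSpadModel()]) and models
#' refit from data ([asSpadModel()]).
#'
#' @slot wavelengths numeric nm, unique.
#' @slot coefficients numeric SPAD per reflectance unit, one per wavelength.
#' @slot intercept numeric SPAD units.
#' @slot provenance character free-text origin tag.
#' @exportClass SpadModel
setClass("SpadModel",
  representation(wavelengths = "numeric", coefficients = "numeric",
                 intercept = "numeric", provenance = "character"),
  validity = function(object) {
    if (anyDuplicated(object@wavelengths))
      return("model wavelengths must be unique")
    if (length(object@coefficients) != length(object@wavelengths))
      return("one coefficient per wavelength")
    if (any(!is.finite(object@coefficients)) || !is.finite(object@intercept))
      return("coefficients and intercept must be finite")
    TRUE
  })

#' Per-pixel SPAD distribution map
#'
#' SPAD predictions inside the plant mask, zero outside, plus the mask, the
#' masked mean and the rendering range.
#'
#' @slot values numeric `H x W` SPAD raster, 0 outside the mask.
#' @slot mask [BinaryMask-class].
#' @slot meanSpad numeric mean over mask pixels.
#' @slot colorRange numeric `(low, high)` SPAD rendering range.
#' @exportClass SpadMap
setClass("SpadMap",
  representation(values = "matrix", mask = "BinaryMask", meanSpad = "numeric",
                 colorRange = "numeric"),
  validity = function(object) {
    if (!all(dim(object@values) == dim(object@mask@data)))
      return("values and mask dimensions must agree")
    if (any(object@values[object@mask@data == 0L] != 0))
      return("values must be 0 outside the mask")
    TRUE
  })
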