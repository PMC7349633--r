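#' Construct a sensor profile
#'
#' @param wavelengths numeric band centers in nm, strictly increasing.
#' @param fwhm numeric FWHM in nm, one per band.
#' @param mosaicPeriod integer mosaic tile edge (5 for the reference
#'   sensor, whose 5x5 tile carries the 25 bands).
#' @param bandLayout optional integer `p x p` matrix mapping tile position
#'   `(r, c)` to band index in wavelength order. Defaults to row-major
#'   within the tile.
#' @return a [SensorProfile-class].
#' @examples
#' p <- defaultSensorProfile()
#' length(wavelengths(p))  # 25
#' @export
SensorProfile <- function(wavelengths, fwhm, mosaicPeriod,
                          bandLayout = NULL) {
  mosaicPeriod <- as.integer(mosaicPeriod)
  if (is.null(bandLayout)) {
    bandLayout <- matrix(seq_len(mosaicPeriod^2), nrow = mosaicPeriod,
                         ncol = mosaicPeriod, byrow = TRUE)
  }
  storage.mode(bandLayout) <- "integer"
  new("SensorProfile", wavelengths = as.numeric(wavelengths),
      fwhm = as.numeric(fwhm), mosaicPeriod = mosaicPeriod,
      bandLayout = bandLayout)
}

#' Reference 25-band sensor profile
#'
#' The band set of the reference snapshot-mosaic imager: 25 wavelengths
#' from 666 to 945 nm on a 5x5 tile, 409 x 217 pixels per band after
#' demosaicing, 10-bit grayscale. The FWHM widens with wavelength (3.35 nm
#' for the shortest group up to 12.10 nm for the longest). Note that 887
#' and 888 nm are adjacent but distinct bands.
#'
#' @return a [SensorProfile-class].
#' @export
defaultSensorProfile <- function() {
  wl <- c(666, 681, 706, 720, 732, 746, 759,
          772, 784, 796, 816, 827,
          837, 849, 859, 869, 887,
          888, 902, 910, 920, 926,
          935, 940, 945)
  fwhm <- rep(c(3.35, 4.69, 6.04, 7.39, 12.10), times = c(7, 5, 5, 5, 3))
  SensorProfile(wl, fwhm, 5L)
}

#' @describeIn SensorProfile wavelengths accessor.
#' @param x a `SensorProfile`.
#' @export
setMethod("wavelengths", "SensorProfile", function(x) x@wavelengths)

#' FWHM accessor
#' @param profile a [SensorProfile-class].
#' @return numeric FWHM (nm) per band.
#' @export
profileFwhm <- function(profile) profile@fwhm

#' Mosaic tile edge accessor
#' @param profile a [SensorProfile-class].
#' @return integer tile edge.
#' @export
mosaicPeriod <- function(profile) profile@mosaicPeriod

#' Band layout accessor
#' @param profile a [SensorProfile-class].
#' @return integer `p x p` matrix of band indices.
#' @export
bandLayout <- function(profile) profile@bandLayout

setMethod("show", "SensorProfile", function(object) {
  wl <- object@wavelengths
  cat(sprintf("SensorProfile: %d bands, %.0f-%.0f nm, mosaic %dx%d\n",
              length(wl), min(wl), max(wl), object@mosaicPeriod,
              object@mosaicPeriod))
})

#' Read / write a sensor profile file
#'
#' JSON or YAML (chosen by extension) with fields `wavelengths`, `fwhm`,
#' `mosaic_period` and optional `band_layout` (row-major list of rows of
#' 1-based band indices).
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return [readSensorProfile()] returns a [SensorProfile-class];
#'   [writeSensorProfile()] returns `path` invisibly.
#' @export
readSensorProfile <- function(path) {
  if (!file.exists(path))
    .stopInput("BadInput", sprintf("profile file not found: %s", path))
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  layout <- obj$band_layout
  if (!is.null(layout)) {
    layout <- if (is.matrix(layout)) layout else do.call(rbind, layout)
  }
  SensorProfile(obj$wavelengths, obj$fwhm, obj$mosaic_period, layout)
}

#' @rdname readSensorProfile
#' @param profile a [SensorProfile-class].
#' @export
writeSensorProfile <- function(profile, path) {
  obj <- list(wavelengths = profile@wavelengths, fwhm = profile@fwhm,
              mosaic_period = profile@mosaicPeriod,
              band_layout = profile@bandLayout)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    obj$band_layout <- lapply(seq_len(nrow(profile@bandLayout)),
                              function(i) profile@bandLayout[i, ])
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  invisible(path)
}
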