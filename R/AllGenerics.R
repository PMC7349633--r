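#' Band center wavelengths (nm)
#' @param x an object carrying band wavelengths.
#' @return numeric vector of nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Raster payload of an object
#' @param x a cube, mask, index image or map.
#' @return the underlying array or matrix.
#' @export
setGeneric("rasterData", function(x) standardGeneric("rasterData"))

#' Extract one band of a spectral cube by exact wavelength
#'
#' @param x a [SpectralCube-class].
#' @param wavelength band center in nm; must match one of the cube's
#'   wavelengths exactly (the reference sensor has two adjacent but
#'   distinct bands at 887 and 888 nm, so no fuzzy matching is done).
#' @return `H x W` numeric matrix.
#' @export
setGeneric("getBand", function(x, wavelength) standardGeneric("getBand"))

#' @rdname wavelengths
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname wavelengths
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' Provenance tag of a mask
#' @param x a [BinaryMask-class].
#' @return character stage tag.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
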