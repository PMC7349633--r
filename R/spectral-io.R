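#' Construct a spectral cube from an array
#'
#' @param data numeric `H x W x B` array (or a list of `H x W` matrices,
#'   one per band).
#' @param wavelengths numeric band centers in nm, strictly increasing.
#' @param valueKind `"grayscale"` or `"reflectance"`.
#' @param bitDepth integer grayscale quantization depth (default 10, the
#'   reference sensor's resolution).
#' @return a [SpectralCube-class].
#' @export
SpectralCube <- function(data, wavelengths, valueKind = "grayscale",
                         bitDepth = 10L) {
  if (is.list(data)) {
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dim(data[[1L]]), length(data)))
  }
  new("SpectralCube", data = data, wavelengths = as.numeric(wavelengths),
      valueKind = valueKind, bitDepth = as.integer(bitDepth))
}

#' @describeIn SpectralCube wavelengths accessor.
#' @param x a `SpectralCube`.
#' @export
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)

#' @describeIn SpectralCube raw array accessor.
#' @export
setMethod("rasterData", "SpectralCube", function(x) x@data)

#' @describeIn SpectralCube value kind accessor.
#' @export
setMethod("valueKind", "SpectralCube", function(x) x@valueKind)

#' @describeIn SpectralCube bit depth accessor.
#' @export
setMethod("bitDepth", "SpectralCube", function(x) x@bitDepth)

#' @describeIn SpectralCube number of bands.
#' @export
nbands <- function(x) length(x@wavelengths)

setMethod("dim", "SpectralCube", function(x) dim(x@data))

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpectralCube: %d x %d pixels, %d bands (%s), %.0f-%.0f nm\n",
              d[1L], d[2L], d[3L], object@valueKind,
              min(object@wavelengths), max(object@wavelengths)))
})

.bandIndex <- function(wavelengths, wavelength) {
  i <- which(wavelengths == wavelength)
  if (length(i) != 1L)
    .stopInput("BandNotFound",
               sprintf("no band at %s nm; available: %s", wavelength,
                       paste(wavelengths, collapse = ", ")))
  i
}

#' @rdname getBand
#' @export
setMethod("getBand", "SpectralCube", function(x, wavelength) {
  x@data[, , .bandIndex(x@wavelengths, wavelength)]
})

#' Construct a binary mask
#'
#' @param data matrix of 0/1 (logical and 0/255 inputs are coerced).
#' @param provenance character stage tag (`"preliminary"`, `"precision"`,
#'   `"reference"`, ...).
#' @return a [BinaryMask-class].
#' @export
BinaryMask <- function(data, provenance = "unspecified") {
  m <- matrix(as.integer(data != 0), nrow = nrow(data), ncol = ncol(data))
  new("BinaryMask", data = m, provenance = provenance)
}

#' @describeIn BinaryMask mask raster accessor.
#' @param x a `BinaryMask`.
#' @export
setMethod("rasterData", "BinaryMask", function(x) x@data)

#' @describeIn BinaryMask provenance accessor.
#' @export
setMethod("provenance", "BinaryMask", function(x) x@provenance)

setMethod("dim", "BinaryMask", function(x) dim(x@data))

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d, %d foreground pixels (%s)\n",
              nrow(object@data), ncol(object@data), sum(object@data),
              object@provenance))
})

.cubeSidecar <- function(path) paste0(path, ".json")

#' Read a spectral cube
#'
#' Accepts either a multi-page TIFF (one page per band, pages in the
#' profile's wavelength order) or a directory containing one single-band
#' image per band plus a `manifest.json` mapping wavelength (nm) to file
#' name. Cubes written by [writeCube()] carry a JSON sidecar with value
#' kind, bit depth and the normalization affine for reflectance cubes;
#' plain third-party TIFFs without a sidecar are read as grayscale.
#'
#' @param path file or directory path.
#' @param profile a [SensorProfile-class]; its wavelength list defines the
#'   band order and count.
#' @return a [SpectralCube-class].
#' @export
readCube <- function(path, profile) {
  wl <- profile@wavelengths
  if (dir.exists(path)) {
    manifest <- file.path(path, "manifest.json")
    if (!file.exists(manifest))
      .stopInput("BadInput", sprintf("no manifest.json in %s", path))
    man <- jsonlite::fromJSON(manifest)
    have <- as.numeric(names(man))
    missing <- setdiff(wl, have)
    if (length(missing))
      .stopInput("MissingBand",
                 sprintf("bands missing from manifest: %s",
                         paste(missing, collapse = ", ")))
    unknown <- setdiff(have, wl)
    if (length(unknown))
      .stopInput("BandNotFound",
                 sprintf("manifest wavelengths not in profile: %s",
                         paste(unknown, collapse = ", ")))
    pages <- lapply(wl, function(w) {
      f <- file.path(path, man[[as.character(w)]])
      if (!file.exists(f))
        .stopInput("MissingBand", sprintf("band file not found: %s", f))
      .readBandImage(f)
    })
  } else {
    if (!file.exists(path))
      .stopInput("BadInput", sprintf("cube not found: %s", path))
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != length(wl))
      .stopInput("MissingBand",
                 sprintf("expected %d bands, found %d pages",
                         length(wl), length(pages)))
  }
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    .stopInput("BadInput", "bands differ in dimensions")
  arr <- array(unlist(pages, use.names = FALSE),
               dim = c(dims[, 1L], length(pages)))
  meta <- if (file.exists(.cubeSidecar(path)))
    jsonlite::fromJSON(.cubeSidecar(path)) else NULL
  if (is.null(meta)) {
    SpectralCube(arr, wl, "grayscale", 10L)
  } else if (identical(meta$value_kind, "reflectance")) {
    arr <- arr / 65535 * meta$scale + meta$offset
    SpectralCube(arr, wl, "reflectance", as.integer(meta$bit_depth))
  } else {
    SpectralCube(arr, wl, "grayscale", as.integer(meta$bit_depth))
  }
}

.readBandImage <- function(f) {
  img <- if (grepl("\\.tiff?$", f, ignore.case = TRUE)) {
    tiff::readTIFF(f, as.is = TRUE)
  } else {
    round(png::readPNG(f) * 65535)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write a spectral cube as a multi-page TIFF
#'
#' Grayscale cubes are stored as 16-bit integer pages (lossless for the
#' 10-bit reference sensor); reflectance cubes are min-max normalized and
#' stored at 16-bit depth with the affine recorded in a `<path>.json`
#' sidecar. Pages are written in band (wavelength) order.
#'
#' @param cube a [SpectralCube-class].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
writeCube <- function(cube, path) {
  B <- nbands(cube)
  d <- dim(cube@data)
  page <- function(b) matrix(cube@data[, , b], d[1L], d[2L])
  if (cube@valueKind == "grayscale") {
    pages <- lapply(seq_len(B), function(b) page(b) / 65535)
    meta <- list(value_kind = "grayscale", bit_depth = cube@bitDepth)
  } else {
    lo <- min(cube@data); hi <- max(cube@data)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(B), function(b) (page(b) - lo) / scale)
    meta <- list(value_kind = "reflectance", bit_depth = cube@bitDepth,
                 offset = lo, scale = scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(meta, .cubeSidecar(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Decode a raw mosaic frame into a spectral cube
#'
#' The snapshot sensor lays a `p x p` tile of spectral filters over the
#' pixel grid, so a raw `H0 x W0` frame interleaves all `p^2` bands. Band
#' `b`, sensed at tile position `(r, c)`, is the sub-grid
#' `raw[r::p, c::p]` and has shape `(H0/p) x (W0/p)`.
#'
#' @param raw numeric `H0 x W0` matrix; both dimensions must be multiples
#'   of the profile's mosaic period.
#' @param profile a [SensorProfile-class] with `p^2` equal to its band
#'   count.
#' @return a grayscale [SpectralCube-class].
#' @export
mosaicToCube <- function(raw, profile) {
  p <- profile@mosaicPeriod
  if (nrow(raw) %% p != 0L || ncol(raw) %% p != 0L)
    .stopInput("MosaicGeometry",
               sprintf("raw frame %d x %d is not a multiple of the mosaic period %d",
                       nrow(raw), ncol(raw), p))
  if (p * p != length(profile@wavelengths))
    .stopInput("MosaicGeometry", "mosaic period^2 must equal the band count")
  H <- nrow(raw) %/% p; W <- ncol(raw) %/% p
  arr <- array(0, dim = c(H, W, p * p))
  for (r in seq_len(p)) {
    for (cc in seq_len(p)) {
      b <- profile@bandLayout[r, cc]
      arr[, , b] <- raw[seq(r, by = p, length.out = H),
                        seq(cc, by = p, length.out = W)]
    }
  }
  SpectralCube(arr, profile@wavelengths, "grayscale", 10L)
}

#' Re-interleave a cube into a raw mosaic frame
#'
#' Exact inverse of [mosaicToCube()]; useful for round-trip checks and for
#' writing simulator output in raw sensor form.
#'
#' @param cube a [SpectralCube-class] with `p^2` bands.
#' @param profile the matching [SensorProfile-class].
#' @return numeric `(H*p) x (W*p)` matrix.
#' @export
cubeToMosaic <- function(cube, profile) {
  p <- profile@mosaicPeriod
  d <- dim(cube@data)
  raw <- matrix(0, nrow = d[1L] * p, ncol = d[2L] * p)
  for (r in seq_len(p)) {
    for (cc in seq_len(p)) {
      b <- profile@bandLayout[r, cc]
      raw[seq(r, by = p, length.out = d[1L]),
          seq(cc, by = p, length.out = d[2L])] <- cube@data[, , b]
    }
  }
  raw
}

#' Read / write a binary mask as PNG
#'
#' Masks are stored 0/255 on disk and mapped to \{0, 1\} in memory.
#'
#' @param path PNG file path.
#' @param provenance tag attached to the mask read back.
#' @return [readMask()] returns a [BinaryMask-class]; [writeMask()]
#'   returns `path` invisibly.
#' @export
readMask <- function(path, provenance = "reference") {
  if (!file.exists(path))
    .stopInput("BadInput", sprintf("mask not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  BinaryMask(img >= 0.5, provenance)
}

#' @rdname readMask
#' @param mask a [BinaryMask-class].
#' @export
writeMask <- function(mask, path) {
  png::writePNG(mask@data * 1.0, path)
  invisible(path)
}
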