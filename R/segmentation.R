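#' Modified difference vegetation index
#'
#' `MDVI(alpha) = I_nir - alpha * I_red`, by default the 888 nm and 681 nm
#' bands. Green vegetation combines low red reflectance (pigment
#' absorption) with a high near-infrared plateau (cell-cavity scattering),
#' so its MDVI is positive, while spectrally flat backgrounds (soil, mulch
#' film, board panels) are driven negative as `alpha` grows.
#'
#' @param cube a [SpectralCube-class] containing both bands.
#' @param alpha numeric modified coefficient (the operating point selected
#'   for field potato scenes is 2.5).
#' @param nir,red band centers in nm (defaults 888 and 681).
#' @return an [MdviImage-class].
#' @export
computeMdvi <- function(cube, alpha, nir = 888, red = 681) {
  img <- getBand(cube, nir) - alpha * getBand(cube, red)
  new("MdviImage", data = img, alpha = alpha,
      sourceWavelengths = c(nir, red))
}

#' @describeIn computeMdvi raster accessor.
#' @param x an `MdviImage`.
#' @export
setMethod("rasterData", "MdviImage", function(x) x@data)

setMethod("show", "MdviImage", function(object) {
  cat(sprintf("MdviImage: %d x %d, alpha = %g, bands %g/%g nm\n",
              nrow(object@data), ncol(object@data), object@alpha,
              object@sourceWavelengths[1L], object@sourceWavelengths[2L]))
})

#' Min-max rescale a real raster to integer levels
#'
#' Maps the minimum to 0 and the maximum to `levels - 1`, linear in
#' between, rounding half-up. Otsu thresholding operates on this discrete
#' histogram; 256 levels mirror the 8-bit convention. A constant input
#' maps to all zeros and is flagged rather than raised as an error.
#'
#' @param img finite numeric matrix.
#' @param levels integer number of levels (default 256).
#' @return list with `data` (integer matrix), `minValue`, `maxValue` of
#'   the input, and logical `constant`.
#' @export
rescaleToLevels <- function(img, levels = 256L) {
  if (any(!is.finite(img)))
    .stopInput("BadInput", "image must be finite")
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    return(list(data = matrix(0L, nrow(img), ncol(img)), minValue = lo,
                maxValue = hi, constant = TRUE))
  }
  scaled <- (img - lo) / (hi - lo) * (levels - 1L)
  out <- matrix(as.integer(floor(scaled + 0.5)), nrow(img), ncol(img))
  list(data = out, minValue = lo, maxValue = hi, constant = FALSE)
}

#' Otsu threshold of an integer image
#'
#' Finds the threshold `t*` in `0..levels-2` maximizing the between-class
#' variance of the grayscale histogram (background: values `<= t`,
#' foreground: values `> t`). Ties are broken toward the lowest threshold.
#'
#' @param img integer matrix (or vector) with values in `0..levels-1`.
#' @param levels integer histogram size (default 256).
#' @return integer threshold `t*`; foreground pixels are those `> t*`.
#' @export
otsuThreshold <- function(img, levels = 256L) {
  v <- as.integer(img)
  if (length(unique(v)) < 2L)
    .stopDegenerate("ConstantImage", "cannot threshold a constant image")
  counts <- tabulate(v + 1L, nbins = levels)
  n <- length(v)
  p <- counts / n
  vals <- 0:(levels - 1L)
  omega <- cumsum(p)                     # P(value <= t)
  mu <- cumsum(p * vals)                 # partial mean
  muT <- mu[levels]
  t <- vals[1:(levels - 1L)]
  w0 <- omega[1:(levels - 1L)]
  m0 <- mu[1:(levels - 1L)]
  sigma <- (muT * w0 - m0)^2 / (w0 * (1 - w0))
  sigma[!is.finite(sigma)] <- -Inf       # empty class: not a valid split
  as.integer(t[which.max(sigma)])        # which.max takes the first (lowest t)
}

#' Median-filter a binary mask
#'
#' Each output pixel is the median of the `window x window` neighborhood
#' centered on it (for a binary mask: the majority vote); borders are
#' handled by edge replication. Removes salt-and-pepper noise left by
#' thresholding before connected-domain labeling.
#'
#' @param mask a [BinaryMask-class] (or 0/1 matrix).
#' @param window odd integer window edge `>= 3` (default 3).
#' @return a [BinaryMask-class] with the same provenance.
#' @export
medianFilterMask <- function(mask, window = 3L) {
  if (window < 3L || window %% 2L == 0L)
    .stopInput("BadWindow", "window must be an odd integer >= 3")
  prov <- if (is(mask, "BinaryMask")) mask@provenance else "unspecified"
  m <- if (is(mask, "BinaryMask")) mask@data else mask
  h <- nrow(m); w <- ncol(m); k <- (window - 1L) %/% 2L
  pad <- m[pmin(pmax(seq_len(h + 2L * k) - k, 1L), h),
           pmin(pmax(seq_len(w + 2L * k) - k, 1L), w), drop = FALSE]
  # summed-area table of the padded mask
  sat <- apply(apply(pad, 2L, cumsum), 1L, cumsum)  # transposed after 2nd apply
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  r1 <- seq_len(h); c1 <- seq_len(w)
  counts <- sat[r1 + window, c1 + window, drop = FALSE] -
    sat[r1, c1 + window, drop = FALSE] -
    sat[r1 + window, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
  BinaryMask(counts >= (window * window + 1L) / 2L, prov)
}

#' Keep the largest connected foreground domain
#'
#' Labels the connected domains of a binary mask (8-connectivity by
#' default) and retains only the maximal-area one; everything else is
#' removed as noise. Among equal-area largest domains the one whose first
#' pixel in raster order (top-to-bottom, left-to-right) comes first is
#' kept, making the operation deterministic.
#'
#' @param mask a [BinaryMask-class] with at least one foreground pixel.
#' @param connectivity 4 or 8 (default 8).
#' @return list with `mask` (the retained-domain [BinaryMask-class]),
#'   `componentCount`, `componentAreas` and `largestComponentArea`.
#' @export
largestComponent <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    .stopInput("BadInput", "connectivity must be 4 or 8")
  m <- if (is(mask, "BinaryMask")) mask@data else mask
  prov <- if (is(mask, "BinaryMask")) mask@provenance else "unspecified"
  fg <- which(m == 1L)
  if (length(fg) == 0L)
    .stopDegenerate("EmptyMask", "mask has no foreground pixels")
  h <- nrow(m); w <- ncol(m)
  id <- matrix(0L, h, w)
  id[fg] <- seq_along(fg)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (s in shifts) {
    dr <- s[1L]; dc <- s[2L]
    rr <- seq_len(h - dr)
    cc <- if (dc >= 0L) seq_len(w - dc) else seq(1L - dc, w)
    a <- id[rr, cc, drop = FALSE]
    b <- id[rr + dr, cc + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges <- c(edges, rbind(a[keep], b[keep]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  areas <- as.numeric(comp$csize)
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # raster-order tie-break: fg is column-major; compute row-major rank
    rows <- ((fg - 1L) %% h) + 1L
    cols <- ((fg - 1L) %/% h) + 1L
    rank <- (rows - 1L) * w + cols
    first <- vapply(best, function(cid)
      min(rank[comp$membership == cid]), numeric(1L))
    best <- best[which.min(first)]
  }
  keep <- fg[comp$membership == best]
  out <- matrix(0L, h, w)
  out[keep] <- 1L
  list(mask = BinaryMask(out, prov), componentCount = comp$no,
       componentAreas = areas, largestComponentArea = max(areas))
}

#' Two-stage plant segmentation (MDVI-OTSU-CDL)
#'
#' Composition of the full segmentation chain: MDVI at the given `alpha`,
#' min-max rescale to 256 levels, Otsu threshold (foreground strictly
#' above the threshold), binary median filter, and retention of the
#' largest connected domain as the target plant. Weeds and neighboring
#' plants share the plant's spectral signature and survive thresholding,
#' which is why the connected-domain stage is needed; by construction it
#' keeps exactly one component, and if a weed patch is larger than the
#' plant it is the weed that is kept (a documented failure mode).
#'
#' @param cube a [SpectralCube-class] (reflectance in the standard
#'   pipeline; the chain itself is value-kind agnostic).
#' @param alpha numeric modified coefficient (default 2.5, the selected
#'   operating point).
#' @param connectivity 4 or 8 (default 8).
#' @param window odd median filter window (default 3).
#' @param nir,red band centers in nm for the index.
#' @return a [SegmentationResult-class].
#' @export
segmentPlant <- function(cube, alpha = 2.5, connectivity = 8L, window = 3L,
                         nir = 888, red = 681) {
  mdvi <- computeMdvi(cube, alpha, nir, red)
  sc <- rescaleToLevels(mdvi@data)
  if (sc$constant)
    .stopDegenerate("ConstantImage", "MDVI image is constant")
  t <- otsuThreshold(sc$data)
  prelim <- BinaryMask(sc$data > t, "preliminary")
  filtered <- medianFilterMask(prelim, window)
  lc <- largestComponent(filtered, connectivity)
  precision <- BinaryMask(lc$mask@data, "precision")
  new("SegmentationResult", preliminaryMask = prelim,
      precisionMask = precision, otsuThreshold = t,
      componentCount = as.integer(lc$componentCount),
      componentAreas = lc$componentAreas,
      largestComponentArea = lc$largestComponentArea, alpha = alpha)
}

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(paste0("SegmentationResult: alpha = %g, Otsu t* = %d, ",
                     "%d domains, plant area %d px\n"),
              object@alpha, object@otsuThreshold, object@componentCount,
              as.integer(object@largestComponentArea)))
})

#' Segmentation accuracy as intersection-over-union
#'
#' `A = |M1 & M2| / |M1 | M2| * 100`, the intersection-over-union of a
#' reference mask and a segmented mask as a percentage. Symmetric in its
#' arguments and bounded in `[0, 100]`.
#'
#' @param reference,segmented [BinaryMask-class] objects (or 0/1 matrices)
#'   of identical shape; the union must be non-empty.
#' @return numeric accuracy in percent.
#' @export
miou <- function(reference, segmented) {
  m1 <- if (is(reference, "BinaryMask")) reference@data else reference
  m2 <- if (is(segmented, "BinaryMask")) segmented@data else segmented
  if (!all(dim(m1) == dim(m2)))
    .stopInput("ShapeMismatch", "masks differ in shape")
  inter <- sum(m1 == 1L & m2 == 1L)
  uni <- sum(m1 == 1L | m2 == 1L)
  if (uni == 0L)
    .stopDegenerate("EmptyUnion", "both masks are empty")
  inter / uni * 100
}

#' Sweep the MDVI modified coefficient
#'
#' Runs the full segmentation chain and scores it against a reference mask
#' for each candidate coefficient; reports the arg-max. The default list
#' covers the six coefficients examined for field potato scenes.
#'
#' @param cube a [SpectralCube-class].
#' @param reference a reference [BinaryMask-class].
#' @param alphas numeric candidates (default `c(0.5, 1, 1.5, 2, 2.5, 3)`).
#' @param ... passed to [segmentPlant()].
#' @return data.frame with columns `alpha`, `accuracy`, `otsuThreshold`;
#'   attribute `bestAlpha` holds the arg-max coefficient.
#' @export
alphaSweep <- function(cube, reference,
                       alphas = c(0.5, 1.0, 1.5, 2.0, 2.5, 3.0), ...) {
  rows <- lapply(alphas, function(a) {
    seg <- segmentPlant(cube, alpha = a, ...)
    data.frame(alpha = a,
               accuracy = miou(reference, seg@precisionMask),
               otsuThreshold = seg@otsuThreshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "bestAlpha") <- out$alpha[which.max(out$accuracy)]
  out
}
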