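# Seeded synthetic 25-band scenes with ground truth, emulating a field
# view: target plant, weeds, a neighboring plant, soil, mulch film,
# residual straw and the 4-level correction board. Signatures are
# piecewise-linear templates (not radiative-transfer output) chosen to
# reproduce the qualitative spectra of the field objects: vegetation has
# low red / high NIR reflectance, film is uniformly high, soil uniformly
# low. That is sufficient to exercise the sign structure of the MDVI.

.sigKnots <- list(
  plant          = cbind(c(600, 681, 706, 759, 772, 1000),
                         c(0.08, 0.08, 0.15, 0.55, 0.62, 0.62)),
  weed           = cbind(c(600, 681, 706, 759, 772, 1000),
                         c(0.11, 0.11, 0.16, 0.50, 0.55, 0.55)),
  neighbor_plant = cbind(c(600, 681, 706, 759, 772, 1000),
                         c(0.07, 0.07, 0.14, 0.56, 0.60, 0.60)),
  soil           = cbind(c(600, 1000), c(0.12, 0.18)),
  film           = cbind(c(600, 1000), c(0.70, 0.74)),
  straw          = cbind(c(600, 1000), c(0.32, 0.38)))

#' Default spectral signatures for the synthetic scene objects
#'
#' Piecewise-linear reflectance templates per object kind, evaluated at
#' the profile's wavelengths. Vegetation (plant, weed, neighbor plant)
#' has red reflectance below 0.15 and a near-infrared plateau above 0.5;
#' mulch film is uniformly at or above 0.6 (polyethylene has no
#' absorption feature in this range); soil stays at or below 0.2; straw
#' sits flat in between.
#'
#' @param profile a [SensorProfile-class].
#' @return numeric matrix, one row per object kind (rownames), one column
#'   per band.
#' @export
defaultSignatures <- function(profile) {
  wl <- profile@wavelengths
  sig <- t(vapply(.sigKnots, function(k)
    approx(k[, 1L], k[, 2L], xout = wl, rule = 2L)$y,
    numeric(length(wl))))
  colnames(sig) <- as.character(wl)
  sig
}

.ellipseMask <- function(h, w, center, radii) {
  r <- outer(((seq_len(h) - center[1L]) / radii[1L])^2,
             ((seq_len(w) - center[2L]) / radii[2L])^2, "+")
  r <= 1
}

#' Specify a synthetic field scene
#'
#' Fixes the geometry, noise level, grayscale model and SPAD field of a
#' synthetic scene. Geometry is expressed as fractions of the scene shape
#' so the same spec scales from the fast 64 x 64 test profile up to the
#' full 217 x 409 sensor geometry. The grayscale model is the inverse of
#' the calibration line: `G = round((R - grayIntercept) / graySlope)`
#' clamped to the bit depth, with full scale at reflectance 1.6 by
#' default so noisy or SPAD-adjusted reflectances survive quantization
#' unclipped.
#'
#' @param seed integer; all stochastic draws of the scene flow from it.
#' @param shape integer `(H, W)` (default `c(64, 64)`; the sensor-sized
#'   scene is `c(217, 409)`).
#' @param noiseSd per-pixel Gaussian reflectance noise SD (default 0).
#' @param signatureJitter per-band multiplicative signature jitter SD
#'   (default 0.01).
#' @param bitDepth grayscale quantization (default 10).
#' @param graySlope,grayIntercept per-band affine reflectance = a*G + b;
#'   scalars are recycled over bands. The default slope `1.6 / 2^bitDepth`
#'   puts full scale at reflectance 1.6 (headroom for noise and the SPAD
#'   field) and represents the board's quarter levels exactly.
#' @param spadField `list(center =, edge =)` SPAD values at the plant
#'   center and rim, or `NULL` for no SPAD field.
#' @param plantCenter,plantRadii,weedCenter,weedRadii,neighborCenter,neighborRadii
#'   fractions of `(H, W)`.
#' @param profile a [SensorProfile-class].
#' @return a `SceneSpec` (plain list, class `"SceneSpec"`).
#' @export
sceneSpec <- function(seed, shape = c(64L, 64L), noiseSd = 0,
                      signatureJitter = 0.01, bitDepth = 10L,
                      graySlope = 1.6 / 2^bitDepth, grayIntercept = 0,
                      spadField = list(center = 52, edge = 44),
                      plantCenter = c(0.52, 0.45), plantRadii = c(0.24, 0.22),
                      weedCenter = c(0.88, 0.10), weedRadii = c(0.06, 0.05),
                      neighborCenter = c(0.20, 0.02),
                      neighborRadii = c(0.08, 0.06),
                      profile = defaultSensorProfile()) {
  B <- length(profile@wavelengths)
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 noiseSd = noiseSd, signatureJitter = signatureJitter,
                 bitDepth = as.integer(bitDepth),
                 graySlope = rep_len(graySlope, B),
                 grayIntercept = rep_len(grayIntercept, B),
                 spadField = spadField, plantCenter = plantCenter,
                 plantRadii = plantRadii, weedCenter = weedCenter,
                 weedRadii = weedRadii, neighborCenter = neighborCenter,
                 neighborRadii = neighborRadii, profile = profile),
            class = "SceneSpec")
}

.withSceneSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic scene with ground truth
#'
#' Paints the scene back-to-front (soil, film, straw, board, weed,
#' neighbor plant, target plant) at the profile's wavelengths, applies
#' per-scene signature jitter and per-pixel Gaussian reflectance noise,
#' embeds a known per-pixel SPAD field in the plant by adjusting the
#' 935 nm band so the published linear model is exactly invertible on the
#' noise-free cube, and derives the grayscale cube through the per-band
#' affine gray model with quantization to the bit depth. Deterministic
#' for a fixed seed; the caller's RNG state is left untouched.
#'
#' @param spec a `SceneSpec` from [sceneSpec()].
#' @return a `SceneBundle`: list with `cubeGrayscale`, `cubeReflectance`
#'   (noise applied, pre-quantization truth), `plantMask` (ground-truth
#'   [BinaryMask-class]), `boardBoxes`, `boardNominal`, `spadTruth`
#'   (`H x W`, 0 outside the plant), `tableTruth` (per-object mean
#'   noise-free spectra), `objectMasks` (logical painting masks per
#'   object kind) and `spec`.
#' @export
generateScene <- function(spec) {
  .withSceneSeed(spec$seed, {
    profile <- spec$profile
    wl <- profile@wavelengths
    B <- length(wl)
    h <- spec$shape[1L]; w <- spec$shape[2L]
    sig <- defaultSignatures(profile)
    jit <- 1 + matrix(rnorm(nrow(sig) * B, sd = spec$signatureJitter),
                      nrow(sig), B)
    sig <- sig * jit
    rownames(jit) <- rownames(sig)

    # board geometry: 4 small panels in a row, top-left corner (the board
    # occupies ~1% of the frame, as in a field view)
    ph <- max(3L, round(0.05 * h)); pw <- max(3L, round(0.04 * w))
    boardBoxes <- lapply(0:3, function(k)
      list(row = 2L, col = 2L + k * (pw + 1L), height = ph, width = pw))
    boardNominal <- c(1.0, 0.75, 0.5, 0)

    # the plant blob is the iterated-median fixed point of its ellipse so
    # the segmentation chain's single median pass leaves it unchanged
    plantMask <- .ellipseMask(h, w, spec$plantCenter * c(h, w),
                              pmax(spec$plantRadii * c(h, w), 2))
    for (it in 1:10) {
      filtered <- medianFilterMask(BinaryMask(plantMask), 3L)@data == 1L
      if (identical(filtered, plantMask)) break
      plantMask <- filtered
    }

    masks <- list(
      soil = matrix(TRUE, h, w),
      film = {
        m <- matrix(FALSE, h, w)
        m[, max(1L, round(0.91 * w)):round(0.94 * w)] <- TRUE
        m
      },
      straw = {
        m <- matrix(FALSE, h, w)
        m[round(0.82 * h):round(0.86 * h), round(0.10 * w):round(0.30 * w)] <- TRUE
        m[round(0.12 * h):round(0.15 * h), round(0.55 * w):round(0.65 * w)] <- TRUE
        m
      },
      weed = .ellipseMask(h, w, spec$weedCenter * c(h, w),
                          pmax(spec$weedRadii * c(h, w), 1.5)),
      neighbor_plant = .ellipseMask(h, w, spec$neighborCenter * c(h, w),
                                    pmax(spec$neighborRadii * c(h, w), 1.5)),
      plant = plantMask)

    boardMask <- matrix(FALSE, h, w)
    for (bx in boardBoxes)
      boardMask[bx$row:(bx$row + bx$height - 1L),
                bx$col:(bx$col + bx$width - 1L)] <- TRUE
    if (any(masks$plant & boardMask))
      .stopInput("BadLayout", "plant overlaps the correction board")

    refl <- array(0, dim = c(h, w, B))
    paint <- function(mask, spectrum) {
      for (b in seq_len(B)) {
        band <- refl[, , b]
        band[mask] <- spectrum[b]
        refl[, , b] <<- band
      }
    }
    paint(masks$soil, sig["soil", ])
    paint(masks$film, sig["film", ])
    paint(masks$straw, sig["straw", ])
    for (k in seq_along(boardBoxes)) {
      bx <- boardBoxes[[k]]
      m <- matrix(FALSE, h, w)
      m[bx$row:(bx$row + bx$height - 1L),
        bx$col:(bx$col + bx$width - 1L)] <- TRUE
      paint(m, rep(boardNominal[k], B))
    }
    paint(masks$weed, sig["weed", ])
    paint(masks$neighbor_plant, sig["neighbor_plant", ])
    paint(masks$plant, sig["plant", ])

    # embed the SPAD field: radial target, exactly invertible through the
    # published model by adjusting the 935 nm band
    spadTruth <- matrix(0, h, w)
    if (!is.null(spec$spadField)) {
      model <- publishedSpadModel()
      ctr <- spec$plantCenter * c(h, w)
      rad <- pmax(spec$plantRadii * c(h, w), 2)
      dn <- sqrt(outer(((seq_len(h) - ctr[1L]) / rad[1L])^2,
                       ((seq_len(w) - ctr[2L]) / rad[2L])^2, "+"))
      target <- spec$spadField$edge +
        (spec$spadField$center - spec$spadField$edge) * (1 - pmin(dn, 1))
      pred <- matrix(model@intercept, h, w)
      for (j in seq_along(model@wavelengths))
        pred <- pred + model@coefficients[j] *
          refl[, , .bandIndex(wl, model@wavelengths[j])]
      b935 <- .bandIndex(wl, 935)
      adj <- refl[, , b935]
      adj[masks$plant] <- adj[masks$plant] +
        (target[masks$plant] - pred[masks$plant]) / 6.190
      refl[, , b935] <- adj
      spadTruth[masks$plant] <- target[masks$plant]
    }

    if (spec$noiseSd > 0)
      refl <- refl + array(rnorm(h * w * B, sd = spec$noiseSd),
                           dim = c(h, w, B))

    gmax <- 2^spec$bitDepth - 1
    gray <- array(0, dim = c(h, w, B))
    for (b in seq_len(B))
      gray[, , b] <- pmin(pmax(round((refl[, , b] - spec$grayIntercept[b]) /
                                       spec$graySlope[b]), 0), gmax)

    tableTruth <- data.frame(kind = rownames(sig), sig,
                             check.names = FALSE, row.names = NULL)

    list(cubeGrayscale = SpectralCube(gray, wl, "grayscale",
                                      spec$bitDepth),
         cubeReflectance = SpectralCube(refl, wl, "reflectance",
                                        spec$bitDepth),
         plantMask = BinaryMask(masks$plant, "reference"),
         boardBoxes = boardBoxes, boardNominal = boardNominal,
         spadTruth = spadTruth, tableTruth = tableTruth,
         objectMasks = masks, spec = spec)
  })
}

#' Generate a synthetic spectra table with known SPAD structure
#'
#' Draws per-sample reflectance vectors from a smooth low-rank spectral
#' model (plant-like base spectrum plus `nLatent` Gaussian-bump
#' components with standard-normal scores, plus independent per-band
#' noise) and computes `SPAD = intercept + weights . R + eps`. Weights
#' are zero outside `informativeBands`. Defaults give SPAD values
#' spanning roughly the agronomic 17-53 range. With `nLatent = 0` the
#' bands are mutually independent, which makes the non-informative bands
#' pure noise — the configuration used for variable-selection checks.
#'
#' @param n samples (`>= 3`).
#' @param seed integer RNG seed (caller state is preserved).
#' @param trueWeights optional full-length weight vector; overrides
#'   `informativeBands`/`weightValues`.
#' @param intercept SPAD intercept; default centers mean SPAD near 36.
#' @param noiseSd SD of the SPAD noise `eps` (default 1.5).
#' @param informativeBands nm with nonzero weight
#'   (default `c(681, 888, 935)`).
#' @param weightValues weights assigned to the informative bands
#'   (recycled; default `c(-40, 30, 40)`).
#' @param nLatent smooth latent components (default 3; 0 = independent
#'   bands).
#' @param reflNoiseSd per-band reflectance noise SD (default 0.08).
#' @param profile a [SensorProfile-class].
#' @return spectra table data.frame (`sample_id`, `spad`, `stage`, one
#'   column per nm) with attributes `trueWeights`, `intercept`,
#'   `noiseSd`, `informativeBands`.
#' @export
generateSpectraDataset <- function(n, seed, trueWeights = NULL,
                                   intercept = NULL, noiseSd = 1.5,
                                   informativeBands = c(681, 888, 935),
                                   weightValues = c(-40, 30, 40),
                                   nLatent = 3L, reflNoiseSd = 0.08,
                                   profile = defaultSensorProfile()) {
  if (n < 3L)
    .stopDegenerate("TooFewSamples", "need at least 3 samples")
  .withSceneSeed(seed, {
    wl <- profile@wavelengths
    B <- length(wl)
    mu <- defaultSignatures(profile)["plant", ]
    if (is.null(trueWeights)) {
      trueWeights <- numeric(B)
      idx <- vapply(informativeBands, function(w) .bandIndex(wl, w),
                    integer(1L))
      trueWeights[idx] <- rep_len(weightValues, length(idx))
    }
    X <- matrix(rep(mu, each = n), n, B)
    if (nLatent > 0L) {
      centers <- seq(min(wl), max(wl), length.out = nLatent + 2L)[-c(1L, nLatent + 2L)]
      for (k in seq_len(nLatent)) {
        bump <- 0.05 * exp(-((wl - centers[k]) / 60)^2)
        X <- X + outer(rnorm(n), bump)
      }
    }
    X <- X + matrix(rnorm(n * B, sd = reflNoiseSd), n, B)
    if (is.null(intercept)) intercept <- 36 - sum(trueWeights * mu)
    spad <- intercept + drop(X %*% trueWeights) + rnorm(n, sd = noiseSd)
    tbl <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                      spad = spad,
                      stage = rep_len(c("S1", "S2"), n),
                      X, check.names = FALSE)
    names(tbl)[-(1:3)] <- as.character(wl)
    attr(tbl, "trueWeights") <- trueWeights
    attr(tbl, "intercept") <- intercept
    attr(tbl, "noiseSd") <- noiseSd
    attr(tbl, "informativeBands") <- informativeBands
    tbl
  })
}
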