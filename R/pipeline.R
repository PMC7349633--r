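#' Pipeline configuration
#'
#' Bundles the operating point of the processing chain. The defaults are
#' the selected field operating point: modified coefficient 2.5,
#' 8-connectivity, UVE threshold 1.0, SPXY split 2:1, display range 0-60
#' SPAD.
#'
#' @param profilePath optional sensor profile file; `NULL` means the
#'   built-in reference profile.
#' @param alpha MDVI modified coefficient.
#' @param connectivity 4 or 8.
#' @param uveThreshold reliability-index cutoff.
#' @param splitRatio integer pair `(cal, val)`.
#' @param colorRange SPAD display range `(low, high)`.
#' @param outputDir directory for artifacts, or `NULL` to skip writing.
#' @param mode `"train"`, `"predict"` or `"evaluate"`.
#' @return a `PipelineConfig` (plain list, class `"PipelineConfig"`).
#' @export
pipelineConfig <- function(profilePath = NULL, alpha = 2.5,
                           connectivity = 8L, uveThreshold = 1.0,
                           splitRatio = c(2L, 1L), colorRange = c(0, 60),
                           outputDir = NULL, mode = "train") {
  structure(list(profilePath = profilePath, alpha = alpha,
                 connectivity = as.integer(connectivity),
                 uveThreshold = uveThreshold,
                 splitRatio = as.integer(splitRatio),
                 colorRange = as.numeric(colorRange),
                 outputDir = outputDir, mode = mode),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' Round-trips losslessly; fields absent from the file fall back to the
#' defaults of [pipelineConfig()].
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return [readPipelineConfig()] returns a `PipelineConfig`;
#'   [writePipelineConfig()] returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    .stopInput("BadInput", sprintf("config not found: %s", path))
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  do.call(pipelineConfig, obj)
}

#' @rdname readPipelineConfig
#' @param config a `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  obj <- unclass(config)
  obj <- obj[!vapply(obj, is.null, logical(1L))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

.configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writePipelineConfig(config, f)
  unname(tools::md5sum(f))
}

.writeRunLog <- function(config, stage_seconds, seeds, outputDir) {
  log <- list(config_hash = .configHash(config), seeds = seeds,
              stage_seconds = stage_seconds,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(log, file.path(outputDir, "run-log.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Validate a fit/predict report structure
#'
#' Checks the machine-readable reports against the published schema
#' (`inst/schema/report-schema.json`): required fields present with the
#' right types.
#'
#' @param report a report list from [runTrain()] or [runPredict()].
#' @param kind `"fit"` or `"predict"`.
#' @return `TRUE` invisibly; raises an input error otherwise.
#' @export
validateReport <- function(report, kind = c("fit", "predict")) {
  kind <- match.arg(kind)
  need <- if (kind == "fit") {
    c("n_calibration", "n_validation", "selected_wavelengths",
      "n_components", "calibration", "validation")
  } else {
    c("mean_spad", "min", "max", "n_pixels", "otsu_threshold", "alpha")
  }
  miss <- setdiff(need, names(report))
  if (length(miss))
    .stopInput("BadInput",
               sprintf("report lacks fields: %s", paste(miss, collapse = ", ")))
  invisible(TRUE)
}

#' Train a SPAD detection model from a spectra table
#'
#' The model-building flow: SPXY split at the configured ratio, UVE
#' wavelength selection on the calibration set, leave-one-out selection
#' of the PLS component count on the retained wavelengths, final PLS fit,
#' and metrics on both subsets. Artifacts (`model.json` bundle,
#' `fit.json` report, `run-log.json`) are written when the config names
#' an output directory.
#'
#' @param table a spectra table (data.frame with `sample_id`, `spad` and
#'   one column per nm), at least 3 samples.
#' @param config a `PipelineConfig`.
#' @return invisible list with `bundle` (model bundle list), `report`
#'   (fit report list), `spadModel`, `plsModel`, `uve`, `split`.
#' @export
runTrain <- function(table, config = pipelineConfig()) {
  t0 <- proc.time()[["elapsed"]]
  n <- nrow(table)
  if (is.null(n) || n < 3L)
    .stopDegenerate("TooFewSamples",
                    sprintf("training needs at least 3 samples, got %s",
                            if (is.null(n)) 0L else n))
  X <- spectraMatrix(table)
  wl <- tableWavelengths(table)
  y <- table$spad
  split <- spxySplit(table, ratio = config$splitRatio)
  tSplit <- proc.time()[["elapsed"]]
  Xc <- X[split$calibration, , drop = FALSE]
  yc <- y[split$calibration]
  nc <- length(split$calibration)
  maxK <- min(nc - 2L, ncol(Xc), 15L)
  # component count for the stability jackknife comes from LOOCV on the
  # full spectrum, mirroring how the final model's count is chosen
  kFull <- plsSelectComponents(Xc, yc, maxComponents = maxK)$bestK
  uve <- uveSelect(Xc, yc, nComponents = kFull,
                   threshold = config$uveThreshold, wavelengths = wl)
  keep <- match(uve@selectedWavelengths, wl)
  if (length(keep) == 0L) {
    # nothing cleared the cutoff: elimination is skipped, not fatal
    message("runTrain: no wavelength reached the UVE cutoff; keeping all")
    keep <- seq_along(wl)
  }
  tUve <- proc.time()[["elapsed"]]
  Xs <- Xc[, keep, drop = FALSE]
  selK <- plsSelectComponents(Xs, yc,
                              maxComponents = min(maxK, length(keep)))
  pls <- plsFit(Xs, yc, selK$bestK, wavelengths = wl[keep])
  pls@rmsecv <- selK$rmsecv
  spad <- asSpadModel(pls)
  calMetrics <- evaluateModel(yc, predict(pls, Xs))
  Xv <- X[split$validation, keep, drop = FALSE]
  yv <- y[split$validation]
  valMetrics <- if (length(yv) >= 2L)
    metricsList(evaluateModel(yv, predict(pls, Xv))) else NULL
  tFit <- proc.time()[["elapsed"]]
  bundle <- list(schema_version = 1L,
                 model = list(intercept = spad@intercept,
                              terms = as.list(stats::setNames(
                                spad@coefficients,
                                as.character(spad@wavelengths)))),
                 uve = list(threshold = uve@threshold,
                            reliability_index = as.list(uve@reliabilityIndex),
                            selected_wavelengths = uve@selectedWavelengths),
                 pls = list(n_components = pls@nComponents,
                            rmsecv = selK$rmsecv),
                 wavelengths = wl)
  report <- list(n_calibration = nc, n_validation = length(split$validation),
                 selected_wavelengths = wl[keep],
                 n_components = pls@nComponents,
                 calibration = metricsList(calMetrics),
                 validation = valMetrics)
  validateReport(report, "fit")
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    writeSpadModel(spad, file.path(config$outputDir, "model.json"))
    jsonlite::write_json(bundle, file.path(config$outputDir, "bundle.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report, file.path(config$outputDir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
    .writeRunLog(config,
                 list(split = tSplit - t0, uve = tUve - tSplit,
                      fit = tFit - tUve),
                 seeds = list(), outputDir = config$outputDir)
  }
  invisible(list(bundle = bundle, report = report, spadModel = spad,
                 plsModel = pls, uve = uve, split = split))
}

#' Predict a SPAD map for one scene
#'
#' The detection flow of the deployed system: calibrate the grayscale
#' cube (when a calibration model or board boxes are supplied), segment
#' the plant at the configured modified coefficient, extract the masked
#' mean reflectance, predict the per-pixel SPAD map and render it.
#' Deterministic given its inputs. Artifacts (mask PNG, SPAD raster TIFF,
#' pseudo-color PNG, `summary.json`, `run-log.json`) are written when the
#' config names an output directory.
#'
#' @param cube a [SpectralCube-class] (grayscale with calibration, or
#'   already-calibrated reflectance).
#' @param model a [SpadModel-class] (default the shipped published
#'   model).
#' @param config a `PipelineConfig`.
#' @param calibration optional [CalibrationModel-class].
#' @param boardBoxes optional list of 4 rectangles; when given (and no
#'   `calibration`), the calibration is fitted from the cube itself.
#' @return invisible list with `map` ([SpadMap-class]), `segmentation`
#'   ([SegmentationResult-class]), `meanReflectance`, `summary` (report
#'   list).
#' @export
runPredict <- function(cube, model = publishedSpadModel(),
                       config = pipelineConfig(), calibration = NULL,
                       boardBoxes = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(calibration) && !is.null(boardBoxes))
    calibration <- fitCalibration(extractBoardReading(cube, boardBoxes))
  refl <- if (!is.null(calibration) && cube@valueKind == "grayscale") {
    applyCalibration(cube, calibration)
  } else cube
  tCal <- proc.time()[["elapsed"]]
  seg <- segmentPlant(refl, alpha = config$alpha,
                      connectivity = config$connectivity)
  tSeg <- proc.time()[["elapsed"]]
  mask <- seg@precisionMask
  meanRefl <- extractMeanReflectance(refl, mask)
  map <- predictMap(refl, mask, model, colorRange = config$colorRange)
  tMap <- proc.time()[["elapsed"]]
  inMask <- map@values[mask@data == 1L]
  summary <- list(mean_spad = map@meanSpad, min = min(inMask),
                  max = max(inMask), n_pixels = sum(mask@data),
                  otsu_threshold = seg@otsuThreshold, alpha = config$alpha)
  validateReport(summary, "predict")
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    writeMask(mask, file.path(config$outputDir, "mask.png"))
    writeSpadMap(map,
                 rasterPath = file.path(config$outputDir, "spad.tif"),
                 renderPath = file.path(config$outputDir, "spad.png"),
                 summaryPath = file.path(config$outputDir, "summary.json"))
    .writeRunLog(config,
                 list(calibrate = tCal - t0, segment = tSeg - tCal,
                      map = tMap - tSeg),
                 seeds = list(), outputDir = config$outputDir)
  }
  invisible(list(map = map, segmentation = seg, meanReflectance = meanRefl,
                 summary = summary))
}
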