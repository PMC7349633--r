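#' Masked mean reflectance of a cube
#'
#' Multiplies each band by the plant mask and averages over the retained
#' pixels, producing the per-sample mean reflectance vector used for model
#' building (one entry per band; 25 for the reference profile).
#'
#' @param cube a reflectance [SpectralCube-class].
#' @param mask a [BinaryMask-class] of matching shape with at least one
#'   foreground pixel.
#' @return named numeric vector (names = wavelengths in nm).
#' @export
extractMeanReflectance <- function(cube, mask) {
  m <- if (is(mask, "BinaryMask")) mask@data else mask
  d <- dim(cube@data)
  if (!all(dim(m) == d[1:2]))
    .stopInput("ShapeMismatch", "mask and cube differ in shape")
  idx <- which(m == 1L)
  if (length(idx) == 0L)
    .stopDegenerate("EmptyMask", "mask has no foreground pixels")
  out <- vapply(seq_len(d[3L]), function(b) mean(cube@data[, , b][idx]),
                numeric(1L))
  names(out) <- as.character(cube@wavelengths)
  out
}

# ---- SPXY -------------------------------------------------------------

#' Deterministic calibration/validation split by joint X-Y distance (SPXY)
#'
#' Kennard-Stone-style selection on the joint distance
#' `d = d_x / max(d_x) + d_y / max(d_y)` (Euclidean in X and in the
#' response): the pair at maximal joint distance seeds the calibration
#' set, then the sample maximizing its minimal distance to the selected
#' set is added until the calibration set holds
#' `ceiling(n * cal / (cal + val))` samples; the remainder forms the
#' validation set. At the reference 2:1 ratio a 100-sample table splits
#' 67/33.
#'
#' @param x a spectra table (data.frame from [readSpectraTable()] /
#'   [generateSpectraDataset()]) or an `n x p` numeric matrix.
#' @param y response vector; taken from the table's `spad` column when
#'   `x` is a table.
#' @param ratio integer pair `(cal, val)`, default `c(2, 1)`.
#' @return list with integer index vectors `calibration` and `validation`
#'   (disjoint, union = all samples, in selection / original order), plus
#'   `ids` entries when `x` carries a `sample_id` column.
#' @export
spxySplit <- function(x, y = NULL, ratio = c(2, 1)) {
  ids <- NULL
  if (is.data.frame(x)) {
    ids <- x$sample_id
    y <- x$spad
    x <- spectraMatrix(x)
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L)
    .stopDegenerate("TooFewSamples",
                    sprintf("need at least 3 samples, got %d", n))
  if (length(ratio) != 2L || any(ratio <= 0) || any(ratio != round(ratio)))
    .stopInput("BadInput", "ratio must be two positive integers")
  dx <- as.matrix(dist(x))
  dy <- abs(outer(as.numeric(y), as.numeric(y), "-"))
  mx <- max(dx); my <- max(dy)
  d <- (if (mx > 0) dx / mx else dx) + (if (my > 0) dy / my else dy)
  nCal <- ceiling(n * ratio[1L] / sum(ratio))
  nCal <- min(max(nCal, 2L), n - 1L)
  seed <- which(d == max(d), arr.ind = TRUE)[1L, ]
  sel <- sort(as.integer(seed))
  while (length(sel) < nCal) {
    rest <- setdiff(seq_len(n), sel)
    minDist <- apply(d[rest, sel, drop = FALSE], 1L, min)
    sel <- c(sel, rest[which.max(minDist)])
  }
  out <- list(calibration = sel, validation = setdiff(seq_len(n), sel))
  if (!is.null(ids)) {
    out$calibrationIds <- ids[out$calibration]
    out$validationIds <- ids[out$validation]
  }
  out
}

# ---- PLS1 (NIPALS) ----------------------------------------------------

# NIPALS PLS1 path: weights, loadings and collapsed coefficients for every
# component count 1..ncomp. Stops early if the X or y residual degenerates.
.plsPath <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2L, xm); f <- y - ym
  W <- P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  k <- 0L
  for (a in seq_len(ncomp)) {
    wv <- drop(crossprod(E, f))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) break
    wv <- wv / nw
    tv <- drop(E %*% wv)
    tt <- sum(tv^2)
    if (tt < 1e-24) break
    pv <- drop(crossprod(E, tv)) / tt
    qv <- sum(f * tv) / tt
    E <- E - tcrossprod(tv, pv)
    f <- f - tv * qv
    k <- a
    W[, a] <- wv; P[, a] <- pv; q[a] <- qv
  }
  if (k == 0L)
    .stopDegenerate("DegenerateTarget", "no usable latent component")
  coefs <- matrix(0, p, k)
  for (a in seq_len(k)) {
    Wa <- W[, 1:a, drop = FALSE]; Pa <- P[, 1:a, drop = FALSE]
    coefs[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[1:a])
  }
  list(xMean = xm, yMean = ym, coefs = coefs, k = k)
}

#' Fit a PLS1 regression model
#'
#' Mean-centered NIPALS partial least squares with a single response.
#' Predictors are not autoscaled by default (reflectances share one
#' scale); set `autoscale = TRUE` to divide each column by its standard
#' deviation. The collapsed coefficient vector is exposed so that
#' `prediction = yMean + (x - xMean) %*% coefficients`.
#'
#' @param X `n x p` numeric matrix of predictors.
#' @param y numeric response of length `n`.
#' @param nComponents integer latent components, `1 <= k <= min(n-1, p)`.
#' @param wavelengths optional nm labels for the predictor columns.
#' @param autoscale logical, divide columns by their SD before fitting.
#' @return a [PlsModel-class].
#' @export
plsFit <- function(X, y, nComponents, wavelengths = NULL,
                   autoscale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (nComponents < 1L || nComponents > min(n - 1L, p))
    .stopInput("BadComponents",
                    sprintf("nComponents must be in 1..%d", min(n - 1L, p)))
  if (var(y) == 0)
    .stopDegenerate("DegenerateTarget", "response has zero variance")
  sds <- rep(1, p)
  if (autoscale) {
    sds <- apply(X, 2L, sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2L, sds, "/")
  }
  path <- .plsPath(X, y, nComponents)
  k <- min(path$k, nComponents)
  b <- path$coefs[, k] / sds
  if (is.null(wavelengths))
    wavelengths <- suppressWarnings(as.numeric(colnames(X)))
  if (is.null(wavelengths) || any(is.na(wavelengths)))
    wavelengths <- seq_len(p)
  new("PlsModel", nComponents = as.integer(k),
      xMean = path$xMean * sds, yMean = path$yMean,
      coefficients = as.numeric(b),
      trainingWavelengths = as.numeric(wavelengths), rmsecv = numeric(0))
}

#' Predict from a PLS model
#' @param object a [PlsModel-class].
#' @param newdata `n x p` matrix or length-`p` vector.
#' @param ... ignored.
#' @return numeric predictions.
#' @export
setMethod("predict", "PlsModel", function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
       else as.matrix(newdata)
  drop(object@yMean + sweep(X, 2L, object@xMean) %*% object@coefficients)
})

setMethod("show", "PlsModel", function(object) {
  cat(sprintf("PlsModel: %d components, %d predictors\n",
              object@nComponents, length(object@coefficients)))
})

#' Select the PLS component count by leave-one-out cross validation
#'
#' For every component count `k = 1..maxComponents` the root mean square
#' error of leave-one-out cross validation (RMSECV) is computed; the
#' minimizing `k` is returned, with ties broken toward the smaller count.
#'
#' @param X `n x p` matrix, `n >= 3`.
#' @param y numeric response.
#' @param maxComponents upper bound on `k`
#'   (default `min(n - 1, p, 15)`).
#' @return list with `bestK` and the numeric vector `rmsecv`.
#' @export
plsSelectComponents <- function(X, y,
                                maxComponents = min(nrow(X) - 1L, ncol(X),
                                                    15L)) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L)
    .stopDegenerate("TooFewSamples", "LOOCV needs at least 3 samples")
  maxComponents <- min(maxComponents, n - 2L, ncol(X))
  press <- matrix(NA_real_, n, maxComponents)
  for (i in seq_len(n)) {
    path <- .plsPath(X[-i, , drop = FALSE], y[-i], maxComponents)
    xc <- X[i, ] - path$xMean
    pred <- path$yMean + drop(xc %*% path$coefs)
    press[i, seq_len(path$k)] <- (y[i] - pred)^2
    if (path$k < maxComponents)  # degenerate tail: carry the last fit
      press[i, (path$k + 1L):maxComponents] <- (y[i] - pred[path$k])^2
  }
  rmsecv <- sqrt(colMeans(press))
  list(bestK = which.min(rmsecv), rmsecv = rmsecv)
}

# ---- UVE --------------------------------------------------------------

#' Uninformative variable elimination by coefficient stability
#'
#' Refits the PLS model with each sample left out in turn and summarizes
#' the stability of every variable's regression coefficient as a
#' reliability index,
#' `RI_j = mean_i(b_ij) / ((n - 1) * sd_i(b_ij))`,
#' i.e. the mean leave-one-out coefficient divided by the standard
#' deviation of its jackknife pseudo-values. The pseudo-value scaling
#' makes RI independent of sample size (a t-like statistic divided by
#' `sqrt(n - 1)`), so a fixed cutoff of 1.0 is meaningful across datasets:
#' a variable is kept when `|RI_j| >= threshold`. If a coefficient is
#' perfectly stable (`sd = 0`) with nonzero mean, its RI is infinite and
#' the variable is always selected.
#'
#' With `noiseAugment = TRUE` the classic construction is used instead:
#' `p` artificial noise columns are appended and the cutoff is the maximal
#' `|RI|` observed among them, overriding `threshold`.
#'
#' @param X `n x p` matrix, `n >= 3`.
#' @param y numeric response.
#' @param nComponents latent components for the underlying PLS fits.
#' @param threshold RI cutoff (default 1.0).
#' @param noiseAugment logical, use the noise-augmented cutoff.
#' @param wavelengths optional nm labels for the columns.
#' @return an [UveResult-class].
#' @export
uveSelect <- function(X, y, nComponents, threshold = 1.0,
                      noiseAugment = FALSE, wavelengths = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L)
    .stopDegenerate("TooFewSamples", "UVE needs at least 3 samples")
  if (is.null(wavelengths))
    wavelengths <- suppressWarnings(as.numeric(colnames(X)))
  if (is.null(wavelengths) || any(is.na(wavelengths)))
    wavelengths <- seq_len(p)
  Xa <- X
  if (noiseAugment) {
    noise <- matrix(rnorm(n * p, sd = mean(apply(X, 2L, sd))), n, p)
    Xa <- cbind(X, noise)
  }
  pa <- ncol(Xa)
  B <- matrix(0, pa, n)
  for (i in seq_len(n)) {
    path <- .plsPath(Xa[-i, , drop = FALSE], y[-i],
                     min(nComponents, n - 2L, pa))
    B[, i] <- path$coefs[, min(path$k, nComponents)]
  }
  bbar <- rowMeans(B)
  s <- apply(B, 1L, sd) * (n - 1)
  ri <- ifelse(s > 0, bbar / s, ifelse(bbar != 0, Inf, 0))
  riReal <- ri[seq_len(p)]
  cutoff <- threshold
  if (noiseAugment) cutoff <- max(abs(ri[(p + 1L):pa]))
  names(riReal) <- as.character(wavelengths)
  selected <- which(abs(riReal) >= cutoff)
  new("UveResult", reliabilityIndex = riReal, threshold = cutoff,
      selectedWavelengths = as.numeric(wavelengths[selected]))
}

#' @describeIn uveSelect logical selection vector for a result.
#' @param result an [UveResult-class].
#' @export
uveSelected <- function(result) {
  abs(result@reliabilityIndex) >= result@threshold
}

setMethod("show", "UveResult", function(object) {
  cat(sprintf("UveResult: %d/%d variables selected at |RI| >= %.3g\n",
              length(object@selectedWavelengths),
              length(object@reliabilityIndex), object@threshold))
})

# ---- Metrics ----------------------------------------------------------

#' Evaluate SPAD predictions
#'
#' Determination coefficient `R2 = 1 - SSE/SST`, root mean square error
#' `RMSE = sqrt(sum((y1 - y2)^2) / n)` and ratio of performance to
#' deviation `RPD = Std / RMSE`, where `Std` is the standard deviation of
#' the measured values (or `referenceStd` when supplied). Grade: good
#' (`RPD > 2`), middle (`1.4 <= RPD <= 2`), poor (`RPD < 1.4`).
#'
#' @param yTrue,yPred numeric vectors of equal length `>= 2`.
#' @param referenceStd optional reference standard deviation for the RPD.
#' @return a [ModelMetrics-class].
#' @export
evaluateModel <- function(yTrue, yPred, referenceStd = NULL) {
  if (length(yTrue) != length(yPred) || length(yTrue) < 2L)
    .stopInput("BadInput", "yTrue and yPred must share a length >= 2")
  n <- length(yTrue)
  sse <- sum((yTrue - yPred)^2)
  sst <- sum((yTrue - mean(yTrue))^2)
  if (sst == 0)
    .stopDegenerate("DegenerateTarget", "measured values are constant")
  r2 <- 1 - sse / sst
  rmse <- sqrt(sse / n)
  if (rmse == 0)
    .stopDegenerate("DegenerateMetric", "RMSE is zero; RPD undefined")
  stdv <- if (is.null(referenceStd)) sd(yTrue) else referenceStd
  rpd <- stdv / rmse
  grade <- if (rpd > 2) "good" else if (rpd >= 1.4) "middle" else "poor"
  new("ModelMetrics", r2 = r2, rmse = rmse, rpd = rpd, n = as.integer(n),
      grade = grade)
}

setMethod("show", "ModelMetrics", function(object) {
  cat(sprintf("ModelMetrics: R2 = %.3f, RMSE = %.3f, RPD = %.3f (%s, n = %d)\n",
              object@r2, object@rmse, object@rpd, object@grade, object@n))
})

#' Metrics as a plain list
#' @param metrics a [ModelMetrics-class].
#' @return list with `r2`, `rmse`, `rpd`, `n`, `grade`.
#' @export
metricsList <- function(metrics) {
  list(r2 = metrics@r2, rmse = metrics@rmse, rpd = metrics@rpd,
       n = metrics@n, grade = metrics@grade)
}

# ---- Spectra tables ---------------------------------------------------

#' Spectra table I/O and accessors
#'
#' A spectra table is a data.frame with columns `sample_id`, `spad`,
#' `stage` and one numeric column per wavelength (header = nm). This is
#' the on-disk CSV layout too.
#'
#' @param path CSV file path.
#' @return [readSpectraTable()] returns the data.frame;
#'   [writeSpectraTable()] returns `path` invisibly.
#' @export
readSpectraTable <- function(path) {
  if (!file.exists(path))
    .stopInput("BadInput", sprintf("spectra table not found: %s", path))
  tbl <- read.csv(path, check.names = FALSE)
  need <- c("sample_id", "spad")
  if (!all(need %in% names(tbl)))
    .stopInput("BadInput", "spectra table needs sample_id and spad columns")
  tbl
}

#' @rdname readSpectraTable
#' @param table a spectra table data.frame.
#' @export
writeSpectraTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname readSpectraTable
#' @export
spectraMatrix <- function(table) {
  wlCols <- !is.na(suppressWarnings(as.numeric(names(table))))
  m <- as.matrix(table[, wlCols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' @rdname readSpectraTable
#' @export
tableWavelengths <- function(table) {
  w <- suppressWarnings(as.numeric(names(table)))
  w[!is.na(w)]
}
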