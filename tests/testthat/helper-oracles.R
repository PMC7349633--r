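# Independent brute-force oracles and small fixtures shared by the tests.
# The oracles deliberately share no code with the implementation paths
# they check.

# two-band profile for tiny segmentation/mapping fixtures
miniProfile <- function() {
  SensorProfile(c(681, 888), c(3.35, 7.39), 1L,
                bandLayout = matrix(1L, 1L, 1L))
}

miniCube <- function(nir, red, valueKind = "reflectance") {
  SpectralCube(array(c(red, nir), dim = c(dim(red), 2L)),
               c(681, 888), valueKind)
}

# exhaustive between-class-variance scan over every candidate threshold
bruteOtsu <- function(v, levels = 256L) {
  v <- as.integer(v)
  n <- length(v)
  best <- -Inf; bestT <- NA_integer_
  for (t in 0:(levels - 2L)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / n; w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; bestT <- t }
  }
  bestT
}

# BFS flood fill labeling from every foreground pixel
floodLabel <- function(m, connectivity = 8L) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (m[i, j] == 1L && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        px <- queue[[1L]]; queue <- queue[-1L]
        for (k in seq_len(nrow(nb))) {
          ii <- px[1L] + nb[k, 1L]; jj <- px[2L] + nb[k, 2L]
          if (ii >= 1L && ii <= h && jj >= 1L && jj <= w &&
              m[ii, jj] == 1L && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# largest-component mask by flood fill (ties: first label in scan order,
# which matches raster-first-pixel tie-breaking for column scans only if
# unique; test masks avoid area ties unless testing ties explicitly)
bruteLargest <- function(m, connectivity = 8L) {
  lab <- floodLabel(m, connectivity)
  if (max(lab) == 0L) stop("empty mask")
  sizes <- tabulate(lab[lab > 0L])
  matrix(as.integer(lab == which.max(sizes)), nrow(m), ncol(m))
}

# per-pixel median by explicit window counting with edge replication
bruteMedianFilter <- function(m, window = 3L) {
  k <- (window - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- integer(0)
    for (di in -k:k) for (dj in -k:k) {
      ii <- min(max(i + di, 1L), h); jj <- min(max(j + dj, 1L), w)
      vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- as.integer(median(vals))
  }
  out
}
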