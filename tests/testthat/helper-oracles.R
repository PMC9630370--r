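# Independent straight-line oracles used to cross-check the package's
# implementations. These share no code with the package paths they verify.

# --- Dice-family losses, written as bare arithmetic ------------------------

oDice3d <- function(p, t, eps = 1e-5) {
  num <- 0; dp <- 0; dt <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * t[i]
    dp <- dp + p[i]
    dt <- dt + t[i]
  }
  1 - (2 * num + eps) / (dp + dt + eps)
}

oDiceCoef <- function(p, t, eps = 1e-5) 1 - oDice3d(p, t, eps)

oAdaptive <- function(p, t, l1 = 0.7, l2 = 0.3, eps = 1e-5, axis = 3) {
  total <- l1 * oDice3d(p, t, eps)
  n <- dim(p)[axis]
  for (i in seq_len(n)) {
    ps <- switch(axis, p[i, , ], p[, i, ], p[, , i])
    ts <- switch(axis, t[i, , ], t[, i, ], t[, , i])
    d <- oDiceCoef(ps, ts, eps)
    total <- total + l2 * (1 - d^2) * (1 - d)
  }
  total
}

# --- geometry oracles -------------------------------------------------------

# exhaustive min/max scan for a label's tight bounding box (0-based, half-open)
oBBox <- function(arr, label) {
  lo <- c(Inf, Inf, Inf); hi <- c(-Inf, -Inf, -Inf)
  d <- dim(arr)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (arr[i, j, k] == label) {
      lo <- pmin(lo, c(i, j, k) - 1)
      hi <- pmax(hi, c(i, j, k))
    }
  }
  list(lo = lo, hi = hi)
}

# brute-force nearest-neighbour resampling by explicit index mapping
oResampleNearest <- function(arr, inSpacing, outSpacing) {
  inShape <- dim(arr)
  outShape <- pmax(1L, as.integer(round(inShape * inSpacing / outSpacing)))
  out <- array(NA_real_, outShape)
  for (k in seq_len(outShape[3])) for (j in seq_len(outShape[2]))
    for (i in seq_len(outShape[1])) {
      src <- round((c(i, j, k) - 1) * outSpacing / inSpacing) + 1
      src <- pmin(pmax(src, 1), inShape)
      out[i, j, k] <- arr[src[1], src[2], src[3]]
    }
  out
}

# flood-fill 26-connected components with an explicit queue
oComponents <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextLab <- 0L
  idx <- which(mask != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    nextLab <- nextLab + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- nextLab
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        n <- cur + c(dx, dy, dz)
        if (any(n < 1) || any(n > d)) next
        if (mask[n[1], n[2], n[3]] != 0 && lab[n[1], n[2], n[3]] == 0L) {
          lab[n[1], n[2], n[3]] <- nextLab
          queue[[length(queue) + 1L]] <- n
        }
      }
    }
  }
  lab
}

# erosion oracle: a voxel survives iff its whole 3x3x3 neighbourhood is
# foreground (outside the grid counts as background)
oErode <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    ok <- i > 1 && j > 1 && k > 1 && i < d[1] && j < d[2] && k < d[3]
    if (ok) {
      ok <- all(mask[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)])
    }
    out[i, j, k] <- ok
  }
  out
}

oDilate <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k]) next
    ii <- max(1, i - 1):min(d[1], i + 1)
    jj <- max(1, j - 1):min(d[2], j + 1)
    kk <- max(1, k - 1):min(d[3], k + 1)
    out[ii, jj, kk] <- TRUE
  }
  out
}

# --- small fixtures ---------------------------------------------------------

# random blobby binary mask: union of a few random boxes
randomBlobMask <- function(shape, nBlobs = 3) {
  m <- array(0L, shape)
  for (b in seq_len(nBlobs)) {
    lo <- sapply(shape, function(n) sample.int(n, 1))
    sz <- sapply(shape, function(n) sample.int(max(2, n %/% 3), 1))
    hi <- pmin(lo + sz, shape)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  }
  m
}

smallPhantomSpec <- function(shape = 32, spacing = 2, noiseSd = 10, seed = 1L) {
  PhantomSpec(shape = shape, spacing = spacing, noiseSd = noiseSd, seed = seed)
}
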