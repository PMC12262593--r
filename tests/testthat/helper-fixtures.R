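# Geometric fixtures and independent brute-force oracles used across tests.
# Oracles are deliberately naive (direct formulas, exhaustive loops) and never
# share code with the implementation under test.

diskMask <- function(r, n = 2 * r + 9) {
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(y, x) (y - ctr)^2 + (x - ctr)^2 <= r^2)
}

ballVoxels <- function(r, margin = 3) {
  n <- 2 * ceiling(r) + 2 * margin
  g <- expand.grid(z = 0:(n - 1), y = 0:(n - 1), x = 0:(n - 1))
  c0 <- (n - 1) / 2
  keep <- (g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r^2
  as.matrix(g[keep, ])
}

spheroidVoxels <- function(a, b) {   # semi-axis a along z, b along y and x
  nz <- 2 * a + 5; nxy <- 2 * b + 5
  g <- expand.grid(z = 0:(nz - 1), y = 0:(nxy - 1), x = 0:(nxy - 1))
  keep <- ((g$z - (nz - 1) / 2) / a)^2 + ((g$y - (nxy - 1) / 2) / b)^2 +
    ((g$x - (nxy - 1) / 2) / b)^2 <= 1
  as.matrix(g[keep, ])
}

capsuleVoxels <- function(r, halfLen) {   # axis along z
  nz <- 2 * ceiling(halfLen + r) + 5; nxy <- 2 * ceiling(r) + 5
  g <- expand.grid(z = 0:(nz - 1), y = 0:(nxy - 1), x = 0:(nxy - 1))
  dz <- pmax(abs(g$z - (nz - 1) / 2) - halfLen, 0)
  keep <- dz^2 + (g$y - (nxy - 1) / 2)^2 + (g$x - (nxy - 1) / 2)^2 <= r^2
  as.matrix(g[keep, ])
}

voxelsToArray <- function(vox, pad = 1L) {
  lo <- apply(vox, 2, min); hi <- apply(vox, 2, max)
  arr <- array(FALSE, dim = hi - lo + 1L + 2L * pad)
  arr[cbind(vox[, 1] - lo[1], vox[, 2] - lo[2], vox[, 3] - lo[3]) + pad + 1L] <- TRUE
  arr
}

translateMatrix <- function(m, dx, dy) {   # zero fill
  out <- matrix(0, nrow(m), ncol(m))
  ys <- seq_len(nrow(m)); xs <- seq_len(ncol(m))
  keepY <- ys + dy >= 1 & ys + dy <= nrow(m)
  keepX <- xs + dx >= 1 & xs + dx <= ncol(m)
  out[ys[keepY] + dy, xs[keepX] + dx] <- m[ys[keepY], xs[keepX]]
  out
}

# --- oracles -------------------------------------------------------------

pearsonOracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  num / den
}

giniOracle <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 1:n) for (j in 1:n) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

welchTOracle <- function(a, b) {
  (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
}

mannWhitneyUOracle <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

dilateOracle2d <- function(mask) {   # one 8-neighbourhood dilation
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    ys <- max(1, y - 1):min(ny, y + 1); xs <- max(1, x - 1):min(nx, x + 1)
    out[y, x] <- any(mask[ys, xs])
  }
  out
}

innerEdgeOracle <- function(mask) {   # true pixels with a false 8-neighbour
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- mask
  out <- matrix(FALSE, ny, nx)
  for (y in 1:ny) for (x in 1:nx)
    if (mask[y, x]) out[y, x] <- !all(pad[y:(y + 2), x:(x + 2)])
  out
}

boundaryDistOracle <- function(ctrUm, boundaryVox, spacing) {
  best <- Inf
  for (i in seq_len(nrow(boundaryVox))) {
    p <- boundaryVox[i, ] * spacing
    best <- min(best, sqrt(sum((p - ctrUm)^2)))
  }
  best
}

randomBlobMask <- function(n, seed) {   # connected-ish random test shapes
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  y <- n %/% 2; x <- n %/% 2
  for (i in 1:(4 * n)) {
    m[y, x] <- TRUE
    y <- min(max(y + sample(-1:1, 1), 2), n - 1)
    x <- min(max(x + sample(-1:1, 1), 2), n - 1)
  }
  m
}

# small three-channel stack for I/O and pipeline plumbing tests
tinyStack <- function(seed = 1, nz = 3, ny = 12, nx = 10) {
  set.seed(seed)
  mk <- function() array(sample(0:4000, nz * ny * nx, TRUE),
                         dim = c(nz, ny, nx))
  MultiChannelStack(channels = list(DAPI = mk(), H3K27ac = mk(), ER = mk()),
                    spacingXY = 0.06, spacingZ = 0.15)
}
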