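# Per-domain features: ER/H3K27ac Pearson correlation, volume, mesh-based
# 3D sphericity, distance to the nuclear boundary, volume classes, and the
# per-cell Gini heterogeneity index.

#' In-domain Pearson correlation between H3K27ac and ER
#'
#' Sample Pearson correlation between the two intensity vectors over all
#' domain voxels (ER-invalid voxels excluded). A constant vector makes the
#' correlation undefined; NA is returned with attribute
#' \code{reason = "zero variance"}.
#'
#' @param domain a \linkS4class{ChromatinDomain}.
#' @return Pearson r, or NA.
#' @export
domainCorrelation <- function(domain) {
  keep <- !is.na(domain@erIntensities)
  h <- domain@h3k27acIntensities[keep]
  e <- domain@erIntensities[keep]
  if (length(h) < 2) {
    r <- NA_real_
    attr(r, "reason") <- "fewer than 2 voxels"
    return(r)
  }
  if (sd(h) == 0 || sd(e) == 0) {
    r <- NA_real_
    attr(r, "reason") <- "zero variance"
    return(r)
  }
  cor(h, e)
}

# Surface area of a voxel set by marching-tetrahedra isosurface meshing at
# level 0.5 on a 3x3x3 box-regularized copy of the binary field, in physical
# coordinates. Falls back to exposed-face counting when the regularized field
# never crosses the level (very small sets).
meshSurfaceArea <- function(voxels, spacing) {
  lo <- apply(voxels, 2, min)
  d <- apply(voxels, 2, max) - lo + 1L + 4L   # pad 2 voxels each side
  field <- array(0, dim = d)
  field[cbind(voxels[, 1] - lo[1] + 3L, voxels[, 2] - lo[2] + 3L,
              voxels[, 3] - lo[3] + 3L)] <- 1
  sm <- cpp_boxmean3(field, dim(field))
  if (max(sm) > 0.5)
    return(cpp_mesh_area(sm, dim(sm), spacing, 0.5))
  warning("regularized field never crosses the iso-level; ",
          "falling back to exposed-face surface area")
  exposedFaceArea(field, spacing)
}

# Sum of exposed voxel face areas (overestimates smooth surfaces ~1.5x; used
# only as a fallback for pathological/very small sets).
exposedFaceArea <- function(field, spacing) {
  d <- dim(field)
  area <- 0
  faces <- list(c(1, spacing[2] * spacing[3]), c(2, spacing[1] * spacing[3]),
                c(3, spacing[1] * spacing[2]))
  for (f in faces) {
    ax <- f[[1]]; a <- f[[2]]
    shifted <- array(0, dim = d)
    n <- d[ax]
    if (ax == 1) { shifted[2:n, , ] <- field[1:(n - 1), , ]
    } else if (ax == 2) { shifted[, 2:n, ] <- field[, 1:(n - 1), ]
    } else shifted[, , 2:n] <- field[, , 1:(n - 1)]
    area <- area + a * (sum(field == 1 & shifted == 0) +
                          sum(field == 0 & shifted == 1))
  }
  area
}

#' 3D sphericity of a domain
#'
#' \deqn{\phi = \pi^{1/3} (6V)^{2/3} / S} with V the domain volume (voxel
#' count times voxel volume) and S its surface area from isosurface meshing
#' of the binary voxel set. A ball scores 1; elongated or irregular shapes
#' score lower (looser chromatin).
#'
#' @param domain a \linkS4class{ChromatinDomain}, or an integer (z, y, x)
#'   voxel matrix.
#' @param spacing voxel spacing \code{c(z, y, x)} in micrometres.
#' @return sphericity, dimensionless.
#' @export
domainSphericity <- function(domain, spacing) {
  voxels <- if (is(domain, "ChromatinDomain")) domain@voxels else domain
  stopifnot(nrow(voxels) >= 1)
  v <- nrow(voxels) * prod(spacing)
  s <- meshSurfaceArea(voxels, spacing)
  pi^(1 / 3) * (6 * v)^(2 / 3) / s
}

#' Distance from a domain to the nuclear boundary
#'
#' Euclidean distance, in micrometres, from the domain's intensity-unweighted
#' voxel centroid to the nearest nuclear boundary voxel.
#'
#' @param domain a \linkS4class{ChromatinDomain}.
#' @param nucleus a \linkS4class{NucleusRegion} with a non-empty boundary.
#' @param spacing voxel spacing \code{c(z, y, x)} in micrometres.
#' @param from \code{"centroid"} (default) or \code{"nearest"} (minimum over
#'   all domain voxels).
#' @return distance in micrometres.
#' @export
boundaryDistance <- function(domain, nucleus, spacing,
                             from = c("centroid", "nearest")) {
  from <- match.arg(from)
  if (nrow(nucleus@boundary) == 0) stop("nucleus boundary is empty")
  b <- sweep(nucleus@boundary, 2, spacing, "*")
  if (from == "centroid") {
    ctr <- colMeans(domain@voxels)
    cvox <- round(ctr) + 1L
    if (!nucleus@mask[matrix(cvox, 1)])
      warning("domain centroid lies outside the nucleus mask")
    p <- matrix(ctr * spacing, nrow = 1)
  } else {
    p <- sweep(domain@voxels, 2, spacing, "*")
  }
  dmin <- Inf
  for (i in seq_len(nrow(p)))
    dmin <- min(dmin, sqrt(min(colSums((t(b) - p[i, ])^2))))
  dmin
}

#' Assign four ordered volume classes
#'
#' In quantile mode (default) the class boundaries are the pooled 25/50/75th
#' percentiles of all supplied volumes, so per-condition class proportions
#' can differ. Explicit strictly increasing boundaries are also accepted.
#'
#' @param volumes numeric vector of domain volumes.
#' @param boundaries NULL for quantile mode, or three increasing thresholds.
#' @return integer vector of classes 1 (smallest) to 4 (largest).
#' @export
assignVolumeClasses <- function(volumes, boundaries = NULL) {
  if (is.null(boundaries)) {
    if (length(volumes) < 4)
      stop("quantile mode needs at least 4 volumes")
    boundaries <- quantile(volumes, c(0.25, 0.5, 0.75), names = FALSE,
                           type = 7)
    if (any(diff(boundaries) == 0))
      warning("tied quantile boundaries; some classes will be empty")
  } else {
    if (length(boundaries) != 3 || any(diff(boundaries) <= 0))
      stop("explicit boundaries must be three strictly increasing values")
  }
  1L + (volumes > boundaries[1]) + (volumes > boundaries[2]) +
    (volumes > boundaries[3])
}

#' Gini inequality index
#'
#' \deqn{G = \sum_{i,j} |x_i - x_j| / (2 n^2 \bar{x})} over the values of one
#' feature within one cell; 0 means all domains identical, values approaching
#' 1 mean extreme heterogeneity.
#'
#' @param values non-negative numeric vector, length >= 2, not all zero.
#' @return G in [0, 1).
#' @export
giniIndex <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (any(values < 0)) stop("Gini index requires non-negative values")
  if (all(values == 0)) stop("Gini index undefined for all-zero values")
  n <- length(values)
  x <- sort(values)
  # equals sum_ij |xi - xj| / (2 n^2 mean)
  (2 * sum(seq_len(n) * x) / (n * sum(x))) - (n + 1) / n
}

#' Feature table for a set of detected domains
#'
#' One row per domain: correlation, volume (voxels and cubic micrometres),
#' sphericity, boundary distance and cell/condition/batch labels. Volume
#' classes are not assigned here (they depend on the pooled cohort; see
#' \code{\link{assignVolumeClasses}}).
#'
#' @param domains list of \linkS4class{ChromatinDomain}.
#' @param nucleus the parent \linkS4class{NucleusRegion}.
#' @param spacing voxel spacing \code{c(z, y, x)} in micrometres.
#' @param cell,condition,batch labels attached to every row.
#' @return data.frame with one row per domain.
#' @export
domainFeatureTable <- function(domains, nucleus, spacing, cell = NA,
                               condition = NA, batch = NA) {
  if (length(domains) == 0)
    return(data.frame(domain = integer(), nucleus = integer(),
                      cell = character(), condition = character(),
                      batch = integer(), corr = numeric(),
                      volumeVox = integer(), volumeUm3 = numeric(),
                      sphericity = numeric(), boundaryDistUm = numeric(),
                      corrMissingReason = character()))
  rows <- lapply(domains, function(d) {
    r <- domainCorrelation(d)
    data.frame(domain = d@label, nucleus = d@parentNucleus,
               cell = as.character(cell), condition = as.character(condition),
               batch = batch, corr = as.numeric(r),
               volumeVox = nrow(d@voxels),
               volumeUm3 = nrow(d@voxels) * prod(spacing),
               sphericity = domainSphericity(d, spacing),
               boundaryDistUm = boundaryDistance(d, nucleus, spacing),
               corrMissingReason = if (is.na(r))
                 as.character(attr(r, "reason")) else NA_character_)
  })
  do.call(rbind, rows)
}

#' Per-cell summary of a feature table
#'
#' @param features data.frame from \code{\link{domainFeatureTable}} (rows
#'   from one or more cells).
#' @return data.frame with one row per cell: domain count, per-feature means
#'   and per-feature Gini indices.
#' @export
cellSummary <- function(features) {
  split_by <- interaction(features$condition, features$batch, features$cell,
                          drop = TRUE)
  rows <- lapply(split(features, split_by), function(f) {
    gini <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2 && any(v > 0)) giniIndex(v) else NA_real_
    }
    data.frame(cell = f$cell[1], condition = f$condition[1],
               batch = f$batch[1], nDomains = nrow(f),
               meanCorr = mean(f$corr, na.rm = TRUE),
               meanVolumeVox = mean(f$volumeVox),
               meanSphericity = mean(f$sphericity),
               meanBoundaryDistUm = mean(f$boundaryDistUm),
               giniVolume = gini(f$volumeVox),
               giniSphericity = gini(f$sphericity),
               giniBoundaryDist = gini(f$boundaryDistUm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
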