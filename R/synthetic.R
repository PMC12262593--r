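# Synthetic multi-channel nuclear stacks with known ground truth.
#
# The generator emulates the acquisition geometry of 3D-SIM nuclear imaging
# (anisotropic voxel grid, default 0.06 um X/Y and 0.15 um Z), an ellipsoidal
# DAPI-bright nucleus, punctate-vs-elongated H3K27ac domains, an ER channel
# whose in-domain intensities correlate with H3K27ac at a controllable level,
# and a rigid X/Y mis-registration of the ER channel. No optics are simulated
# (no PSF, no reconstruction artifacts).

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed from a master seed and (batch, cell, condition)
# indices; stays below 2^31.
deriveSeed <- function(seed, batch = 0L, cell = 0L, condition = 0L) {
  s <- (as.double(seed) %% 2147483399) * 48271 +
    batch * 97003 + cell * 389 + condition * 7919
  as.integer(s %% 2147483399) + 1L
}

roundClip <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x
}

#' Generate a synthetic multi-channel nuclear stack
#'
#' Builds a seeded three-channel (DAPI, H3K27ac, ER) 3D stack on the raw
#' (anisotropic) voxel grid together with complete ground truth. The nucleus
#' is an axis-aligned ellipsoid; DAPI is bright inside and dim outside (both
#' with Gaussian camera noise, rounded to non-negative integer counts).
#' Chromatin domains are spheres or spherocylinders (capsules) with uniformly
#' random 3D orientation, placed wholly inside the nucleus with an optional
#' pull toward the nuclear periphery. The ER channel is a linear mix of the
#' H3K27ac channel and independent noise, solved so that the expected Pearson
#' correlation over in-domain voxels equals \code{erCorrelation}, and is then
#' rigidly shifted in X/Y by \code{channelShiftXY} (vacated pixels 0).
#'
#' @param spec a \linkS4class{ConditionSpec}.
#' @param gridShape raw grid \code{c(nz, ny, nx)}.
#' @param spacing raw voxel spacing \code{c(z, y, x)} in micrometres.
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @param nucleusSemiAxesFrac ellipsoid semi-axes as fractions of the grid
#'   half-extent per axis (z, y, x).
#' @param dapiNucleusMean,dapiNucleusSd,dapiBackgroundMean,dapiBackgroundSd
#'   DAPI intensity model (camera counts); defaults keep the nucleus far above
#'   and the background far below the conventional 500-count floor.
#' @param nucleoplasmMean,nucleoplasmSd diffuse in-nucleus H3K27ac intensity
#'   outside domains. The nucleoplasm is modelled as slightly brighter but
#'   markedly more uniform than the extracellular background, which is what
#'   makes a background-percentile threshold selective for domains.
#' @param speckFraction,speckMean,speckSd sparse bright speckle component of
#'   the extracellular H3K27ac background (debris / autofluorescence). Real
#'   fluorescence backgrounds are heavy-tailed, and this tail is what a
#'   top-percentile background threshold keys on; without it the threshold
#'   would sit inside the Gaussian noise and a data-driven cutoff could not
#'   separate domains from diffuse signal on any data. Specks are kept at
#'   least \code{speckClearanceUm} away from the nuclear surface (debris is
#'   extracellular, not perinuclear).
#' @param speckClearanceUm minimum distance of specks from the nucleus
#'   surface, micrometres; the default clears the diagonal (Chebyshev) reach
#'   of a 10-iteration square-element dilation (10 * sqrt(2) * 0.06 um).
#' @return list with elements \code{stack} (\linkS4class{MultiChannelStack})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @export
generateStack <- function(spec, gridShape = c(10L, 256L, 256L),
                          spacing = c(0.15, 0.06, 0.06), seed = 1L,
                          nucleusSemiAxesFrac = c(0.78, 0.82, 0.82),
                          dapiNucleusMean = 900, dapiNucleusSd = 50,
                          dapiBackgroundMean = 100, dapiBackgroundSd = 40,
                          nucleoplasmMean = 140, nucleoplasmSd = 12,
                          speckFraction = 0.003, speckMean = 450,
                          speckSd = 40, speckClearanceUm = 1) {
  stopifnot(is(spec, "ConditionSpec"))
  validObject(spec)
  gridShape <- as.integer(gridShape)
  nz <- gridShape[1]; ny <- gridShape[2]; nx <- gridShape[3]
  sz <- spacing[1]; sy <- spacing[2]; sx <- spacing[3]

  # ellipsoid in physical coordinates, centred on the grid
  centerUm <- c((nz - 1) / 2 * sz, (ny - 1) / 2 * sy, (nx - 1) / 2 * sx)
  halfExtentUm <- c((nz - 1) / 2 * sz, (ny - 1) / 2 * sy, (nx - 1) / 2 * sx)
  axesUm <- nucleusSemiAxesFrac * halfExtentUm
  for (d in 1:3) {
    if (axesUm[d] >= halfExtentUm[d] + 1e-9 || axesUm[d] <= 0)
      stop("nucleus ellipsoid does not fit the grid along dimension ",
           c("z", "y", "x")[d])
  }

  radiusUm <- spec@domainRadiusVox * sy
  halfLenUm <- radiusUm * (spec@elongationRatio - 1)
  if (abs(spec@erCorrelation) < 1 && abs(spec@erCorrelation) > 0 &&
      spec@intensitySd == 0)
    stop("unreachable erCorrelation: a partial correlation requires ",
         "intensitySd > 0 inside domains")

  withSeed(seed, {
    # voxel-centre physical coordinates along each axis
    zc <- (0:(nz - 1)) * sz; yc <- (0:(ny - 1)) * sy; xc <- (0:(nx - 1)) * sx
    qz <- (zc - centerUm[1]) / axesUm[1]
    qy <- (yc - centerUm[2]) / axesUm[2]
    qx <- (xc - centerUm[3]) / axesUm[3]
    # inside-ellipsoid mask, dim (nz, ny, nx)
    q2 <- outer(outer(qz^2, qy^2, "+"), qx^2, "+")
    inside <- q2 <= 1
    nvox <- nz * ny * nx

    dapi <- array(roundClip(rnorm(nvox, dapiBackgroundMean,
                                  dapiBackgroundSd)), dim = gridShape)
    dapi[inside] <- roundClip(rnorm(sum(inside), dapiNucleusMean,
                                    dapiNucleusSd))

    h3 <- array(roundClip(rnorm(nvox, spec@backgroundMean,
                                spec@backgroundSd)), dim = gridShape)
    h3[inside] <- roundClip(rnorm(sum(inside), nucleoplasmMean,
                                  nucleoplasmSd))
    if (speckFraction > 0) {
      qClear <- 1 + speckClearanceUm / min(axesUm[2:3])
      outsideIdx <- which(q2 > qClear^2)
      nSpeck <- round(speckFraction * length(outsideIdx))
      if (nSpeck > 0) {
        at <- sample(outsideIdx, nSpeck)
        h3[at] <- roundClip(rnorm(nSpeck, speckMean, speckSd))
      }
    }

    # Poisson count with its far upper tail truncated: extreme draws cannot
    # be packed under the minimum-separation constraint
    nDomains <- max(1L, min(rpois(1, spec@nDomainsMean),
                            ceiling(1.3 * spec@nDomainsMean)))
    voxList <- vector("list", nDomains)
    dominfo <- vector("list", nDomains)
    placedSegs <- list()
    minSepUm <- 0.35   # keeps distinct domains from touching after dilation
    insideEllipsoid <- function(vox) {
      q <- cbind((vox[, 1] * sz - centerUm[1]) / axesUm[1],
                 (vox[, 2] * sy - centerUm[2]) / axesUm[2],
                 (vox[, 3] * sx - centerUm[3]) / axesUm[3])
      all(rowSums(q^2) <= 1)
    }
    segPoints <- function(ctr, u, h) {
      if (h <= 0) return(matrix(ctr, 1))
      t <- seq(-h, h, length.out = 25)
      sweep(outer(t, u), 2, ctr, "+")
    }
    for (i in seq_len(nDomains)) {
      placed <- FALSE
      for (try in 1:2500) {
        # uniform direction + biased radial coordinate in ellipsoid coords
        v <- rnorm(3); v <- v / sqrt(sum(v^2))
        rho <- runif(1)^(1 / 3)                     # uniform in the ball
        if (spec@boundaryBias > 0)
          rho <- rho^(1 / (1 + 3 * spec@boundaryBias))  # pull to periphery
        ctr <- centerUm + v * rho * axesUm
        if (spec@domainShape == "spherocylinder") {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
        } else u <- c(0, 0, 1)
        ends <- rbind(ctr - halfLenUm * u, ctr + halfLenUm * u)
        qe <- sweep(ends, 2, centerUm) / rep(axesUm, each = 2)
        if (any(rowSums(qe^2) > 1)) next        # cheap reject
        pts <- segPoints(ctr, u, halfLenUm)
        # keep distinct domains separated so dilation cannot bridge them
        tooClose <- FALSE
        for (ps in placedSegs) {
          dmin <- sqrt(min(outer(rowSums(pts^2), rowSums(ps^2), "+") -
                             2 * tcrossprod(pts, ps)))
          if (dmin < 2 * radiusUm + minSepUm) { tooClose <- TRUE; break }
        }
        if (tooClose) next
        vox <- rasterizeCapsule(ctr, u, halfLenUm, radiusUm, gridShape,
                                spacing)
        if (nrow(vox) > 0 && insideEllipsoid(vox)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        if (i == 1)
          stop("could not place domain 1 inside the nucleus; the domain is ",
               "too large for the nucleus ellipsoid")
        # sequential packing saturated: keep the domains already placed
        warning("nucleus saturated after ", i - 1, " of ", nDomains,
                " domains; truth records the placed domains")
        voxList <- voxList[seq_len(i - 1)]
        dominfo <- dominfo[seq_len(i - 1)]
        break
      }
      placedSegs[[length(placedSegs) + 1L]] <- segPoints(ctr, u, halfLenUm)
      voxList[[i]] <- vox
      dominfo[[i]] <- data.frame(
        label = i, shapeClass = spec@domainShape,
        centroidZ = mean(vox[, 1]), centroidY = mean(vox[, 2]),
        centroidX = mean(vox[, 3]),
        centerZUm = ctr[1], centerYUm = ctr[2], centerXUm = ctr[3],
        radiusUm = radiusUm, halfLengthUm = halfLenUm,
        axisZ = u[1], axisY = u[2], axisX = u[3], nVoxels = nrow(vox))
      idx <- vox[, 1] + 1L + nz * (vox[, 2] + as.integer(ny) * vox[, 3])
      h3[idx] <- roundClip(rnorm(nrow(vox), spec@intensityMean,
                                 spec@intensitySd))
    }

    # ER = a * H3K27ac + b * noise, solved for the in-domain correlation
    rho <- spec@erCorrelation
    a <- if (rho > 0) 1 else if (rho < 0) -1 else 0
    b <- if (abs(rho) == 1) 0
         else if (rho == 0) max(spec@intensitySd, 1)
         else spec@intensitySd * sqrt(1 / rho^2 - 1)
    if (a != 0 && b == 0) {
      er <- if (a > 0) h3 else 2 * spec@intensityMean - h3
      er[er < 0] <- 0
    } else {
      er <- roundClip(a * (h3 - spec@intensityMean) + b * rnorm(nvox) +
                        spec@intensityMean)
    }
    er <- shiftSlices(array(er, dim = gridShape), spec@channelShiftXY[1],
                      spec@channelShiftXY[2])$channel

    stack <- MultiChannelStack(
      channels = list(DAPI = dapi, H3K27ac = h3, ER = er),
      spacingXY = sy, spacingZ = sz,
      metadata = list(generator = list(condition = spec@name, seed = seed)))
    truth <- new("GroundTruth",
      domains = do.call(rbind, dominfo), voxels = voxList,
      channelShift = spec@channelShiftXY, nucleusCenterUm = centerUm,
      nucleusSemiAxesUm = axesUm, spacing = spacing, gridShape = gridShape)
    list(stack = stack, truth = truth)
  })
}

# Voxels (0-based z, y, x) within `radiusUm` of the segment
# [ctr - h*u, ctr + h*u] in physical coordinates.
rasterizeCapsule <- function(ctr, u, halfLenUm, radiusUm, gridShape, spacing) {
  nz <- gridShape[1]; ny <- gridShape[2]; nx <- gridShape[3]
  ext <- abs(u) * halfLenUm + radiusUm
  lo <- pmax(floor((ctr - ext) / spacing), 0)
  hi <- pmin(ceiling((ctr + ext) / spacing), gridShape - 1)
  zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
  g <- expand.grid(z = zz, y = yy, x = xx)
  p <- cbind(g$z * spacing[1], g$y * spacing[2], g$x * spacing[3])
  d <- sweep(p, 2, ctr)
  if (halfLenUm > 0) {
    t <- pmin(pmax(d %*% u, -halfLenUm), halfLenUm)
    d <- d - tcrossprod(as.numeric(t), u)
  }
  keep <- rowSums(d^2) <= radiusUm^2
  as.matrix(g[keep, c("z", "y", "x"), drop = FALSE])
}

# Rigid integer in-plane translation of every slide; vacated pixels are 0 and
# flagged FALSE in the validity mask.
shiftSlices <- function(channel, dx, dy) {
  d <- dim(channel)
  out <- array(0, dim = d)
  valid <- array(FALSE, dim = d)
  ny <- d[2]; nx <- d[3]
  ys <- seq_len(ny); xs <- seq_len(nx)
  ysDst <- ys + dy; xsDst <- xs + dx
  keepY <- ysDst >= 1 & ysDst <= ny
  keepX <- xsDst >= 1 & xsDst <= nx
  if (any(keepY) && any(keepX)) {
    out[, ysDst[keepY], xsDst[keepX]] <- channel[, ys[keepY], xs[keepX]]
    valid[, ysDst[keepY], xsDst[keepX]] <- TRUE
  }
  list(channel = out, valid = valid)
}

#' Generate a labelled cohort of synthetic stacks
#'
#' Produces \code{length(specs) * nCellsPerCondition * nBatches} stacks with
#' complete condition/batch/cell labels. Per-stack seeds are derived
#' deterministically from the master seed and the (batch, cell, condition)
#' indices, so any single cell can be regenerated without the rest of the
#' cohort. Each batch carries a reproducible additive offset on the in-domain
#' H3K27ac intensity mean (a simple batch effect), drawn from
#' \code{N(0, batchIntensitySd)}.
#'
#' @param specs list of \linkS4class{ConditionSpec} with distinct names.
#' @param nCellsPerCondition cells per condition per batch.
#' @param nBatches number of batches.
#' @param seed master seed.
#' @param batchIntensitySd standard deviation of the per-batch intensity
#'   offset (camera counts); 0 disables the batch effect.
#' @param ... passed to \code{\link{generateStack}}.
#' @return list with \code{index} (data.frame: condition, batch, cell, seed)
#'   and \code{stacks} (list of \code{generateStack} results, same order).
#' @export
generateCohort <- function(specs, nCellsPerCondition, nBatches = 1L,
                           seed = 1L, batchIntensitySd = 40, ...) {
  nms <- vapply(specs, function(s) s@name, "")
  if (anyDuplicated(nms)) stop("duplicate condition names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  stopifnot(nCellsPerCondition >= 1, nBatches >= 1)
  batchOffsets <- withSeed(deriveSeed(seed, batch = 999999L),
                           rnorm(nBatches, 0, batchIntensitySd))
  index <- expand.grid(cell = seq_len(nCellsPerCondition),
                       condition = nms, batch = seq_len(nBatches),
                       stringsAsFactors = FALSE)
  index$seed <- mapply(function(b, cl, cd) deriveSeed(seed, b, cl, cd),
                       index$batch, index$cell, match(index$condition, nms))
  stacks <- vector("list", nrow(index))
  for (i in seq_len(nrow(index))) {
    sp <- specs[[match(index$condition[i], nms)]]
    sp@intensityMean <- sp@intensityMean + batchOffsets[index$batch[i]]
    stacks[[i]] <- generateStack(sp, seed = index$seed[i], ...)
  }
  list(index = index[, c("condition", "batch", "cell", "seed")],
       stacks = stacks)
}

#' Built-in study conditions
#'
#' Two reference conditions mirroring the estrogen-stimulated versus
#' estrogen-deprived contrast: \code{"E2-like"} domains are elongated
#' spherocylinders (elongation 4), brighter, better correlated with the ER
#' channel and centrally placed; \code{"ED-like"} domains are compact spheres,
#' dimmer, less correlated and pulled toward the nuclear periphery. Both share
#' the background model and the rigid ER channel shift.
#'
#' @param channelShiftXY integer \code{c(dx, dy)} ER mis-registration.
#' @return named list of two \linkS4class{ConditionSpec} objects.
#' @export
defaultConditionSpecs <- function(channelShiftXY = c(3L, -2L)) {
  list(
    "ED-like" = conditionSpec("ED-like", nDomainsMean = 30,
      domainShape = "sphere", elongationRatio = 1, domainRadiusVox = 3,
      intensityMean = 650, intensitySd = 80, erCorrelation = 0.55,
      boundaryBias = 0.6, backgroundMean = 120, backgroundSd = 25,
      channelShiftXY = channelShiftXY),
    "E2-like" = conditionSpec("E2-like", nDomainsMean = 30,
      domainShape = "spherocylinder", elongationRatio = 4,
      domainRadiusVox = 3, intensityMean = 700, intensitySd = 80,
      erCorrelation = 0.75, boundaryBias = 0.1, backgroundMean = 120,
      backgroundSd = 25, channelShiftXY = channelShiftXY))
}

#' True nucleus mask on an arbitrary grid
#'
#' Rasterizes the ground-truth nucleus ellipsoid, e.g. on the enhanced grid
#' for comparison with segmentation output.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param gridShape target grid \code{c(nz, ny, nx)}.
#' @param spacing target voxel spacing \code{c(z, y, x)} in micrometres.
#' @return 3D logical array.
#' @export
truthNucleusMask <- function(truth, gridShape = truth@gridShape,
                             spacing = truth@spacing) {
  nz <- gridShape[1]; ny <- gridShape[2]; nx <- gridShape[3]
  qz <- ((0:(nz - 1)) * spacing[1] - truth@nucleusCenterUm[1]) /
    truth@nucleusSemiAxesUm[1]
  qy <- ((0:(ny - 1)) * spacing[2] - truth@nucleusCenterUm[2]) /
    truth@nucleusSemiAxesUm[2]
  qx <- ((0:(nx - 1)) * spacing[3] - truth@nucleusCenterUm[3]) /
    truth@nucleusSemiAxesUm[3]
  outer(outer(qz^2, qy^2, "+"), qx^2, "+") <= 1
}

#' True domain voxel sets on an arbitrary grid
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param gridShape,spacing target grid and spacing (defaults: raw grid).
#' @return list of integer (z, y, x) matrices, one per true domain.
#' @export
truthDomainVoxels <- function(truth, gridShape = truth@gridShape,
                              spacing = truth@spacing) {
  lapply(seq_len(nrow(truth@domains)), function(i) {
    d <- truth@domains[i, ]
    ctr <- c(d$centerZUm, d$centerYUm, d$centerXUm)
    rasterizeCapsule(ctr, c(d$axisZ, d$axisY, d$axisX), d$halfLengthUm,
                     d$radiusUm, gridShape, spacing)
  })
}
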