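#' @useDynLib SIMDomains, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats cor median quantile rnorm runif rpois sd t.test
#'   wilcox.test kruskal.test shapiro.test var
#' @importFrom utils head write.csv read.csv
NULL

# Internal coordinate convention: 3D arrays are dim = c(nz, ny, nx), 0-based
# (z, y, x) voxel coordinates in all exported tables.

#' Multi-channel 3D image stack
#'
#' Container for a multi-channel 3D fluorescence stack on a common voxel grid.
#' Channels are named 3D arrays with dimensions \code{c(nz, ny, nx)} (slide,
#' row, column). Voxel spacing is anisotropic: \code{spacingXY} applies to rows
#' and columns, \code{spacingZ} to the slide axis. \code{slideFlags} records,
#' per slide, whether it was acquired (\code{"real"}) or inserted by
#' \code{\link{interpolateZ}} (\code{"interpolated"}).
#'
#' @slot channels named list of 3D numeric arrays, identical dimensions.
#' @slot spacingXY in-plane voxel spacing, micrometres.
#' @slot spacingZ slide spacing, micrometres.
#' @slot slideFlags character vector, one of \code{"real"},
#'   \code{"interpolated"} per slide.
#' @slot metadata free-form list (provenance, validity masks after alignment).
#' @export
setClass("MultiChannelStack",
  representation(channels = "list", spacingXY = "numeric",
                 spacingZ = "numeric", slideFlags = "character",
                 metadata = "list"),
  prototype(metadata = list()))

setValidity("MultiChannelStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0) return("stack must contain at least one channel")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("all channels must be named")
  dims <- lapply(ch, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("channels must be 3D arrays (slide, row, col)")
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    return("all channels must share identical grid shape")
  if (length(object@slideFlags) != dims[[1]][1])
    return("slideFlags must have one entry per slide")
  if (!all(object@slideFlags %in% c("real", "interpolated")))
    return("slideFlags must be 'real' or 'interpolated'")
  if (length(object@spacingXY) != 1 || object@spacingXY <= 0 ||
      length(object@spacingZ) != 1 || object@spacingZ <= 0)
    return("spacings must be single positive numbers")
  TRUE
})

#' Construct a MultiChannelStack
#'
#' @param channels named list of 3D arrays, dim \code{c(nz, ny, nx)}.
#' @param spacingXY,spacingZ voxel spacing in micrometres.
#' @param slideFlags per-slide acquisition flags; default all \code{"real"}.
#' @param metadata optional list.
#' @return A \linkS4class{MultiChannelStack}.
#' @export
MultiChannelStack <- function(channels, spacingXY, spacingZ,
                              slideFlags = NULL, metadata = list()) {
  if (is.null(slideFlags))
    slideFlags <- rep("real", dim(channels[[1]])[1])
  new("MultiChannelStack", channels = channels, spacingXY = spacingXY,
      spacingZ = spacingZ, slideFlags = slideFlags, metadata = metadata)
}

#' Synthetic imaging condition specification
#'
#' Parameterizes one experimental condition for the synthetic stack generator:
#' how many chromatin domains to place, their shape (sphere or spherocylinder,
#' the elongated primitive), size and brightness, the target Pearson
#' correlation between the ER and H3K27ac channels inside domains, the pull of
#' domain placement toward the nuclear periphery, the background noise model,
#' and the rigid X/Y mis-registration applied to the ER channel.
#'
#' @slot name condition label.
#' @slot nDomainsMean expected number of domains per nucleus (Poisson mean).
#' @slot domainShape \code{"sphere"} or \code{"spherocylinder"}.
#' @slot elongationRatio total length / diameter; 1 for spheres.
#' @slot domainRadiusVox domain radius in X/Y voxels.
#' @slot intensityMean,intensitySd in-domain H3K27ac intensity (camera counts).
#' @slot erCorrelation target in-domain Pearson correlation, in [-1, 1].
#' @slot boundaryBias fraction in [0, 1]; 0 = uniform placement, 1 = strong
#'   pull toward the nuclear surface.
#' @slot backgroundMean,backgroundSd H3K27ac background intensity.
#' @slot channelShiftXY integer \code{c(dx, dy)} applied to the ER channel.
#' @export
setClass("ConditionSpec",
  representation(name = "character", nDomainsMean = "numeric",
                 domainShape = "character", elongationRatio = "numeric",
                 domainRadiusVox = "numeric", intensityMean = "numeric",
                 intensitySd = "numeric", erCorrelation = "numeric",
                 boundaryBias = "numeric", backgroundMean = "numeric",
                 backgroundSd = "numeric", channelShiftXY = "integer"))

setValidity("ConditionSpec", function(object) {
  if (!object@domainShape %in% c("sphere", "spherocylinder"))
    return("domainShape must be 'sphere' or 'spherocylinder'")
  if (object@elongationRatio < 1)
    return("elongationRatio must be >= 1")
  if ((object@domainShape == "sphere") != (object@elongationRatio == 1))
    return("elongationRatio must equal 1 iff domainShape is 'sphere'")
  if (abs(object@erCorrelation) > 1)
    return("|erCorrelation| must be <= 1")
  if (object@intensitySd < 0 || object@backgroundSd < 0)
    return("intensity and background standard deviations must be >= 0")
  if (object@boundaryBias < 0 || object@boundaryBias > 1)
    return("boundaryBias must lie in [0, 1]")
  if (length(object@channelShiftXY) != 2)
    return("channelShiftXY must be an integer pair (dx, dy)")
  if (object@nDomainsMean <= 0) return("nDomainsMean must be positive")
  if (object@domainRadiusVox <= 0) return("domainRadiusVox must be positive")
  TRUE
})

#' @rdname ConditionSpec-class
#' @param name,nDomainsMean,domainShape,elongationRatio,domainRadiusVox
#'   see slots.
#' @param intensityMean,intensitySd,erCorrelation,boundaryBias see slots.
#' @param backgroundMean,backgroundSd,channelShiftXY see slots.
#' @return A \linkS4class{ConditionSpec}.
#' @export
conditionSpec <- function(name, nDomainsMean = 30,
                          domainShape = c("sphere", "spherocylinder"),
                          elongationRatio = 1, domainRadiusVox = 3,
                          intensityMean = 650, intensitySd = 80,
                          erCorrelation = 0.6, boundaryBias = 0.3,
                          backgroundMean = 120, backgroundSd = 25,
                          channelShiftXY = c(0L, 0L)) {
  new("ConditionSpec", name = name, nDomainsMean = nDomainsMean,
      domainShape = match.arg(domainShape),
      elongationRatio = elongationRatio, domainRadiusVox = domainRadiusVox,
      intensityMean = intensityMean, intensitySd = intensitySd,
      erCorrelation = erCorrelation, boundaryBias = boundaryBias,
      backgroundMean = backgroundMean, backgroundSd = backgroundSd,
      channelShiftXY = as.integer(channelShiftXY))
}

#' Ground truth for a synthetic stack
#'
#' @slot domains data.frame, one row per placed domain: label, shape class,
#'   centroid (0-based voxels, raw grid), physical radius and half-length
#'   (micrometres), orientation axis.
#' @slot voxels list of integer matrices, the true (z, y, x) voxel set of each
#'   domain on the raw grid (0-based).
#' @slot channelShift integer \code{c(dx, dy)} applied to the ER channel.
#' @slot nucleusCenterUm,nucleusSemiAxesUm ellipsoid parameters (z, y, x),
#'   micrometres.
#' @slot spacing raw grid spacing \code{c(z, y, x)}, micrometres.
#' @slot gridShape raw grid dimensions \code{c(nz, ny, nx)}.
#' @export
setClass("GroundTruth",
  representation(domains = "data.frame", voxels = "list",
                 channelShift = "integer", nucleusCenterUm = "numeric",
                 nucleusSemiAxesUm = "numeric", spacing = "numeric",
                 gridShape = "integer"))

#' Segmented 3D nucleus region
#'
#' @slot label integer nucleus label.
#' @slot mask 3D logical array, accepted per-slide regions stacked in z.
#' @slot boundary integer matrix of 0-based (z, y, x) boundary voxel
#'   coordinates (per-slide Sobel edge map positions).
#' @slot perSlideAreas integer vector, accepted-region pixel count per slide.
#' @export
setClass("NucleusRegion",
  representation(label = "integer", mask = "array", boundary = "matrix",
                 perSlideAreas = "integer"))

setValidity("NucleusRegion", function(object) {
  if (length(dim(object@mask)) != 3) return("mask must be a 3D array")
  if (ncol(object@boundary) != 3)
    return("boundary must be an n x 3 (z, y, x) matrix")
  if (length(object@perSlideAreas) != dim(object@mask)[1])
    return("perSlideAreas must have one entry per slide")
  TRUE
})

#' Detected 3D chromatin domain
#'
#' One refined 3D connected component of above-threshold H3K27ac signal.
#'
#' @slot label integer domain label within its stack.
#' @slot voxels integer matrix of 0-based (z, y, x) coordinates.
#' @slot h3k27acIntensities,erIntensities per-voxel intensities; ER values are
#'   NA where the aligned ER channel has no data (vacated pixels).
#' @slot parentNucleus label of the containing nucleus.
#' @export
setClass("ChromatinDomain",
  representation(label = "integer", voxels = "matrix",
                 h3k27acIntensities = "numeric", erIntensities = "numeric",
                 parentNucleus = "integer"))

setValidity("ChromatinDomain", function(object) {
  if (ncol(object@voxels) != 3) return("voxels must be an n x 3 matrix")
  n <- nrow(object@voxels)
  if (length(object@h3k27acIntensities) != n ||
      length(object@erIntensities) != n)
    return("intensity vectors must match the voxel count")
  TRUE
})

#' Estimated channel shift
#'
#' @slot dx,dy integer pixel correction to apply to the moving channel.
#' @slot peakCorr Pearson correlation at the optimum.
#' @slot slideIndex 1-based slide the estimate came from; NA for a per-stack
#'   (median) estimate.
#' @export
setClass("ShiftEstimate",
  representation(dx = "integer", dy = "integer", peakCorr = "numeric",
                 slideIndex = "integer"))

setValidity("ShiftEstimate", function(object) {
  if (abs(object@peakCorr) > 1 + 1e-12)
    return("peakCorr must lie in [-1, 1]")
  TRUE
})
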