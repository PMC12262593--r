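#' @name stack-accessors
#' @title Accessors for MultiChannelStack objects
#' @param x a \linkS4class{MultiChannelStack}.
#' @param channel channel name.
#' @return \code{channelNames}: character vector; \code{getChannel}: a 3D
#'   array; \code{spacingXY}, \code{spacingZ}: numeric scalars (micrometres);
#'   \code{slideFlags}: character vector; \code{nSlides}: integer.
NULL

#' @rdname stack-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname stack-accessors
#' @export
setMethod("channelNames", "MultiChannelStack", function(x) names(x@channels))

#' @rdname stack-accessors
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))
#' @rdname stack-accessors
#' @export
setMethod("getChannel", "MultiChannelStack", function(x, channel) {
  if (!channel %in% names(x@channels))
    stop("unknown channel '", channel, "'; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[channel]]
})

#' @rdname stack-accessors
#' @export
setGeneric("spacingXY", function(x) standardGeneric("spacingXY"))
#' @rdname stack-accessors
#' @export
setMethod("spacingXY", "MultiChannelStack", function(x) x@spacingXY)

#' @rdname stack-accessors
#' @export
setGeneric("spacingZ", function(x) standardGeneric("spacingZ"))
#' @rdname stack-accessors
#' @export
setMethod("spacingZ", "MultiChannelStack", function(x) x@spacingZ)

#' @rdname stack-accessors
#' @export
setGeneric("slideFlags", function(x) standardGeneric("slideFlags"))
#' @rdname stack-accessors
#' @export
setMethod("slideFlags", "MultiChannelStack", function(x) x@slideFlags)

#' @rdname stack-accessors
#' @export
setGeneric("nSlides", function(x) standardGeneric("nSlides"))
#' @rdname stack-accessors
#' @export
setMethod("nSlides", "MultiChannelStack", function(x) dim(x@channels[[1]])[1])

#' Voxel spacing of a stack as a (z, y, x) triple
#'
#' @param x a \linkS4class{MultiChannelStack}.
#' @return numeric length-3 vector, micrometres.
#' @export
voxelSpacing <- function(x) c(x@spacingZ, x@spacingXY, x@spacingXY)

setMethod("show", "MultiChannelStack", function(object) {
  d <- dim(object@channels[[1]])
  cat("MultiChannelStack:", d[1], "slides x", d[2], "x", d[3], "px\n")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  cat(sprintf("  spacing: %.3f um (X/Y), %.3f um (Z)\n",
              object@spacingXY, object@spacingZ))
  nr <- sum(object@slideFlags == "real")
  cat("  slides:", nr, "real,", length(object@slideFlags) - nr,
      "interpolated\n")
})

setMethod("show", "ConditionSpec", function(object) {
  cat("ConditionSpec '", object@name, "': ", object@nDomainsMean,
      " domains (", object@domainShape,
      ", elongation ", object@elongationRatio,
      ", radius ", object@domainRadiusVox, " px)\n", sep = "")
  cat(sprintf("  intensity %g +/- %g, background %g +/- %g, ER rho %.2f, ",
              object@intensityMean, object@intensitySd,
              object@backgroundMean, object@backgroundSd,
              object@erCorrelation))
  cat(sprintf("boundary bias %.2f, shift (%d, %d)\n",
              object@boundaryBias, object@channelShiftXY[1],
              object@channelShiftXY[2]))
})

setMethod("show", "NucleusRegion", function(object) {
  cat("NucleusRegion", object@label, "-", sum(object@perSlideAreas > 0),
      "slides,", sum(object@mask), "voxels,", nrow(object@boundary),
      "boundary voxels\n")
})

setMethod("show", "ChromatinDomain", function(object) {
  cat("ChromatinDomain", object@label, "-", nrow(object@voxels),
      "voxels (nucleus", paste0(object@parentNucleus, ")"), "\n")
})

setMethod("show", "ShiftEstimate", function(object) {
  src <- if (is.na(object@slideIndex)) "per-stack median"
         else paste("slide", object@slideIndex)
  cat(sprintf("ShiftEstimate (dx = %d, dy = %d), peak r = %.4f [%s]\n",
              object@dx, object@dy, object@peakCorr, src))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@domains), "domains; nucleus semi-axes",
      paste(sprintf("%.2f", object@nucleusSemiAxesUm), collapse = " x "),
      "um; ER shift (", object@channelShift[1], ",",
      object@channelShift[2], ")\n")
})

#' @name domain-accessors
#' @title Accessors for detected domains and nuclei
#' @param x a \linkS4class{ChromatinDomain} or \linkS4class{NucleusRegion}.
#' @return \code{domainVoxels}, \code{nucleusBoundary}: integer matrices of
#'   0-based (z, y, x) coordinates; \code{nucleusMask}: 3D logical array.
NULL

#' @rdname domain-accessors
#' @export
setGeneric("domainVoxels", function(x) standardGeneric("domainVoxels"))
#' @rdname domain-accessors
#' @export
setMethod("domainVoxels", "ChromatinDomain", function(x) x@voxels)

#' @rdname domain-accessors
#' @export
setGeneric("nucleusMask", function(x) standardGeneric("nucleusMask"))
#' @rdname domain-accessors
#' @export
setMethod("nucleusMask", "NucleusRegion", function(x) x@mask)

#' @rdname domain-accessors
#' @export
setGeneric("nucleusBoundary", function(x) standardGeneric("nucleusBoundary"))
#' @rdname domain-accessors
#' @export
setMethod("nucleusBoundary", "NucleusRegion", function(x) x@boundary)
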