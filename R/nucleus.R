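# Per-slide DAPI nucleus segmentation: intensity threshold, 8-connectivity
# components, morphological refinement (fill / dilate x10 / fill), size and
# circularity filters, Sobel boundary extraction, and 3D stacking.

#' Threshold a DAPI slide
#'
#' @param slide 2D intensity matrix.
#' @param cutoff intensity cutoff; pixels strictly above it are ON.
#' @return 2D logical mask.
#' @export
thresholdDapi <- function(slide, cutoff = 500) {
  stopifnot(is.matrix(slide), length(slide) > 0)
  slide > cutoff
}

#' Largest connected components of a binary mask
#'
#' Labels ON pixels with an 8-connectivity neighbourhood structure and keeps
#' the \code{topK} largest components.
#'
#' @param mask 2D logical mask.
#' @param topK maximum number of components to return.
#' @return list of 2D logical masks, ordered by pixel count, largest first.
#' @export
candidateComponents <- function(mask, topK = 15L) {
  stopifnot(is.matrix(mask))
  lab <- cpp_label2d(mask)
  if (max(lab) == 0) return(list())
  sizes <- tabulate(lab)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(topK, length(sizes)))]
  lapply(keep, function(k) lab == k)
}

#' Morphological refinement of a candidate nucleus region
#'
#' Hole filling, dilation (default 10 iterations, full 3x3 structuring
#' element), and a second hole filling. The output always contains the input.
#'
#' @param region 2D logical mask (a single component).
#' @param dilations number of dilation iterations.
#' @return refined 2D logical mask.
#' @export
refineRegion <- function(region, dilations = 10L) {
  stopifnot(is.matrix(region))
  cpp_fill2d(cpp_dilate2d(cpp_fill2d(region), as.integer(dilations)))
}

#' Circularity of a 2D region
#'
#' \code{4 * pi * Area / Perimeter^2}; 1 for a disk, decreasing with
#' elongation and irregularity. The perimeter is measured by Moore contour
#' tracing with chain-code step lengths (1 axial, sqrt(2) diagonal).
#'
#' @param region 2D logical mask (a single component).
#' @return circularity score, or NA for an empty region.
#' @export
regionCircularity <- function(region) {
  area <- sum(region)
  if (area == 0) return(NA_real_)
  per <- cpp_perimeter(region)
  if (per <= 0) return(NA_real_)
  4 * pi * area / per^2
}

#' Accept or reject a refined nucleus region
#'
#' A refined per-slide region is a nucleus section if its pixel count is at
#' least \code{minPx} and its circularity exceeds \code{minShape} (strict).
#'
#' @param region refined 2D logical mask.
#' @param minPx minimum pixel count (default 100000, sized for 1500 x 1500
#'   slides).
#' @param minShape circularity lower bound (strict), default 0.4.
#' @return TRUE or FALSE.
#' @export
acceptNucleus <- function(region, minPx = 100000, minShape = 0.4) {
  area <- sum(region)
  if (area == 0) return(FALSE)
  circ <- regionCircularity(region)
  if (is.na(circ)) {
    warning("degenerate region with zero perimeter rejected")
    return(FALSE)
  }
  area >= minPx && circ > minShape
}

#' Sobel boundary of a binary region
#'
#' Computes Sobel gradients Gx and Gy on the binary mask (zero padding, so
#' frame-touching regions still yield closed contours), combines them as
#' \code{sqrt(Gx^2 + Gy^2)}, and binarizes at \code{> 0}. The positive set
#' forms a closed contour around each region; it includes the pixels on both
#' sides of the edge.
#'
#' @param region 2D logical mask.
#' @return 2D logical edge map.
#' @export
extractBoundary <- function(region) {
  stopifnot(is.matrix(region), sum(region) > 0)
  m <- region * 1
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(0, ny + 2, nx + 2)   # zero padding
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  sh <- function(dy, dx) pad[(2:(ny + 1)) + dy, (2:(nx + 1)) + dx]
  # Sobel kernels: Gy along rows, Gx along columns
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  sqrt(gx^2 + gy^2) > 0
}

#' Segment nuclei on a single slide
#'
#' threshold -> components -> refine -> accept, returning the accepted
#' regions and their Sobel boundaries.
#'
#' @param slide 2D DAPI intensity matrix.
#' @param cutoff DAPI ON cutoff (strict \code{>}).
#' @param topK number of largest candidate components examined.
#' @param minPx,minShape acceptance filters (see \code{\link{acceptNucleus}}).
#' @param dilations refinement dilation iterations.
#' @return list with \code{regions} and \code{boundaries}: lists of 2D
#'   logical masks, one per accepted nucleus section.
#' @export
segmentSlide <- function(slide, cutoff = 500, topK = 15L, minPx = 100000,
                         minShape = 0.4, dilations = 10L) {
  comps <- candidateComponents(thresholdDapi(slide, cutoff), topK)
  regions <- list(); boundaries <- list()
  for (comp in comps) {
    ref <- refineRegion(comp, dilations)
    if (acceptNucleus(ref, minPx, minShape)) {
      regions[[length(regions) + 1L]] <- ref
      boundaries[[length(boundaries) + 1L]] <- extractBoundary(ref)
    }
  }
  list(regions = regions, boundaries = boundaries)
}

#' Stack per-slide nucleus sections into 3D nuclei
#'
#' Accepted per-slide masks are concatenated along z and labelled as 3D
#' connected components (26-neighbourhood), so sections that overlap in
#' consecutive slides share a nucleus label. Each nucleus carries the
#' per-slide Sobel boundary positions of its own sections.
#'
#' @param perSlide list (ordered by z) of \code{\link{segmentSlide}} results.
#' @return list of \linkS4class{NucleusRegion} objects (possibly empty).
#' @export
stackNuclei <- function(perSlide) {
  nz <- length(perSlide)
  if (nz == 0) return(list())
  dims <- NULL
  for (s in perSlide) if (length(s$regions)) { dims <- dim(s$regions[[1]]); break }
  if (is.null(dims)) return(list())
  mask <- array(FALSE, dim = c(nz, dims[1], dims[2]))
  bmask <- array(FALSE, dim = c(nz, dims[1], dims[2]))
  for (z in seq_len(nz)) {
    for (r in perSlide[[z]]$regions) mask[z, , ] <- mask[z, , ] | r
    for (b in perSlide[[z]]$boundaries) bmask[z, , ] <- bmask[z, , ] | b
  }
  lab <- cpp_label3d(mask, dim(mask))
  nlab <- max(lab)
  if (nlab == 0) return(list())
  # attach boundary pixels to the nearest labelled section on their slide: a
  # boundary pixel belongs to the nucleus whose section produced it; since
  # boundaries hug their sections, assign by 2-step dilation of each label.
  out <- vector("list", nlab)
  for (k in seq_len(nlab)) {
    m <- lab == k
    areas <- apply(m, 1, sum)
    grown <- cpp_dilate3d(m, dim(m), 2L)
    bk <- which(bmask & grown, arr.ind = TRUE)
    boundary <- cbind(z = bk[, 1] - 1L, y = bk[, 2] - 1L, x = bk[, 3] - 1L)
    out[[k]] <- new("NucleusRegion", label = as.integer(k), mask = m,
                    boundary = boundary, perSlideAreas = as.integer(areas))
  }
  out
}

#' Segment all nuclei in an enhanced stack
#'
#' Runs per-slide segmentation on the DAPI channel of every slide (real and
#' interpolated) and stacks the results into 3D nuclei.
#'
#' @param stack a \linkS4class{MultiChannelStack} (typically enhanced).
#' @param dapiChannel channel name holding the DAPI signal.
#' @param ... passed to \code{\link{segmentSlide}}.
#' @return list of \linkS4class{NucleusRegion} objects.
#' @export
segmentNuclei <- function(stack, dapiChannel = "DAPI", ...) {
  dapi <- getChannel(stack, dapiChannel)
  perSlide <- lapply(seq_len(dim(dapi)[1]),
                     function(z) segmentSlide(dapi[z, , ], ...))
  stackNuclei(perSlide)
}

# Union mask of a list of NucleusRegion objects (3D logical array), or NULL.
nucleiUnionMask <- function(nuclei) {
  if (length(nuclei) == 0) return(NULL)
  m <- nuclei[[1]]@mask
  for (n in nuclei[-1]) m <- m | n@mask
  m
}
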