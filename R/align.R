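# Cross-correlation channel alignment: exhaustive integer-shift search for
# the Pearson-correlation peak between two channels, and rigid correction.

#' Estimate the shift between two slides
#'
#' Exhaustively scans integer corrections \code{(dx, dy)} with
#' \code{|dx|, |dy| <= maxShift} and returns the one maximizing the Pearson
#' correlation between \code{ref} and the correspondingly shifted
#' \code{moving} over their overlap. Ties are broken by smallest
#' \code{|dx| + |dy|}, then lexicographically by \code{(dy, dx)}.
#'
#' @param ref,moving 2D intensity matrices of identical shape.
#' @param maxShift search radius in pixels.
#' @param minOverlap minimum overlap fraction of the frame considered.
#' @param slideIndex optional 1-based slide index recorded in the result.
#' @return a \linkS4class{ShiftEstimate}.
#' @export
estimateShift <- function(ref, moving, maxShift = 50L, minOverlap = 0.25,
                          slideIndex = NA_integer_) {
  stopifnot(is.matrix(ref), is.matrix(moving))
  if (!all(dim(ref) == dim(moving)))
    stop("ref and moving must have identical shape")
  res <- cpp_best_shift(ref * 1, moving * 1, as.integer(maxShift),
                        minOverlap)
  if (!res$valid)
    stop("undefined correlation: zero-variance overlap at every ",
         "candidate shift")
  new("ShiftEstimate", dx = as.integer(res$dx), dy = as.integer(res$dy),
      peakCorr = res$corr, slideIndex = as.integer(slideIndex))
}

#' Estimate the channel shift for a whole stack
#'
#' Runs \code{\link{estimateShift}} on every requested slide and summarizes.
#' In \code{"global"} mode (default) the correction is the per-stack median of
#' the per-slide estimates, which resists low-signal slides; \code{"per-slide"}
#' mode keeps the individual estimates.
#'
#' @param stack a \linkS4class{MultiChannelStack}.
#' @param refChannel,movingChannel channel names (reference, to-be-shifted).
#' @param maxShift search radius in pixels.
#' @param mode \code{"global"} or \code{"per-slide"}.
#' @param slides 1-based slide indices to estimate on (default: all).
#' @return list with \code{perSlide} (list of \linkS4class{ShiftEstimate})
#'   and \code{global} (a \linkS4class{ShiftEstimate} with the median
#'   correction, \code{slideIndex = NA}).
#' @export
estimateStackShift <- function(stack, refChannel = "H3K27ac",
                               movingChannel = "ER", maxShift = 50L,
                               mode = c("global", "per-slide"),
                               slides = NULL) {
  mode <- match.arg(mode)
  ref <- getChannel(stack, refChannel)
  mov <- getChannel(stack, movingChannel)
  if (is.null(slides)) slides <- seq_len(dim(ref)[1])
  perSlide <- lapply(slides, function(z)
    estimateShift(ref[z, , ], mov[z, , ], maxShift, slideIndex = z))
  dxs <- vapply(perSlide, function(e) e@dx, 1L)
  dys <- vapply(perSlide, function(e) e@dy, 1L)
  glob <- new("ShiftEstimate", dx = as.integer(round(median(dxs))),
              dy = as.integer(round(median(dys))),
              peakCorr = median(vapply(perSlide, function(e) e@peakCorr, 1)),
              slideIndex = NA_integer_)
  list(perSlide = perSlide, global = glob, mode = mode)
}

#' Apply an integer shift to a 3D channel
#'
#' Rigidly translates every slide by \code{(dx, dy)}; vacated pixels are
#' filled with 0 and marked invalid so downstream correlation features can
#' exclude them.
#'
#' @param channel 3D array (slide, row, col).
#' @param dx,dy integer pixel shift (columns, rows), or a
#'   \linkS4class{ShiftEstimate} as \code{dx}.
#' @return list with \code{channel} (shifted array) and \code{valid}
#'   (logical array, FALSE where vacated).
#' @export
applyShift <- function(channel, dx, dy = NULL) {
  if (is(dx, "ShiftEstimate")) { dy <- dx@dy; dx <- dx@dx }
  d <- dim(channel)
  if (abs(dx) >= d[3] || abs(dy) >= d[2])
    stop("shift (", dx, ", ", dy, ") larger than the image")
  shiftSlices(channel, dx, dy)
}

#' Align a moving channel inside a stack
#'
#' Estimates the shift (global median by default) and applies it to the
#' moving channel in place; the validity mask is recorded under
#' \code{metadata$validMask[[movingChannel]]} and the estimate under
#' \code{metadata$shift[[movingChannel]]}.
#'
#' @inheritParams estimateStackShift
#' @return the corrected \linkS4class{MultiChannelStack}.
#' @export
alignChannel <- function(stack, refChannel = "H3K27ac",
                         movingChannel = "ER", maxShift = 50L,
                         mode = c("global", "per-slide"), slides = NULL) {
  mode <- match.arg(mode)
  est <- estimateStackShift(stack, refChannel, movingChannel, maxShift,
                            mode, slides)
  mov <- getChannel(stack, movingChannel)
  if (mode == "global") {
    sh <- applyShift(mov, est$global)
    chosen <- est$global
  } else {
    d <- dim(mov)
    out <- array(0, dim = d); valid <- array(FALSE, dim = d)
    bySlide <- setNames(est$perSlide,
                        vapply(est$perSlide, function(e) e@slideIndex, 1L))
    for (z in seq_len(d[1])) {
      e <- bySlide[[as.character(z)]]
      if (is.null(e)) e <- est$global
      s <- applyShift(mov[z, , , drop = FALSE], e@dx, e@dy)
      out[z, , ] <- s$channel; valid[z, , ] <- s$valid
    }
    sh <- list(channel = out, valid = valid)
    chosen <- est
  }
  stack@channels[[movingChannel]] <- sh$channel
  stack@metadata$validMask[[movingChannel]] <- sh$valid
  stack@metadata$shift[[movingChannel]] <- chosen
  stack
}
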