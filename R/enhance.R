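# Z-anisotropy balancing: insert two interpolated slides between each pair of
# adjacent real slides, turning (e.g.) 0.15 um Z spacing into 0.05 um.

#' Balance voxel dimensions by Z-axis interpolation
#'
#' Inserts two equidistant slides between every pair of adjacent real
#' Z-slides. The interpolated intensity is the distance-weighted average of
#' the two neighbouring real slides, \code{2/3 * closer + 1/3 * farther}, so a
#' stack with \code{N} real slides becomes \code{3N - 2} slides with
#' one-third the original Z spacing and flag pattern real, interp, interp,
#' real, ... All channels are interpolated identically; real slides are
#' unmodified; interpolated intensities are kept in floating point.
#'
#' An already-enhanced stack (any \code{"interpolated"} flag present) is
#' rejected rather than re-interpolated.
#'
#' @param stack a \linkS4class{MultiChannelStack} of real slides.
#' @return the enhanced \linkS4class{MultiChannelStack}.
#' @export
interpolateZ <- function(stack) {
  stopifnot(is(stack, "MultiChannelStack"))
  validObject(stack)
  if (any(stack@slideFlags == "interpolated"))
    stop("stack is already enhanced; refusing to re-interpolate")
  nz <- nSlides(stack)
  if (nz < 2) stop("at least 2 real slides are required for interpolation")
  nOut <- 3L * nz - 2L
  channels <- lapply(stack@channels, function(ch) {
    d <- dim(ch)
    out <- array(0, dim = c(nOut, d[2], d[3]))
    out[seq(1L, nOut, by = 3L), , ] <- ch
    for (s in seq_len(nz - 1L)) {
      a <- ch[s, , ]        # closer real slide for the first insertion
      b <- ch[s + 1L, , ]
      out[3L * s - 1L, , ] <- (2 / 3) * a + (1 / 3) * b
      out[3L * s, , ] <- (2 / 3) * b + (1 / 3) * a
    }
    out
  })
  flags <- rep("interpolated", nOut)
  flags[seq(1L, nOut, by = 3L)] <- "real"
  MultiChannelStack(channels = channels, spacingXY = stack@spacingXY,
                    spacingZ = stack@spacingZ / 3, slideFlags = flags,
                    metadata = stack@metadata)
}
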