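# TIFF + sidecar I/O and CSV tables.
#
# Stacks are written as one multi-page 32-bit float TIFF per channel
# (pages = slides, stored as intensity / 65535) plus a JSON sidecar holding
# spacing, slide flags, channel file names and whether the data are integer
# counts. Integer stacks round-trip bit-exactly (values are recovered by
# scaling and rounding); interpolated (floating point) stacks round-trip to
# 32-bit float precision.

#' Write a stack to TIFF files with a JSON sidecar
#'
#' @param stack a \linkS4class{MultiChannelStack}.
#' @param dir output directory (created if needed).
#' @param name basename for the files (\code{<name>_<channel>.tif},
#'   \code{<name>.json}).
#' @return invisibly, the sidecar path.
#' @export
writeStack <- function(stack, dir, name = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  integerData <- all(vapply(stack@channels,
                            function(ch) all(ch == round(ch)), TRUE))
  files <- list()
  for (ch in names(stack@channels)) {
    arr <- stack@channels[[ch]]
    if (max(arr) > 65535)
      stop("intensities above 65535 cannot be stored; channel ", ch)
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / 65535)
    f <- file.path(dir, paste0(name, "_", ch, ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = 32)
    files[[ch]] <- basename(f)
  }
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(list(
    channels = files, spacingXY = stack@spacingXY,
    spacingZ = stack@spacingZ, slideFlags = stack@slideFlags,
    integerData = integerData, metadata = stack@metadata$generator),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a stack written by \code{writeStack}
#'
#' @param dir directory holding the files.
#' @param name basename used at write time.
#' @param channelMap optional named character vector renaming channels on
#'   read (\code{c(newName = "storedName")}).
#' @param fallbackSpacing \code{c(z, xy)} spacing used, with a warning, when
#'   the sidecar lacks spacing metadata.
#' @return a \linkS4class{MultiChannelStack}.
#' @export
readStack <- function(dir, name = "stack", channelMap = NULL,
                      fallbackSpacing = c(0.15, 0.06)) {
  sidecar <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$spacingXY) || is.null(meta$spacingZ)) {
    warning("sidecar lacks spacing metadata; using fallback spacing")
    meta$spacingZ <- fallbackSpacing[1]; meta$spacingXY <- fallbackSpacing[2]
  }
  channels <- list()
  for (ch in names(meta$channels)) {
    pages <- tiff::readTIFF(file.path(dir, meta$channels[[ch]]), all = TRUE)
    arr <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                            ncol(pages[[1]])))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * 65535
    if (isTRUE(meta$integerData)) {
      arr <- round(arr)
      storage.mode(arr) <- "integer"
    }
    channels[[ch]] <- arr
  }
  if (!is.null(channelMap)) {
    missing <- setdiff(unname(channelMap), names(channels))
    if (length(missing))
      stop("channel(s) not in file: ", paste(missing, collapse = ", "),
           "; available: ", paste(names(channels), collapse = ", "))
    channels <- setNames(channels[unname(channelMap)], names(channelMap))
  }
  MultiChannelStack(channels = channels, spacingXY = meta$spacingXY,
                    spacingZ = meta$spacingZ, slideFlags = meta$slideFlags)
}

#' Assemble channels from a flat list of pages
#'
#' Multi-channel multi-page TIFFs come in two common layouts: channel-major
#' (all slides of channel 1, then channel 2, ...) or slide-major
#' (all channels of slide 1, then slide 2, ...). Given the channel names and
#' the layout, this reshapes a flat page list into named channel arrays.
#'
#' @param pages list of 2D matrices, length = nChannels * nSlides.
#' @param channels channel names in storage order.
#' @param layout \code{"channel-major"} or \code{"slide-major"}.
#' @return named list of 3D arrays, dim \code{c(nz, ny, nx)}.
#' @export
assembleChannels <- function(pages, channels,
                             layout = c("channel-major", "slide-major")) {
  layout <- match.arg(layout)
  nc <- length(channels)
  if (length(pages) %% nc != 0)
    stop("page count ", length(pages), " is not a multiple of the ",
         nc, " channels; specify the correct layout or channel names")
  nz <- length(pages) %/% nc
  out <- list()
  for (i in seq_len(nc)) {
    sel <- if (layout == "channel-major") (i - 1) * nz + seq_len(nz)
           else seq(i, by = nc, length.out = nz)
    arr <- array(0, dim = c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_len(nz)) arr[z, , ] <- pages[[sel[z]]]
    out[[channels[i]]] <- arr
  }
  out
}

#' Write a data.frame as a commented CSV
#'
#' Prepends header comment lines (units, coordinate convention) that
#' \code{readTableCsv} skips.
#'
#' @param df data.frame.
#' @param path output path.
#' @param comment character vector of comment lines (without "#").
#' @return invisibly, the path.
#' @export
writeTableCsv <- function(df, path, comment = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in c(comment,
               "coordinates are 0-based (z, y, x); distances/volumes in um"))
    writeLines(paste("#", cm), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTableCsv
#' @export
readTableCsv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
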