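# End-to-end orchestration: enhance -> segment -> align -> detect ->
# features, with a serializable parameter record and per-stage counts.

#' Pipeline run configuration
#'
#' All tunable parameters with their conventional defaults: DAPI ON cutoff
#' 500 (strict), top-15 candidate components, 10 refinement dilations,
#' nucleus acceptance at 100000 px and circularity 0.4, background top 0.1
#' percentile, 2 domain refinement dilations, domain retention in
#' [10, 100000] voxels, alignment search radius 50 px. The configuration
#' round-trips losslessly through JSON.
#'
#' @param seed integer seed recorded in the manifest.
#' @param dapiCutoff,topK,nucleusDilations,minNucleusPx,minCircularity
#'   nucleus segmentation parameters.
#' @param backgroundTopPercentile background fraction above the domain
#'   threshold.
#' @param domainRefineIterations,domainMinVoxels,domainMaxVoxels domain
#'   detection parameters.
#' @param maxShift,alignMode,alignSlides channel alignment parameters;
#'   \code{alignSlides = NULL} estimates on every slide.
#' @param channels named vector mapping roles (dapi, h3, er) to channel
#'   names; the er entry may be NA for two-channel data.
#' @param spacingOverride optional \code{c(z, xy)} spacing override.
#' @param outDir optional output directory; when set, \code{runPipeline}
#'   writes the feature CSV and manifest JSON there.
#' @return a list of class \code{RunConfig}.
#' @export
runConfig <- function(seed = 1L, dapiCutoff = 500, topK = 15L,
                      nucleusDilations = 10L, minNucleusPx = 100000,
                      minCircularity = 0.4, backgroundTopPercentile = 0.001,
                      domainRefineIterations = 2L, domainMinVoxels = 10L,
                      domainMaxVoxels = 100000L, maxShift = 50L,
                      alignMode = "global", alignSlides = NULL,
                      channels = c(dapi = "DAPI", h3 = "H3K27ac",
                                   er = "ER"),
                      spacingOverride = NULL, outDir = NULL) {
  cfg <- list(seed = seed, dapiCutoff = dapiCutoff, topK = topK,
              nucleusDilations = nucleusDilations,
              minNucleusPx = minNucleusPx, minCircularity = minCircularity,
              backgroundTopPercentile = backgroundTopPercentile,
              domainRefineIterations = domainRefineIterations,
              domainMinVoxels = domainMinVoxels,
              domainMaxVoxels = domainMaxVoxels, maxShift = maxShift,
              alignMode = alignMode, alignSlides = alignSlides,
              channels = as.list(channels),
              spacingOverride = spacingOverride, outDir = outDir)
  class(cfg) <- "RunConfig"
  cfg
}

#' Serialize / restore a run configuration
#'
#' @param config a \code{RunConfig}.
#' @param path JSON file path.
#' @return \code{readRunConfig}: the restored \code{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- runConfig()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  if (length(cfg$channels)) cfg$channels <- as.list(cfg$channels)
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full analysis pipeline on one stack
#'
#' enhance (Z interpolation) -> per-slide nucleus segmentation -> channel
#' alignment (when an ER channel is mapped) -> background-percentile domain
#' detection -> per-domain features. Deterministic given the stack and
#' configuration. If no nucleus is accepted the run completes with an empty
#' feature table and a warning.
#'
#' @param stack a raw (real-slides-only) \linkS4class{MultiChannelStack}.
#' @param config a \code{\link{runConfig}}.
#' @param cell,condition,batch labels attached to feature rows.
#' @return list: \code{features} (data.frame), \code{nuclei},
#'   \code{domains}, \code{threshold}, \code{shift}, \code{enhanced} (the
#'   enhanced stack), and \code{manifest} (parameters, input fingerprint and
#'   per-stage counts; written to \code{outDir} if configured).
#' @export
runPipeline <- function(stack, config = runConfig(), cell = "cell1",
                        condition = NA, batch = NA) {
  stopifnot(is(stack, "MultiChannelStack"))
  ch <- config$channels
  for (role in c("dapi", "h3"))
    if (is.null(ch[[role]]) || !ch[[role]] %in% channelNames(stack))
      stop("channel mapping for '", role, "' not found in stack; ",
           "available: ", paste(channelNames(stack), collapse = ", "))
  hasEr <- !is.null(ch$er) && !is.na(ch$er) &&
    ch$er %in% channelNames(stack)
  if (!is.null(config$spacingOverride)) {
    stack@spacingZ <- config$spacingOverride[1]
    stack@spacingXY <- config$spacingOverride[2]
  }

  enhanced <- interpolateZ(stack)
  spacing <- voxelSpacing(enhanced)

  nuclei <- segmentNuclei(enhanced, dapiChannel = ch$dapi,
                          cutoff = config$dapiCutoff, topK = config$topK,
                          minPx = config$minNucleusPx,
                          minShape = config$minCircularity,
                          dilations = config$nucleusDilations)

  shift <- NULL
  if (hasEr) {
    enhanced <- alignChannel(enhanced, refChannel = ch$h3,
                             movingChannel = ch$er,
                             maxShift = config$maxShift,
                             mode = config$alignMode,
                             slides = config$alignSlides)
    shift <- enhanced@metadata$shift[[ch$er]]
  }

  h3 <- getChannel(enhanced, ch$h3)
  er <- if (hasEr) getChannel(enhanced, ch$er) else NULL
  erValid <- if (hasEr) enhanced@metadata$validMask[[ch$er]] else NULL

  features <- NULL; domains <- list(); thr <- NULL
  if (length(nuclei) == 0) {
    warning("no nucleus accepted; returning an empty feature table")
    features <- domainFeatureTable(list(), NULL, spacing)
  } else {
    thr <- backgroundThreshold(h3, nucleiUnionMask(nuclei),
                               config$backgroundTopPercentile)
    tables <- list()
    for (nuc in nuclei) {
      doms <- detectDomains(h3, thr$threshold, nuc, er, erValid,
                            minVoxels = config$domainMinVoxels,
                            maxVoxels = config$domainMaxVoxels,
                            refineIterations = config$domainRefineIterations)
      domains <- c(domains, doms)
      tables[[length(tables) + 1L]] <-
        domainFeatureTable(doms, nuc, spacing, cell = cell,
                           condition = condition, batch = batch)
    }
    features <- do.call(rbind, tables)
  }

  manifest <- list(
    parameters = unclass(config),
    input = list(dim = dim(getChannel(stack, ch$dapi)),
                 channels = channelNames(stack),
                 fingerprint = vapply(stack@channels, sum, 1)),
    counts = list(nuclei = length(nuclei), domains = length(domains),
                  slides = nSlides(enhanced)),
    threshold = thr,
    shift = if (!is.null(shift) && is(shift, "ShiftEstimate"))
      list(dx = shift@dx, dy = shift@dy, peakCorr = shift@peakCorr)
    else NULL)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeTableCsv(features,
                  file.path(config$outDir,
                            paste0(cell, "_domain_features.csv")))
    jsonlite::write_json(manifest,
                         file.path(config$outDir,
                                   paste0(cell, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  list(features = features, nuclei = nuclei, domains = domains,
       threshold = thr, shift = shift, enhanced = enhanced,
       manifest = manifest)
}

#' Analyze a synthetic cohort end to end
#'
#' Runs \code{\link{runPipeline}} on every stack of a
#' \code{\link{generateCohort}} result, pools the feature tables with their
#' condition/batch/cell labels, and assigns pooled-quartile volume classes.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param config a \code{\link{runConfig}}.
#' @return list: \code{features} (pooled per-domain table with
#'   \code{volumeClass}), \code{cells} (per-cell summaries), \code{runs}
#'   (per-stack manifests).
#' @export
analyzeCohort <- function(cohort, config = runConfig()) {
  tables <- list(); runs <- list()
  for (i in seq_len(nrow(cohort$index))) {
    lab <- cohort$index[i, ]
    res <- runPipeline(cohort$stacks[[i]]$stack, config,
                       cell = paste0("b", lab$batch, "c", lab$cell),
                       condition = lab$condition, batch = lab$batch)
    tables[[i]] <- res$features
    runs[[i]] <- res$manifest
  }
  features <- do.call(rbind, tables)
  if (nrow(features) >= 4)
    features$volumeClass <- assignVolumeClasses(features$volumeVox)
  list(features = features,
       cells = if (nrow(features)) cellSummary(features) else NULL,
       runs = runs)
}

#' Directional cohort benchmark
#'
#' Generates a two-condition cohort (estrogen-stimulated-like versus
#' estrogen-deprived-like, \code{\link{defaultConditionSpecs}}), runs the
#' full pipeline on every stack, and summarizes the condition contrast:
#' pooled feature means, pooled-quartile volume-class distribution, and the
#' per-batch t statistics of the stimulated condition against the deprived
#' one for volume, sphericity and boundary distance.
#'
#' @param seed master seed for the cohort.
#' @param nCellsPerCondition,nBatches cohort layout (cells are split evenly
#'   across batches).
#' @param gridShape raw grid per stack.
#' @param minNucleusPx nucleus size filter, scaled to the field of view.
#' @param maxShift,alignSlides alignment parameters for the cohort scale.
#' @return list: \code{features}, \code{conditionMeans} (data.frame),
#'   \code{volumeClassShare} (fraction per class per condition),
#'   \code{batchT} (per-batch, per-feature t table), \code{checks} (named
#'   logical vector of the expected contrast directions).
#' @export
benchmarkCohort <- function(seed, nCellsPerCondition = 10, nBatches = 2,
                            gridShape = c(10L, 256L, 256L),
                            minNucleusPx = 5000, maxShift = 6L,
                            alignSlides = c(8L, 14L, 20L)) {
  stopifnot(nCellsPerCondition %% nBatches == 0)
  co <- generateCohort(defaultConditionSpecs(),
                       nCellsPerCondition = nCellsPerCondition %/% nBatches,
                       nBatches = nBatches, seed = seed,
                       gridShape = gridShape)
  cfg <- runConfig(seed = seed, minNucleusPx = minNucleusPx,
                   maxShift = maxShift, alignSlides = alignSlides)
  res <- analyzeCohort(co, cfg)
  f <- res$features
  agg <- aggregate(f[, c("volumeVox", "sphericity", "boundaryDistUm",
                         "corr")],
                   by = list(condition = f$condition), FUN = mean,
                   na.rm = TRUE)
  shares <- prop.table(table(f$condition, f$volumeClass), margin = 1)
  bt <- do.call(rbind, lapply(
    c("volumeVox", "sphericity", "boundaryDistUm"), function(feat)
      cbind(feature = feat,
            batchTSummary(f, feat, ref = "E2-like", others = "ED-like"))))
  e2 <- agg[agg$condition == "E2-like", ]
  ed <- agg[agg$condition == "ED-like", ]
  meanClass <- tapply(f$volumeClass, f$condition, mean)
  checks <- c(
    volumeHigher = e2$volumeVox > ed$volumeVox,
    sphericityLower = e2$sphericity < ed$sphericity,
    distanceLarger = e2$boundaryDistUm > ed$boundaryDistUm,
    classesRightShifted = meanClass[["E2-like"]] > meanClass[["ED-like"]],
    tVolumePositive = all(bt$t[bt$feature == "volumeVox"] > 0),
    tSphericityNegative = all(bt$t[bt$feature == "sphericity"] < 0),
    tDistancePositive = all(bt$t[bt$feature == "boundaryDistUm"] > 0))
  list(features = f, conditionMeans = agg, volumeClassShare = shares,
       batchT = bt, checks = checks)
}
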