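mkNucleus <- function(mask) {
  new("NucleusRegion", label = 1L, mask = mask,
      boundary = matrix(integer(), 0, 3),
      perSlideAreas = as.integer(apply(mask, 1, sum)))
}

test_that("background threshold is the 99.9th percentile of outside voxels", {
  h <- array(5, dim = c(3, 4, 4))
  numask <- array(FALSE, dim = c(3, 4, 4)); numask[2, 2:3, 2:3] <- TRUE
  bt <- backgroundThreshold(h, numask)
  expect_equal(bt$threshold, 5)
  expect_equal(bt$nBackground, 48 - 4)
  # the integers 1..1e6 shuffled: matches the sort-based oracle value
  set.seed(4)
  vals <- sample(1e6)
  h2 <- array(vals, dim = c(100, 100, 100))
  bt2 <- backgroundThreshold(h2, array(FALSE, dim = c(100, 100, 100)))
  x <- sort(vals)                       # linear interpolation oracle
  hpos <- (1e6 - 1) * 0.999 + 1
  oracle <- x[floor(hpos)] + (hpos - floor(hpos)) *
    (x[ceiling(hpos)] - x[floor(hpos)])
  expect_equal(bt2$threshold, oracle)
  expect_equal(bt2$threshold, 999000.001, tolerance = 1e-6)
  # about 0.1% of background lies strictly above the threshold
  frac <- mean(vals > bt2$threshold)
  expect_lt(abs(frac - 0.001), 2e-4)
  # all-inside mask has no background
  expect_error(backgroundThreshold(h, array(TRUE, dim = dim(h))),
               "no voxels outside")
})

test_that("a bright block inside the nucleus becomes one retained domain", {
  d <- c(12L, 12L, 12L)
  h <- array(10, dim = d)
  h[5:7, 5:7, 5:7] <- 1000
  nuc <- mkNucleus(array(TRUE, dim = d))
  doms <- detectDomains(h, 500, nuc)
  expect_length(doms, 1)
  expect_gte(nrow(doms[[1]]@voxels), 27)
  # all 27 seed voxels survive refinement
  seeds <- which(h > 500, arr.ind = TRUE) - 1L
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(key(seeds) %in% key(doms[[1]]@voxels)))
})

test_that("retention bounds are inclusive at 10 and 100000 voxels", {
  d <- c(20L, 20L, 20L)
  nuc <- mkNucleus(array(TRUE, dim = d))
  mkBlock <- function(n) {            # n voxels in a 1-voxel-high slab
    h <- array(0, dim = d)
    h[10, 10, 1:n] <- 1000
    h
  }
  # with no refinement dilation the component size is the seed size
  expect_length(detectDomains(mkBlock(9), 500, nuc, refineIterations = 0L), 0)
  expect_length(detectDomains(mkBlock(10), 500, nuc, refineIterations = 0L), 1)
  big <- array(0, dim = d); big[1:15, 1:20, 1:20] <- 1000  # 6000 voxels
  expect_length(detectDomains(big, 500, nuc, refineIterations = 0L,
                              maxVoxels = 5999L), 0)
  expect_length(detectDomains(big, 500, nuc, refineIterations = 0L,
                              maxVoxels = 6000L), 1)
})

test_that("well-separated blocks stay separate; refinement is per-component", {
  d <- c(24L, 24L, 24L)
  h <- array(0, dim = d)
  h[4:6, 4:6, 4:6] <- 1000
  h[12:14, 12:14, 12:14] <- 1000   # > 2 voxels away in every axis
  nuc <- mkNucleus(array(TRUE, dim = d))
  doms <- detectDomains(h, 500, nuc)
  expect_length(doms, 2)
  # each refined component is its own 7x7x7 dilation result, unmerged
  expect_true(all(vapply(doms, function(x) nrow(x@voxels), 1) == 343))
})

test_that("ON voxels are restricted to the nucleus and respond monotonically to the threshold", {
  d <- c(10L, 10L, 10L)
  set.seed(8)
  h <- array(sample(0:1000, prod(d), TRUE), dim = d)
  numask <- array(FALSE, dim = d); numask[3:8, 3:8, 3:8] <- TRUE
  nuc <- mkNucleus(numask)
  onAt <- function(thr) sum(numask & h > thr)
  thrs <- c(100, 300, 500, 700, 900)
  expect_true(all(diff(vapply(thrs, onAt, 1)) <= 0))
  for (thr in c(300, 700)) {
    doms <- detectDomains(h, thr, nuc)
    for (dm in doms) {
      idx <- dm@voxels + 1L
      # every retained domain's seed has at least one super-threshold voxel
      expect_true(any(h[idx] > thr))
      # voxels stay within the nucleus plus its dilation margin
      margin <- SIMDomains:::cpp_dilate3d(numask, dim(numask), 2L)
      expect_true(all(margin[idx]))
    }
  }
})

test_that("detection recovers generator ground truth (counts and Jaccard)", {
  # counts at the default study conditions
  for (cond in defaultConditionSpecs()) {
    g <- generateStack(cond, seed = 31)
    cfg <- runConfig(minNucleusPx = 5000, maxShift = 6,
                     alignSlides = c(8L, 14L, 20L))
    res <- runPipeline(g$stack, cfg, condition = cond@name)
    nTrue <- nrow(g$truth@domains)
    expect_lte(abs(length(res$domains) - nTrue) / nTrue, 0.2)
  }
  # per-domain overlap accuracy, on domains large enough that the fixed
  # 2-voxel refinement margin is a minor fraction of the object
  sp <- conditionSpec("jaccard", nDomainsMean = 6, domainShape = "sphere",
                      domainRadiusVox = 12, boundaryBias = 0,
                      channelShiftXY = c(0L, 0L))
  g <- generateStack(sp, gridShape = c(26L, 224L, 224L), seed = 31)
  cfg <- runConfig(minNucleusPx = 4000, maxShift = 4, alignSlides = 20L)
  res <- runPipeline(g$stack, cfg, condition = "jaccard")
  nTrue <- nrow(g$truth@domains)
  expect_lte(abs(length(res$domains) - nTrue) / nTrue, 0.2)
  enh <- res$enhanced
  truthVox <- truthDomainVoxels(g$truth, dim(getChannel(enh, "H3K27ac")),
                                voxelSpacing(enh))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  detKeys <- lapply(res$domains, function(d) key(d@voxels))
  for (tv in truthVox) {
    if (nrow(tv) < 50) next
    tk <- key(tv)
    jac <- max(vapply(detKeys, function(dk)
      length(intersect(tk, dk)) / length(union(tk, dk)), 1))
    expect_gte(jac, 0.5)
  }
})
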