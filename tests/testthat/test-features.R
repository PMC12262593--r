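mkDomain <- function(h, e, vox = NULL) {
  n <- length(h)
  if (is.null(vox)) vox <- cbind(z = 0L, y = 0L, x = seq_len(n) - 1L)
  new("ChromatinDomain", label = 1L, voxels = vox,
      h3k27acIntensities = as.numeric(h), erIntensities = as.numeric(e),
      parentNucleus = 1L)
}

test_that("domain correlation matches affine expectations and the sum-formula oracle", {
  h <- c(3, 8, 1, 9, 4)
  expect_equal(domainCorrelation(mkDomain(h, 2 * h + 5)), 1)
  expect_equal(domainCorrelation(mkDomain(h, -h)), -1)
  expect_equal(domainCorrelation(mkDomain(1:4, c(1, 2, 3, 100))),
               pearsonOracle(1:4, c(1, 2, 3, 100)), tolerance = 1e-12)
  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(length(a))
    expect_equal(domainCorrelation(mkDomain(a, b)), pearsonOracle(a, b),
                 tolerance = 1e-10)
  }
  r <- domainCorrelation(mkDomain(rep(2, 5), 1:5))
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "zero variance")
})

test_that("sphericity is calibrated on balls and closed-form spheroids", {
  expect_equal(domainSphericity(ballVoxels(10), c(1, 1, 1)), 1,
               tolerance = 0.05)
  a <- 24; b <- 6
  e <- sqrt(1 - (b / a)^2)
  sTrue <- 2 * pi * b^2 * (1 + (a / b) * asin(e) / e)
  vTrue <- 4 / 3 * pi * a * b^2
  phiTrue <- pi^(1 / 3) * (6 * vTrue)^(2 / 3) / sTrue
  expect_equal(domainSphericity(spheroidVoxels(a, b), c(1, 1, 1)), phiTrue,
               tolerance = 0.05 * phiTrue)
})

test_that("sphericity is scale invariant and decreases with capsule elongation", {
  expect_equal(domainSphericity(ballVoxels(10), c(1, 1, 1)),
               domainSphericity(ballVoxels(15), c(1, 1, 1)),
               tolerance = 0.03)
  targetV <- nrow(ballVoxels(10))
  phis <- vapply(c(1, 2, 4, 8), function(el) {
    f <- function(r) 4 / 3 * pi * r^3 + 2 * pi * r^3 * (el - 1) - targetV
    r <- uniroot(f, c(1, 20))$root
    domainSphericity(capsuleVoxels(r, r * (el - 1)), c(1, 1, 1))
  }, 1)
  expect_true(all(diff(phis) < 0))
})

test_that("anisotropic spacing enters the sphericity surface integral", {
  # a ball in physical units sampled on an anisotropic grid still scores ~1
  g <- expand.grid(z = 0:20, y = 0:60, x = 0:60)
  keep <- ((g$z - 10) * 0.15)^2 + ((g$y - 30) * 0.05)^2 +
    ((g$x - 30) * 0.05)^2 <= 1.2^2
  vox <- as.matrix(g[keep, ])
  expect_equal(domainSphericity(vox, c(0.15, 0.05, 0.05)), 1,
               tolerance = 0.06)
})

test_that("boundary distance matches geometry and the exhaustive oracle", {
  d <- c(41L, 41L, 41L)
  mask <- array(FALSE, dim = d)
  g <- expand.grid(z = 1:41, y = 1:41, x = 1:41)
  inside <- (g$z - 21)^2 + (g$y - 21)^2 + (g$x - 21)^2 <= 15^2
  mask[as.matrix(g[inside, ])] <- TRUE
  shell <- (g$z - 21)^2 + (g$y - 21)^2 + (g$x - 21)^2
  bnd <- as.matrix(g[shell <= 15^2 & shell > 14^2, ]) - 1L
  nuc <- new("NucleusRegion", label = 1L, mask = mask, boundary = bnd,
             perSlideAreas = as.integer(apply(mask, 1, sum)))
  ctrDom <- mkDomain(1:3, 1:3, cbind(z = 19:21, y = 20L, x = 20L))
  expect_equal(boundaryDistance(ctrDom, nuc, c(1, 1, 1)), 15,
               tolerance = 1.2)
  touching <- mkDomain(1:3, 1:3, cbind(z = 21L, y = 21L, x = 33:35))
  expect_lte(boundaryDistance(touching, nuc, c(1, 1, 1)), 1.5)
  set.seed(9)
  for (i in 1:5) {
    vox <- cbind(z = sample(15:25, 4), y = sample(15:25, 4),
                 x = sample(15:25, 4))
    dom <- mkDomain(1:4, 1:4, vox)
    sp <- c(0.15, 0.06, 0.06)
    expect_equal(boundaryDistance(dom, nuc, sp),
                 boundaryDistOracle(colMeans(vox) * sp, bnd, sp),
                 tolerance = 1e-10)
  }
})

test_that("volume classes: quartiles, explicit boundaries, degeneracies", {
  cl <- assignVolumeClasses(1:100)
  expect_equal(as.integer(table(cl)), c(25L, 25L, 25L, 25L))
  expect_equal(assignVolumeClasses(c(5, 50, 500, 5000), c(10, 100, 1000)),
               1:4)
  expect_warning(cl2 <- assignVolumeClasses(rep(3, 8)), "tied")
  expect_true(all(cl2 == 1))
  expect_error(assignVolumeClasses(1:10, c(10, 5, 20)),
               "strictly increasing")
  expect_error(assignVolumeClasses(1:3), "at least 4")
})

test_that("Gini index matches frozen values and the pairwise oracle; scale invariant", {
  expect_equal(giniIndex(rep(4, 6)), 0)
  expect_equal(giniIndex(c(0, 0, 0, 1)), 0.75)
  expect_equal(giniIndex(c(1, 3)), 0.25)
  set.seed(12)
  for (i in 1:20) {
    x <- runif(sample(2:25, 1), 0, 10)
    expect_equal(giniIndex(x), giniOracle(x), tolerance = 1e-12)
    expect_equal(giniIndex(3.7 * x), giniIndex(x), tolerance = 1e-12)
  }
  expect_error(giniIndex(c(0, 0)), "all-zero")
  expect_error(giniIndex(c(-1, 2)), "non-negative")
  expect_error(giniIndex(5), "at least 2")
})

test_that("feature table and per-cell summary carry labels and Gini columns", {
  g <- generateStack(defaultConditionSpecs()[["ED-like"]], seed = 19)
  cfg <- runConfig(minNucleusPx = 5000, maxShift = 6,
                   alignSlides = c(10L, 14L))
  res <- runPipeline(g$stack, cfg, cell = "c1", condition = "ED-like",
                     batch = 1)
  f <- res$features
  expect_true(all(c("corr", "volumeVox", "volumeUm3", "sphericity",
                    "boundaryDistUm") %in% names(f)))
  expect_true(all(f$condition == "ED-like"))
  expect_true(all(f$volumeVox >= 10 & f$volumeVox <= 100000))
  expect_true(all(f$corr[!is.na(f$corr)] >= -1 & f$corr[!is.na(f$corr)] <= 1))
  expect_true(all(f$boundaryDistUm >= 0))
  expect_equal(f$volumeUm3, f$volumeVox * prod(voxelSpacing(res$enhanced)))
  cs <- cellSummary(f)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$nDomains, nrow(f))
  expect_true(cs$giniVolume >= 0 && cs$giniVolume < 1)
})
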