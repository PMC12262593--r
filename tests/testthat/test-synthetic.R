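test_that("identical seeds give bit-identical stacks, different seeds differ", {
  sp <- defaultConditionSpecs()[["ED-like"]]
  g1 <- generateStack(sp, seed = 42)
  g2 <- generateStack(sp, seed = 42)
  g3 <- generateStack(sp, seed = 43)
  expect_identical(g1$stack@channels, g2$stack@channels)
  expect_identical(g1$truth@domains, g2$truth@domains)
  expect_false(identical(g1$stack@channels, g3$stack@channels))
})

test_that("perfect target correlation with no mixing noise gives r = 1 in every domain", {
  sp <- conditionSpec("coloc", nDomainsMean = 8, erCorrelation = 1,
                      intensitySd = 60)
  g <- generateStack(sp, seed = 5)
  h <- getChannel(g$stack, "H3K27ac")
  er <- getChannel(g$stack, "ER")
  d <- dim(h)
  for (vox in g$truth@voxels) {
    idx <- vox + 1L
    expect_equal(cor(h[idx], er[idx]), 1)
  }
})

test_that("realized elongation tracks the request and separates conditions", {
  specs <- defaultConditionSpecs()
  axisRatio <- function(vox, spacing = c(0.15, 0.06, 0.06)) {
    p <- vox * rep(spacing, each = nrow(vox))
    ev <- eigen(cov(p), symmetric = TRUE, only.values = TRUE)$values
    sqrt(ev[1] / mean(ev[2:3]))
  }
  ratios <- lapply(names(specs), function(cond) {
    unlist(lapply(1:4, function(s) {
      g <- generateStack(specs[[cond]], seed = 300 + s)
      vapply(g$truth@voxels, axisRatio, 1)
    }))
  })
  names(ratios) <- names(specs)
  expect_gte(length(ratios[["E2-like"]]), 100)
  expect_gt(mean(ratios[["E2-like"]]), mean(ratios[["ED-like"]]))
  # mean principal-axis ratio within 15% of the requested elongation
  expect_lt(abs(mean(ratios[["E2-like"]]) / 4 - 1), 0.15)
  expect_lt(abs(mean(ratios[["ED-like"]]) / 1 - 1), 0.15)
})

test_that("realized in-domain colocalization is within 0.1 of the target", {
  for (rho in c(0.3, 0.6, 0.9)) {
    sp <- conditionSpec("rho-check", nDomainsMean = 40, domainRadiusVox = 4,
                        erCorrelation = rho, channelShiftXY = c(0L, 0L))
    vals <- lapply(1:3, function(s) {
      g <- generateStack(sp, seed = 1000 * rho + s)
      h <- getChannel(g$stack, "H3K27ac"); er <- getChannel(g$stack, "ER")
      idx <- do.call(rbind, g$truth@voxels) + 1L
      cbind(h[idx], er[idx])
    })
    m <- do.call(rbind, vals)
    expect_gte(nrow(m), 1e4)
    expect_lt(abs(cor(m[, 1], m[, 2]) - rho), 0.1)
  }
})

test_that("DAPI respects the nucleus brightness floor on both sides", {
  g <- generateStack(defaultConditionSpecs()[["ED-like"]], seed = 9)
  dapi <- getChannel(g$stack, "DAPI")
  inside <- truthNucleusMask(g$truth)
  expect_gte(mean(dapi[inside] > 500), 0.99)
  expect_gte(mean(dapi[!inside] < 500), 0.99)
})

test_that("every true domain voxel lies inside the nucleus ellipsoid", {
  for (cond in defaultConditionSpecs()) {
    g <- generateStack(cond, seed = 21)
    tr <- g$truth
    for (vox in tr@voxels) {
      q <- sweep(sweep(vox, 2, c(0.15, 0.06, 0.06) / 1, "*"), 2,
                 tr@nucleusCenterUm) / rep(tr@nucleusSemiAxesUm,
                                           each = nrow(vox))
      expect_true(all(rowSums(q^2) <= 1 + 1e-12))
    }
  }
})

test_that("cohort generation is labelled, counted and reproducible", {
  specs <- defaultConditionSpecs()
  co <- generateCohort(specs, nCellsPerCondition = 3, nBatches = 2, seed = 7)
  expect_equal(nrow(co$index), 12)
  expect_setequal(unique(co$index$condition), names(specs))
  expect_equal(as.integer(table(co$index$condition)), c(6L, 6L))
  co2 <- generateCohort(specs, nCellsPerCondition = 3, nBatches = 2, seed = 7)
  expect_identical(co$index$seed, co2$index$seed)
  expect_identical(co$stacks[[5]]$stack@channels,
                   co2$stacks[[5]]$stack@channels)
  # a single cell regenerates from its recorded sub-seed alone
  i <- 7
  sp <- specs[[co$index$condition[i]]]
  expect_false(identical(co$index$seed[1], co$index$seed[2]))
})

test_that("batch intensity offsets shift batch means but preserve condition order", {
  specs <- defaultConditionSpecs()
  co <- generateCohort(specs, nCellsPerCondition = 3, nBatches = 2,
                       seed = 11, batchIntensitySd = 60)
  inDomainMean <- function(entry) {
    h <- getChannel(entry$stack, "H3K27ac")
    idx <- do.call(rbind, entry$truth@voxels) + 1L
    mean(h[idx])
  }
  m <- cbind(co$index, mu = vapply(co$stacks, inDomainMean, 1))
  agg <- aggregate(mu ~ condition + batch, data = m, FUN = mean)
  for (cond in names(specs)) {
    v <- agg$mu[agg$condition == cond]
    expect_gt(abs(diff(v)), 1)   # batches differ
  }
  for (b in 1:2) {               # condition ordering preserved within batch
    v <- agg[agg$batch == b, ]
    expect_gt(v$mu[v$condition == "E2-like"], v$mu[v$condition == "ED-like"])
  }
})

test_that("generator input validation", {
  specs <- defaultConditionSpecs()
  expect_error(generateCohort(list(specs[[1]], specs[[1]]), 2),
               "duplicate condition names")
  # a domain too large for a tiny nucleus cannot be placed
  sp <- conditionSpec("big", nDomainsMean = 2, domainRadiusVox = 40)
  expect_error(generateStack(sp, gridShape = c(4L, 64L, 64L)), "too large")
  # partial correlation is unreachable without in-domain variance
  sp2 <- conditionSpec("flat", erCorrelation = 0.5, intensitySd = 0)
  expect_error(generateStack(sp2), "unreachable")
  # invalid specs are rejected at construction
  expect_error(conditionSpec("bad", erCorrelation = 1.5))
  expect_error(conditionSpec("bad", domainShape = "sphere",
                             elongationRatio = 2))
})
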