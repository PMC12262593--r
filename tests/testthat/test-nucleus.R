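test_that("DAPI threshold is strictly greater-than", {
  slide <- matrix(c(499, 500, 501, 0), 2, 2)
  expect_identical(thresholdDapi(slide), slide == 501)
  expect_false(any(thresholdDapi(matrix(0, 4, 4))))
  expect_true(all(thresholdDapi(matrix(0:8, 3, 3), cutoff = -1)))
})

test_that("candidate components: 8-connectivity, size ranking, top-k truncation", {
  # two diagonally touching pixels form one component
  m <- matrix(FALSE, 4, 4); m[1, 1] <- m[2, 2] <- TRUE
  expect_length(candidateComponents(m), 1)
  # 30 disjoint blobs of increasing size -> the 15 largest, ordered
  n <- 30
  m <- matrix(FALSE, 40, 40 * n)
  for (i in 1:n) m[1:i, 40 * (i - 1) + 1] <- TRUE
  comps <- candidateComponents(m, topK = 15)
  expect_length(comps, 15)
  sizes <- vapply(comps, sum, 1)
  expect_equal(sizes, 30:16)
  # fewer blobs than top-k: all returned
  expect_length(candidateComponents(diag(3) > 0, topK = 15), 1)
  m3 <- matrix(FALSE, 9, 3); m3[c(1, 4, 7), 2] <- TRUE
  m3 <- t(m3)
  expect_length(candidateComponents(t(m3), topK = 15), 3)
})

test_that("refinement fills holes and dilates like the independent oracle", {
  skip_if_not_installed("EBImage")
  oracle <- function(m, iter) {
    x <- EBImage::fillHull(m * 1)
    br <- EBImage::makeBrush(3, "box")
    for (i in seq_len(iter)) x <- EBImage::dilate(x, br)
    EBImage::fillHull(x) > 0
  }
  # annulus -> solid disk grown by the dilation steps
  ann <- diskMask(12, 45) & !diskMask(6, 45)
  expect_identical(unname(refineRegion(ann, 10)),
                   unname(oracle(ann, 10)))
  # random blobs, various iteration counts
  for (seed in 1:8) {
    m <- randomBlobMask(25, seed)
    it <- seed %% 4
    expect_identical(unname(refineRegion(m, it)), unname(oracle(m, it)))
  }
})

test_that("refining a solid disk grows it by the dilation radius (Chebyshev)", {
  r <- 8; n <- 45
  d <- diskMask(r, n)
  out <- refineRegion(d, 10)
  # full 3x3 dilation x10 = Chebyshev distance <= 10 from the disk
  ctr <- (n + 1) / 2
  oracle <- matrix(FALSE, n, n)
  dv <- which(d, arr.ind = TRUE)
  for (y in 1:n) for (x in 1:n)
    oracle[y, x] <- any(pmax(abs(dv[, 1] - y), abs(dv[, 2] - x)) <= 10)
  expect_identical(unname(out), unname(oracle))
  expect_true(all(out[d]))   # monotone: output contains input
})

test_that("refinement output always contains its input", {
  for (seed in 11:16) {
    m <- randomBlobMask(20, seed)
    expect_true(all(refineRegion(m, 2)[m]))
  }
})

test_that("nucleus acceptance applies the size and circularity boundaries strictly", {
  # solid disk of ~120k px: accepted, circularity in the expected disk range
  d <- diskMask(196, 405)
  expect_gte(sum(d), 100000)
  expect_true(acceptNucleus(d))
  expect_gt(regionCircularity(d), 0.85)
  expect_lt(regionCircularity(d), 1.05)
  # same shape, area below 100000 -> rejected regardless of circularity
  d2 <- diskMask(126, 260)                      # ~49.9k px
  expect_lt(sum(d2), 50500)
  expect_false(acceptNucleus(d2))
  # exact boundary: area == minPx accepted, one pixel fewer rejected
  sq <- matrix(TRUE, 400, 250)                   # exactly 100000 px
  big <- matrix(FALSE, 402, 252); big[2:401, 2:251] <- sq
  expect_true(acceptNucleus(big))
  big[2, 2] <- FALSE                             # 99999 px
  expect_false(acceptNucleus(big))
  # a 1 x 200000 line: area passes, circularity ~1.6e-5 fails
  line <- matrix(FALSE, 3, 200002); line[2, 2:200001] <- TRUE
  expect_false(acceptNucleus(line))
  expect_lt(regionCircularity(line), 0.4)
})

test_that("acceptance is monotone under scaling at fixed shape", {
  small <- diskMask(60, 130)
  large <- diskMask(200, 410)
  expect_false(acceptNucleus(small))    # fails only on area
  expect_gt(regionCircularity(small), 0.4)
  expect_true(acceptNucleus(large))
  expect_equal(regionCircularity(small), regionCircularity(large),
               tolerance = 0.02)
})

test_that("Sobel boundary matches hand-computed and oracle expectations", {
  # a single pixel lights up exactly its 8-neighbour ring
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  b <- extractBoundary(m)
  ring <- matrix(FALSE, 5, 5); ring[2:4, 2:4] <- TRUE; ring[3, 3] <- FALSE
  expect_identical(unname(b), unname(ring))
  # full-frame mask: boundary only at the frame border (zero padding)
  full <- matrix(TRUE, 6, 7)
  bf <- extractBoundary(full)
  expect_true(all(bf[c(1, 6), ]) && all(bf[, c(1, 7)]))
  expect_false(any(bf[2:5, 2:6]))
  # solid square: every region pixel adjacent to background is flagged,
  # and the in-mask boundary equals the inner-edge oracle
  sq <- matrix(FALSE, 12, 12); sq[4:9, 3:10] <- TRUE
  bs <- extractBoundary(sq)
  inner <- innerEdgeOracle(sq)
  expect_true(all(bs[inner]))
  expect_identical(unname(bs & sq), unname(inner))
})

test_that("in-mask Sobel boundary equals the inner-edge oracle on smooth blobs", {
  shapes <- list(diskMask(9, 25),
                 outer(1:30, 1:30, function(y, x)
                   ((y - 15) / 11)^2 + ((x - 16) / 6)^2 <= 1),
                 refineRegion(randomBlobMask(20, 4), 3))
  for (m in shapes)
    expect_identical(unname(extractBoundary(m) & m),
                     unname(innerEdgeOracle(m)))
})

test_that("stacking joins z-overlapping sections and separates disjoint ones", {
  mkSlide <- function(masks) list(regions = masks,
                                  boundaries = lapply(masks, extractBoundary))
  d <- diskMask(5, 24)
  # same disk on 12 slides -> one nucleus spanning 12 slides
  nuc <- stackNuclei(rep(list(mkSlide(list(d))), 12))
  expect_length(nuc, 1)
  expect_equal(sum(nuc[[1]]@perSlideAreas > 0), 12)
  # two disjoint disks per slide -> two nuclei
  d2 <- matrix(FALSE, 24, 48); d2[1:24, 1:24] <- d
  d3 <- matrix(FALSE, 24, 48); d3[1:24, 25:48] <- d
  nuc2 <- stackNuclei(rep(list(mkSlide(list(d2, d3))), 5))
  expect_length(nuc2, 2)
  # disk on slides 1-5, different corner disk on slides 8-12 -> two nuclei
  corner <- matrix(FALSE, 24, 24); corner[1:9, 1:9] <- diskMask(4, 9)
  empty <- list(regions = list(), boundaries = list())
  seq12 <- c(rep(list(mkSlide(list(d))), 5), rep(list(empty), 2),
             rep(list(mkSlide(list(corner))), 5))
  expect_length(stackNuclei(seq12), 2)
  expect_length(stackNuclei(list()), 0)
})

test_that("segmentation recovers the true synthetic nucleus (Jaccard >= 0.9)", {
  # field scaled so the 10-iteration dilation margin is small relative to the
  # nucleus, as in full-frame acquisitions; accuracy is judged on the real
  # (measured) slides, where the DAPI section is not a nearest-slide carryover
  sp <- defaultConditionSpecs()[["ED-like"]]
  g <- generateStack(sp, gridShape = c(10L, 768L, 768L), seed = 3)
  enh <- interpolateZ(g$stack)
  nuclei <- segmentNuclei(enh, minPx = 45000)
  expect_length(nuclei, 1)
  truthEnh <- truthNucleusMask(g$truth, dim(getChannel(enh, "DAPI")),
                               voxelSpacing(enh))
  m <- nucleusMask(nuclei[[1]])
  real <- which(slideFlags(enh) == "real")
  jac <- sum(m[real, , ] & truthEnh[real, , ]) /
    sum(m[real, , ] | truthEnh[real, , ])
  expect_gte(jac, 0.9)
})
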