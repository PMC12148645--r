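test_that("streamline length matches hand geometry and a brute-force oracle", {
  expect_identical(streamlineLength(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_identical(streamlineLength(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 2)
  expect_error(streamlineLength(matrix(1:3, 1)), "2 points")
  set.seed(8)
  for (rep in 1:5) {
    s <- randomStreamline(50)
    oracle <- sum(vapply(seq_len(49), function(i)
      sqrt(sum((s[i + 1, ] - s[i, ])^2)), numeric(1)))
    expect_equal(streamlineLength(s), oracle, tolerance = 1e-12)
  }
})

test_that("length filtering is inclusive at both bounds", {
  mk <- function(L) rbind(c(0, 0, 0), c(L, 0, 0))
  sl <- lapply(c(4.9, 5, 40, 40.1), mk)
  expect_identical(filterByLength(sl, 5, 40), c(2L, 3L))
  expect_identical(filterByLength(list(), 5, 40), integer(0))
  expect_error(filterByLength(sl, 40, 5), "exceed")
})

test_that("length filtering agrees with generator bookkeeping", {
  ph <- simulatePhantom(gridDims = c(30, 30, 30), nPathways = 2,
                        fibersPerBundle = 15, nDistractors = 10,
                        nOutliers = 0, lengthRange = c(3, 50), seed = 6)
  keep <- filterByLength(ph@tractogram, 5, 40)
  expect_identical(sort(keep), which(ph@lengths >= 5 & ph@lengths <= 40))
})

test_that("streamline assignment follows the nearest-voxel mask test", {
  grid <- VolumeGrid(c(20, 20, 20), voxelSize = 1)
  mask <- array(FALSE, c(20, 20, 20))
  mask[10, 10, 10] <- TRUE   # voxel index (9,9,9) 0-based
  ctr <- voxelToWorld(c(9, 9, 9), grid)
  ## a streamline with a vertex at the voxel center is assigned
  s1 <- rbind(ctr + c(-3, 0, 0), ctr, ctr + c(3, 0, 0))
  ## one displaced by > 1 voxel everywhere is not
  s2 <- s1 + 3
  tg <- Tractogram(list(s1, s2), grid)
  asg <- assignStreamlines(tg, list(A = mask))
  expect_identical(asg$A, 1L)
})

test_that("endpoint-only segments are caught after resampling", {
  ## 10-mm straight segment sampled only at its endpoints, crossing a
  ## one-voxel-thick slab midway: resampling must recover the crossing
  grid <- VolumeGrid(c(20, 20, 20), voxelSize = 1)
  slab <- array(FALSE, c(20, 20, 20))
  slab[, , 10] <- TRUE
  zSlab <- voxelToWorld(c(0, 0, 9), grid)[3]
  p <- voxelToWorld(c(9, 9, 9), grid) + c(0, 0, -5)
  q <- p + c(0, 0, 10)
  tg <- Tractogram(list(rbind(p, q)), grid)
  expect_identical(assignStreamlines(tg, list(S = slab))$S, 1L)
  expect_true(ddaHitsMask(rbind(p, q), grid, slab))
})

test_that("assignment matches the exact DDA intersection oracle on phantoms", {
  for (s in 1:6) {
    ph <- smallPhantom(seed = 200 + s)
    asg <- assignStreamlines(ph@tractogram, ph@lrMasks)
    for (p in names(ph@lrMasks)) {
      oracle <- which(vapply(streamlines(ph@tractogram), ddaHitsMask,
                             logical(1), ph@grid, ph@lrMasks[[p]]))
      expect_identical(sort(asg[[p]]), oracle)
    }
  }
})

test_that("assignment refuses masks on a mismatched grid", {
  ph <- smallPhantom(seed = 1)
  badMask <- array(TRUE, c(10, 10, 10))
  expect_error(assignStreamlines(ph@tractogram, list(B = badMask)),
               "dimensions")
})

test_that("MDF distance has its metric properties and matches the oracle", {
  set.seed(12)
  a <- randomStreamline(30)
  expect_equal(mdfDistance(a, a), 0, tolerance = 1e-12)
  shifted <- a + matrix(rep(c(1, 0, 0), each = 30), ncol = 3)
  expect_equal(mdfDistance(a, shifted), 1, tolerance = 1e-10)
  for (rep in 1:5) {
    b <- randomStreamline(17)
    expect_equal(mdfDistance(a, b), bruteMdf(a, b), tolerance = 1e-10)
    expect_equal(mdfDistance(a, b), mdfDistance(b, a), tolerance = 1e-12)
    ## flip invariance of the minimum
    expect_equal(mdfDistance(a, b[17:1, ]), mdfDistance(a, b),
                 tolerance = 1e-12)
  }
})

test_that("quickBundles clusters degenerate and separated inputs correctly", {
  a <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_length(quickBundles(list(a), 5), 1L)
  dup <- replicate(6, a, simplify = FALSE)
  cl <- quickBundles(dup, 5)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$members, 1:6)

  ## two parallel bundles 20 mm apart with ~1 mm internal spread
  set.seed(3)
  mk <- function(offset) lapply(1:8, function(i)
    rbind(c(0, offset + rnorm(1, sd = 0.3), 0),
          c(10, offset + rnorm(1, sd = 0.3), 0)))
  sl <- c(mk(0), mk(20))
  cl <- quickBundles(sl, 5)
  expect_length(cl, 2L)
  expect_identical(sort(cl[[1]]$members), 1:8)
  expect_identical(sort(cl[[2]]$members), 9:16)
  expect_error(quickBundles(sl, 0), "positive")
})

test_that("quickBundles cluster count does not increase with threshold", {
  ph <- smallPhantom(seed = 31, fibersPerBundle = 12)
  sl <- streamlines(ph@tractogram)
  counts <- vapply(c(1, 2, 4, 8, 16, 32), function(th)
    length(quickBundles(sl, th)), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("outlier rejection keeps coherent bundles and drops gross deviants", {
  a <- rbind(c(0, 0, 0), c(10, 0, 0))
  dup <- replicate(5, a, simplify = FALSE)
  expect_identical(removeOutliers(dup), 1:5)
  ## vacuous alpha keeps everything, even a wild outlier
  wild <- c(dup, list(a + 100))
  expect_identical(removeOutliers(wild, outlierAlpha = 0), 1:6)
  expect_error(removeOutliers(dup, thresholdLadder = numeric(0)), "empty")
  expect_error(removeOutliers(dup[1]), "at least 2")

  ## phantom truth: recall of injected outliers and retention of members
  recall <- retention <- c()
  for (s in 1:5) {
    ph <- simulatePhantom(seed = 400 + s)
    for (p in names(ph@lrMasks)) {
      mem <- which(vapply(ph@truthLabels, function(x) p %in% x, logical(1)))
      outs <- which(ph@outlierFlags & !is.na(ph@outlierOf) & ph@outlierOf == p)
      idx <- c(mem, outs)
      kept <- idx[removeOutliers(streamlines(ph@tractogram)[idx])]
      retention <- c(retention, mean(mem %in% kept))
      recall <- c(recall, mean(!(outs %in% kept)))
    }
  }
  expect_gte(mean(retention), 0.95)
  expect_gte(mean(recall), 0.9)
})

test_that("bundle occupancy marks exactly the traversed voxels", {
  grid <- VolumeGrid(c(20, 20, 20), voxelSize = 1)
  ## axis-aligned streamline through three voxel centers
  p0 <- voxelToWorld(c(5, 9, 9), grid)
  s <- rbind(p0, p0 + c(2, 0, 0))
  occ <- bundleOccupancy(list(s), grid)
  expect_identical(sum(occ), 3L)
  expect_true(all(occ[cbind(6:8, 10, 10)]))
  expect_identical(sum(bundleOccupancy(list(), grid)), 0L)

  ## phantom bundle equals the exact DDA voxel set
  ph <- smallPhantom(seed = 77, nOutliers = 0, nDistractors = 0)
  sl <- streamlines(ph@tractogram)
  occ <- bundleOccupancy(sl, ph@grid)
  oracle <- array(FALSE, ph@grid@dims)
  for (s in sl) {
    v <- ddaStreamlineVoxels(s, ph@grid)
    if (nrow(v)) oracle[v + 1L] <- TRUE
  }
  expect_identical(occ, oracle)
})

test_that("bundle means average the masked voxels and skip NaNs", {
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, 1, 1] <- TRUE
  cmap <- array(0.5, c(4, 4, 4))
  expect_identical(as.numeric(bundleMeanFeature(mask, cmap)), 0.5)
  vmap <- cmap; vmap[1, 1, 1] <- 0.2; vmap[2, 1, 1] <- 0.4
  expect_equal(as.numeric(bundleMeanFeature(mask, vmap)), 0.3)
  expect_error(bundleMeanFeature(array(FALSE, c(4, 4, 4)), cmap), "empty")
  nmap <- vmap; nmap[1, 1, 1] <- NaN
  expect_message(v <- bundleMeanFeature(mask, nmap), "1 NaN")
  expect_identical(attr(v, "nExcluded"), 1L)
  expect_equal(as.numeric(v), 0.4)
  ## random mask/map against an explicit loop
  set.seed(5)
  rmask <- array(runif(64) < 0.3, c(4, 4, 4))
  rmap <- array(rnorm(64), c(4, 4, 4))
  acc <- 0; nn <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    if (rmask[i, j, k]) { acc <- acc + rmap[i, j, k]; nn <- nn + 1 }
  expect_equal(as.numeric(bundleMeanFeature(rmask, rmap)), acc / nn,
               tolerance = 1e-12)
})

test_that("end-to-end classification recovers phantom truth exactly", {
  for (s in 1:3) {
    ph <- simulatePhantom(seed = 500 + s)
    asg <- assignStreamlines(ph@tractogram, ph@lrMasks)
    for (i in seq_along(ph@truthLabels)) {
      got <- names(asg)[vapply(asg, function(v) i %in% v, logical(1))]
      expect_true(setequal(got, ph@truthLabels[[i]]))
    }
  }
})
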