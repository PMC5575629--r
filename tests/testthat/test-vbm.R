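# Mask construction, Gaussian smoothing, voxelwise t-maps, cluster
# extraction, feature assembly.

test_that("the GM mask thresholds the voxelwise mean across subjects", {
  v1 <- GMVolume(array(0.05, c(4, 4, 4)), subjectID = "a")
  v2 <- GMVolume(array(0.25, c(4, 4, 4)), subjectID = "b")
  m <- makeGMMask(list(v1, v2), threshold = 0.1)   # mean 0.15 > 0.1
  expect_true(all(maskArray(m)))
  expect_false(any(maskArray(suppressWarnings(makeGMMask(list(v1))))))
})

test_that("an all-zero cohort yields an empty mask with a warning", {
  vols <- list(GMVolume(array(0, c(4, 4, 4)), subjectID = "z1"),
               GMVolume(array(0, c(4, 4, 4)), subjectID = "z2"))
  expect_warning(m <- makeGMMask(vols), "empty")
  expect_false(any(maskArray(m)))
})

test_that("the mask equals a brute-force per-voxel mean comparison", {
  set.seed(1)
  vols <- lapply(1:5, function(i)
    GMVolume(array(runif(6^3), c(6, 6, 6)), subjectID = paste0("s", i)))
  m <- makeGMMask(vols, threshold = 0.4)
  oracle <- array(FALSE, c(6, 6, 6))
  for (x in 1:6) for (y in 1:6) for (z in 1:6)
    oracle[x, y, z] <- mean(vapply(vols, function(v) v@data[x, y, z],
                                   numeric(1))) > 0.4
  expect_identical(maskArray(m), oracle)
})

test_that("shape mismatches are reported with the offending subject", {
  v1 <- GMVolume(array(0.5, c(4, 4, 4)), subjectID = "good")
  v2 <- GMVolume(array(0.5, c(4, 4, 5)), subjectID = "odd")
  expect_error(makeGMMask(list(v1, v2)), "odd")
})

test_that("smoothing uses sigma = FWHM / 2.3548 per axis and the stated kernel", {
  expect_equal(10 / morphoprop:::FWHM_TO_SIGMA, 4.24661, tolerance = 5e-6)
  # impulse response: values equal the separable Gaussian kernel
  fwhm <- 3; sigma <- fwhm / (2 * sqrt(2 * log(2)))
  shape <- c(15, 15, 15)
  imp <- array(0, shape); imp[8, 8, 8] <- 1
  sm <- volumeData(smoothGaussian(GMVolume(imp), fwhm = fwhm))
  r <- ceiling(4 * sigma)
  w <- exp(-(-r:r)^2 / (2 * sigma^2)); w <- w / sum(w)
  expected <- outer(outer(w, w), w)
  idx <- 8 + (-r:r)
  expect_equal(sm[idx, idx, idx], expected, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)  # kernel mass away from edges
})

test_that("constant volumes are invariant under smoothing and sums are approximately preserved", {
  const <- GMVolume(array(0.73, c(8, 8, 8)))
  expect_equal(volumeData(smoothGaussian(const, fwhm = 10)),
               volumeData(const), tolerance = 1e-12)
  set.seed(2)
  v <- GMVolume(array(runif(16^3), c(16, 16, 16)))
  sm <- smoothGaussian(v, fwhm = 4)
  # replicate padding: the total GM mass moves by well under 1%
  expect_lt(abs(sum(volumeData(sm)) - sum(volumeData(v))) / sum(volumeData(v)),
            0.01)
  expect_error(smoothGaussian(v, fwhm = 0), "fwhm")
})

test_that("the pooled-variance t statistic matches hand computation", {
  ad <- volumesWithVoxel(c(0.2, 0.3, 0.4))
  nc <- volumesWithVoxel(c(0.5, 0.6, 0.7))
  mask <- makeGMMask(c(ad, nc), threshold = 0.1)
  tm <- suppressMessages(voxelwiseTTest(ad, nc, mask))  # constant background
  expect_identical(tm@df, 4L)
  expect_equal(tm@t[2, 2, 2], -3.674, tolerance = 5e-4)
  # identical group means with nonzero variance -> t = 0
  tm0 <- voxelwiseTTest(volumesWithVoxel(c(0.2, 0.4)),
                        volumesWithVoxel(c(0.4, 0.2)), mask) |>
    suppressMessages()
  expect_equal(tm0@t[2, 2, 2], 0)
})

test_that("the full t-map equals a per-voxel t.test oracle and is antisymmetric", {
  set.seed(3)
  shape <- c(5, 4, 3)
  g1 <- lapply(1:4, function(i)
    GMVolume(array(runif(prod(shape), 0.2, 0.8), shape), subjectID = paste0("a", i)))
  g2 <- lapply(1:5, function(i)
    GMVolume(array(runif(prod(shape), 0.2, 0.8), shape), subjectID = paste0("b", i)))
  mask <- makeGMMask(c(g1, g2))
  tm <- voxelwiseTTest(g1, g2, mask)
  for (lin in sample(which(maskArray(mask)), 10)) {
    cc <- arrayInd(lin, shape)
    x1 <- vapply(g1, function(v) v@data[cc[1], cc[2], cc[3]], numeric(1))
    x2 <- vapply(g2, function(v) v@data[cc[1], cc[2], cc[3]], numeric(1))
    ref <- t.test(x1, x2, var.equal = TRUE)
    expect_equal(tm@t[lin], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tm@p[lin], ref$p.value, tolerance = 1e-10)
  }
  swapped <- voxelwiseTTest(g2, g1, mask)
  expect_equal(swapped@t, -tm@t)
  expect_equal(swapped@p, tm@p)
  # one-sided atrophy contrast: p = P(T <= t)
  less <- voxelwiseTTest(g1, g2, mask, tail = "less")
  expect_equal(less@p[which(maskArray(mask))[1]],
               pt(tm@t[which(maskArray(mask))[1]], 7))
})

test_that("cluster connectivity follows the 6/18/26 definitions", {
  p <- array(1, c(4, 4, 4))
  p[1, 1, 1] <- 0; p[2, 1, 1] <- 0           # face-adjacent pair
  cs <- extractClusters(tmapFromP(p), pThreshold = 0.05)
  expect_identical(nClusters(cs), 1L)
  expect_identical(nrow(cs@clusters[[1]]), 2L)
  p <- array(1, c(4, 4, 4))
  p[1, 1, 1] <- 0; p[2, 2, 1] <- 0           # edge-diagonal pair
  expect_identical(nClusters(extractClusters(tmapFromP(p), connectivity = 6)), 2L)
  expect_identical(nClusters(extractClusters(tmapFromP(p), connectivity = 18)), 1L)
  p <- array(1, c(4, 4, 4))
  p[1, 1, 1] <- 0; p[2, 2, 2] <- 0           # corner-diagonal pair
  expect_identical(nClusters(extractClusters(tmapFromP(p), connectivity = 18)), 2L)
  expect_identical(nClusters(extractClusters(tmapFromP(p), connectivity = 26)), 1L)
})

test_that("component labeling matches a BFS flood-fill oracle on random maps", {
  set.seed(4)
  for (i in 1:30) {
    conn <- c(6, 18, 26)[(i %% 3) + 1]
    d <- c(sample(4:8, 1), sample(4:8, 1), sample(4:8, 1))
    supra <- array(runif(prod(d)) < 0.35, d)
    p <- array(1, d); p[supra] <- 0.01
    cs <- extractClusters(tmapFromP(p), pThreshold = 0.05, connectivity = conn)
    expect_identical(partitionOf(clusterLabels(cs)),
                     partitionOf(bfsFloodFill(supra, conn)))
  }
})

test_that("the extent threshold discards small components and 0 keeps all", {
  p <- array(1, c(6, 4, 4))
  p[1:3, 1, 1] <- 0      # component of 3
  p[6, 4, 4] <- 0        # singleton
  cs0 <- extractClusters(tmapFromP(p), extentThreshold = 0)
  expect_identical(nClusters(cs0), 2L)
  cs1 <- extractClusters(tmapFromP(p), extentThreshold = 1)
  expect_identical(nClusters(cs1), 1L)
  expect_identical(nrow(cs1@clusters[[1]]), 3L)
  expect_warning(extractClusters(tmapFromP(array(1, c(4, 4, 4)))),
                 "suprathreshold")
})

test_that("feature assembly reads the stated voxels in lexicographic order", {
  p <- array(1, c(4, 4, 4))
  p[3, 1, 2] <- 0; p[2, 1, 2] <- 0; p[2, 2, 2] <- 0  # one 18-connected cluster
  cs <- extractClusters(tmapFromP(p), connectivity = 18)
  expect_identical(nClusters(cs), 1L)
  set.seed(5)
  vols <- lapply(1:2, function(i)
    GMVolume(array(runif(64), c(4, 4, 4)), subjectID = paste0("s", i)))
  fm <- assembleFeatures(vols, cs)
  expect_identical(dim(featureValues(fm)), c(2L, 3L))
  vi <- voxelIndex(fm)
  # column order = lexicographic sort of (cluster, x, y, z)
  key <- order(vi$cluster, vi$x, vi$y, vi$z)
  expect_identical(key, seq_len(nrow(vi)))
  expect_identical(vi$x, c(2L, 2L, 3L))
  expect_identical(vi$y, c(1L, 2L, 1L))
  for (j in seq_len(3))
    expect_identical(unname(featureValues(fm)[1, j]),
                     vols[[1]]@data[vi$x[j], vi$y[j], vi$z[j]])
  # permuting subjects permutes rows identically
  fm2 <- assembleFeatures(vols[2:1], cs)
  expect_identical(featureValues(fm2), featureValues(fm)[2:1, ])
})

test_that("noiseless single-region cohorts are recovered as a cluster around the region", {
  spec <- cohortSpec(nPerClass = 3, volumeShape = c(16, 16, 16),
                     atrophyRegions = list(list(center = c(8, 8, 8),
                                                radius = 3, effect = 0.3)),
                     noiseSD = 0, seed = 1)
  ch <- generateVolumeCohort(spec)
  smoothed <- lapply(ch$volumes, smoothGaussian, fwhm = 2)
  mask <- makeGMMask(smoothed)
  tm <- suppressMessages(
    voxelwiseTTest(smoothed[ch$labels == "AD"], smoothed[ch$labels == "NC"], mask))
  cs <- extractClusters(tm, pThreshold = 0.05)
  region <- which(morphoprop:::sphereMask(c(16, 16, 16), c(8, 8, 8), 3))
  detected <- which(clusterLabels(cs) > 0)
  expect_true(all(region %in% detected))
  # nothing beyond the smoothing halo: the truncated kernel reaches at
  # most 4 voxels per axis, so detected voxels stay within Chebyshev
  # distance region radius + 4 of the center
  cc <- arrayInd(detected, c(16, 16, 16))
  cheb <- apply(abs(cc - matrix(8, nrow(cc), 3, byrow = TRUE)), 1, max)
  expect_lte(max(cheb), 3 + 4)
})
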