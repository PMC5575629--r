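# VBM-style feature extraction: group GM mask, isotropic Gaussian
# smoothing, voxelwise pooled-variance t-maps, suprathreshold cluster
# extraction, and assembly of per-subject feature vectors.

FWHM_TO_SIGMA <- 2 * sqrt(2 * log(2))  # FWHM = 2.354820 * sigma

#' Group gray-matter mask
#'
#' The voxelwise mean GM probability across all subjects is thresholded:
#' a voxel enters the mask when the mean exceeds `threshold` (default
#' 0.1, the conventional GM inclusion cut-off).
#'
#' @param volumes list of [GMVolume-class] with consistent shapes.
#' @param threshold mean-probability cut-off.
#' @return A [GMMask-class].
#' @examples
#' v1 <- GMVolume(array(0.05, c(4, 4, 4))); v2 <- GMVolume(array(0.25, c(4, 4, 4)))
#' sum(maskArray(makeGMMask(list(v1, v2))))  # mean 0.15 > 0.1 everywhere
#' @export
makeGMMask <- function(volumes, threshold = 0.1) {
  checkScalar(threshold, "threshold")
  m <- cohortMatrix(volumes)
  avg <- rowMeans(m)
  mask <- array(avg > threshold, dim = attr(m, "volDim"))
  if (!any(mask)) warning("GM mask is empty at threshold ", threshold)
  new("GMMask", mask = mask, threshold = threshold)
}

# Banded 1-D convolution operator with replicate (nearest-neighbor)
# boundary padding: out[i] = sum_off w[off] * in[clamp(i + off, 1, n)].
# Rows sum to 1 exactly, so constant signals are invariant.
gaussianAxisOperator <- function(n, sigmaVox) {
  if (sigmaVox < 1e-8) return(diag(n))
  r <- max(1L, ceiling(4 * sigmaVox))
  off <- seq.int(-r, r)
  w <- exp(-off^2 / (2 * sigmaVox^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (j in seq_along(off)) {
    src <- pmin(pmax(seq_len(n) + off[j], 1L), n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + w[j]
  }
  K
}

#' Isotropic Gaussian smoothing of a GM volume
#'
#' Separable convolution with a Gaussian kernel whose per-axis standard
#' deviation in voxels is `(fwhm / voxelSize) / (2 sqrt(2 ln 2))`.
#' Boundaries use replicate padding, so constant volumes pass through
#' unchanged and the volume-wide sum is approximately preserved.
#'
#' @param volume a [GMVolume-class].
#' @param fwhm full width at half maximum in mm (default 10).
#' @return A smoothed [GMVolume-class] of the same shape.
#' @examples
#' v <- GMVolume(array(runif(8^3), c(8, 8, 8)))
#' s <- smoothGaussian(v, fwhm = 4)
#' @export
smoothGaussian <- function(volume, fwhm = 10) {
  stopIfNot(is(volume, "GMVolume"), "'volume' must be a GMVolume")
  checkScalar(fwhm, "fwhm", positive = TRUE)
  a <- volume@data
  d <- dim(a)
  sig <- (fwhm / volume@voxelSize) / FWHM_TO_SIGMA
  K1 <- gaussianAxisOperator(d[1], sig[1])
  K2 <- gaussianAxisOperator(d[2], sig[2])
  K3 <- gaussianAxisOperator(d[3], sig[3])
  a <- array(K1 %*% matrix(a, d[1], d[2] * d[3]), d)          # x axis
  a <- aperm(array(K2 %*% matrix(aperm(a, c(2, 1, 3)), d[2], d[1] * d[3]),
                   c(d[2], d[1], d[3])), c(2, 1, 3))          # y axis
  a <- array(matrix(a, d[1] * d[2], d[3]) %*% t(K3), d)       # z axis
  GMVolume(a, voxelSize = volume@voxelSize, subjectID = volume@subjectID)
}

#' Voxelwise two-sample t-test
#'
#' Pooled-variance two-sample t statistic per in-mask voxel, first group
#' (patients) versus second group (controls), with df = n1 + n2 - 2.
#' The default p-value is two-sided; `tail = "less"` tests the atrophy
#' contrast (first group mean below the second). A voxel with zero
#' pooled variance and zero mean difference gets t = 0, p = 1; zero
#' pooled variance with a nonzero difference (possible only in noiseless
#' synthetic data) gives t = +-Inf, p = 0. Both kinds are counted in
#' `nDegenerate` and reported via a message.
#'
#' @param groupAD,groupNC lists of smoothed [GMVolume-class] (>= 2 each).
#' @param mask a [GMMask-class].
#' @param tail `"two.sided"` (default) or `"less"`.
#' @return A [TMap-class].
#' @export
voxelwiseTTest <- function(groupAD, groupNC, mask,
                           tail = c("two.sided", "less")) {
  tail <- match.arg(tail)
  stopIfNot(is(mask, "GMMask"), "'mask' must be a GMMask")
  stopIfNot(length(groupAD) >= 2L && length(groupNC) >= 2L,
            "each group needs at least 2 subjects")
  m1 <- cohortMatrix(groupAD)
  m2 <- cohortMatrix(groupNC)
  stopIfNot(identical(attr(m1, "volDim"), attr(m2, "volDim")),
            "groups have inconsistent volume dimensions")
  d <- attr(m1, "volDim")
  stopIfNot(identical(dim(mask@mask), d), "mask shape does not match volumes")
  keep <- as.vector(mask@mask)
  n1 <- ncol(m1); n2 <- ncol(m2)
  x1 <- m1[keep, , drop = FALSE]; x2 <- m2[keep, , drop = FALSE]
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - mu1)^2); ss2 <- rowSums((x2 - mu2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- mu1 - mu2
  tv <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  nDeg <- sum(se == 0)
  if (nDeg > 0)
    message(nDeg, " in-mask voxel(s) had zero pooled variance")
  pv <- if (tail == "two.sided") 2 * stats::pt(-abs(tv), df)
        else stats::pt(tv, df)
  tArr <- array(NA_real_, d); pArr <- array(NA_real_, d)
  tArr[keep] <- tv; pArr[keep] <- pv
  new("TMap", t = tArr, p = pArr, df = as.integer(df), tail = tail,
      nDegenerate = as.integer(nDeg))
}

# Neighbor offsets for 6/18/26-connectivity in 3-D.
connectivityOffsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1,
                 stop("'connectivity' must be 6, 18 or 26", call. = FALSE))
  off[keep, , drop = FALSE]
}

#' Extract suprathreshold clusters from a t-map
#'
#' Voxels with p < `pThreshold` are grouped into connected components
#' under the chosen connectivity; components with at most
#' `extentThreshold` voxels are discarded (the default 0 keeps every
#' component, i.e. a zero-adjacent-voxel extent cut). Cluster ids are
#' assigned in lexicographic order of each component's smallest voxel,
#' making the labeling independent of voxel visiting order.
#'
#' @param tmap a [TMap-class].
#' @param pThreshold p-value cut-off in (0, 1) (default 0.05, uncorrected).
#' @param extentThreshold minimum component size minus one.
#' @param connectivity 6 (face), 18 (face+edge) or 26 (full) adjacency.
#' @return A [ClusterMaskSet-class]; empty (with a warning) when no
#'   voxel survives the threshold.
#' @export
extractClusters <- function(tmap, pThreshold = 0.05, extentThreshold = 0L,
                            connectivity = 6L) {
  stopIfNot(is(tmap, "TMap"), "'tmap' must be a TMap")
  stopIfNot(pThreshold > 0 && pThreshold < 1, "'pThreshold' must be in (0, 1)")
  stopIfNot(extentThreshold >= 0, "'extentThreshold' must be >= 0")
  connectivity <- as.integer(connectivity)
  d <- dim(tmap@p)
  supra <- which(!is.na(tmap@p) & tmap@p < pThreshold)
  lab <- array(0L, d)
  if (length(supra) == 0L) {
    warning("no suprathreshold voxels at p < ", pThreshold)
    return(new("ClusterMaskSet", labels = lab, clusters = list(),
               connectivity = connectivity))
  }
  comp <- labelComponents(supra, d, connectivity)
  # order clusters by their lexicographically smallest voxel; drop small ones
  coords <- arrayInd(supra, d)
  clusters <- list()
  for (cid in seq_len(max(comp))) {
    idx <- which(comp == cid)
    if (length(idx) <= extentThreshold) next
    cc <- coords[idx, , drop = FALSE]
    ord <- order(cc[, 1], cc[, 2], cc[, 3])
    clusters[[length(clusters) + 1L]] <- cc[ord, , drop = FALSE]
  }
  if (length(clusters) > 0L) {
    firstVox <- t(vapply(clusters, function(cc) cc[1, ], numeric(3)))
    ord <- order(firstVox[, 1], firstVox[, 2], firstVox[, 3])
    clusters <- clusters[ord]
    for (k in seq_along(clusters))
      lab[clusters[[k]]] <- k
  }
  new("ClusterMaskSet", labels = lab, clusters = clusters,
      connectivity = connectivity)
}

# Connected components of the given linear voxel indices via the voxel
# adjacency graph. Returns a component id per input index.
labelComponents <- function(linIdx, volDim, connectivity) {
  pos <- integer(prod(volDim))
  pos[linIdx] <- seq_along(linIdx)
  coords <- arrayInd(linIdx, volDim)
  offs <- connectivityOffsets(connectivity)
  # keep one of each +-pair to avoid duplicate edges
  offs <- offs[offs[, 1] * 9 + offs[, 2] * 3 + offs[, 3] > 0, , drop = FALSE]
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= volDim[1] &
          nb[, 2] >= 1 & nb[, 2] <= volDim[2] &
          nb[, 3] >= 1 & nb[, 3] <= volDim[3]
    if (!any(ok)) next
    nbLin <- nb[ok, 1] + (nb[ok, 2] - 1L) * volDim[1] +
             (nb[ok, 3] - 1L) * volDim[1] * volDim[2]
    hit <- pos[nbLin] > 0L
    if (!any(hit)) next
    edges <- c(edges, rbind(which(ok)[hit], pos[nbLin[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(linIdx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

#' Assemble per-subject feature vectors from cluster masks
#'
#' Reads each subject's GM value at every cluster voxel. Columns are
#' ordered by cluster id ascending, then voxel coordinate lexicographic
#' ascending (x, then y, then z), matching the cluster ordering
#' contract; by convention the values come from the unsmoothed
#' segmentation volumes.
#'
#' @param volumes list of [GMVolume-class] sharing the cluster grid.
#' @param clusters a nonempty [ClusterMaskSet-class].
#' @return A [FeatureMatrix-class] with one row per subject and a
#'   `voxelIndex` recording (cluster, x, y, z) per column (1-based).
#' @export
assembleFeatures <- function(volumes, clusters) {
  stopIfNot(is(clusters, "ClusterMaskSet"), "'clusters' must be a ClusterMaskSet")
  stopIfNot(length(clusters@clusters) >= 1L, "cluster set is empty")
  m <- cohortMatrix(volumes)
  d <- attr(m, "volDim")
  stopIfNot(identical(d, dim(clusters@labels)),
            "volumes do not share the cluster grid")
  vox <- do.call(rbind, clusters@clusters)
  cid <- rep(seq_along(clusters@clusters),
             vapply(clusters@clusters, nrow, integer(1)))
  lin <- vox[, 1] + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2]
  values <- t(m[lin, , drop = FALSE])
  FeatureMatrix(values,
                subjectIDs = vapply(volumes, function(v) v@subjectID, character(1)),
                voxelIndex = data.frame(cluster = cid, x = vox[, 1],
                                        y = vox[, 2], z = vox[, 3]))
}
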