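# Synthetic cohorts: GM probability volumes with localized atrophy, and
# low-dimensional two-class feature clouds for propagation-only tests.

#' Specification of a synthetic two-class volume cohort
#'
#' Describes a cohort of gray-matter probability volumes with known
#' ground truth: class "NC" subjects are a smooth ellipsoidal brain
#' template plus voxelwise Gaussian noise; class "AD" subjects
#' additionally have GM probability reduced by a fixed effect inside
#' designated spherical atrophy regions. All voxel values are clipped to
#' \[0, 1\] after noise.
#'
#' @slot nPerClass positive integer, subjects per class.
#' @slot volumeShape integer triple of voxel counts.
#' @slot voxelSize positive numeric triple (mm).
#' @slot atrophyRegions list of `list(center =, radius =, effect =)`;
#'   centers in voxels (1-based), radius in voxels, effect in GM
#'   probability units.
#' @slot noiseSD nonnegative per-voxel noise standard deviation.
#' @slot seed integer master seed; identical seeds give bit-identical
#'   cohorts, and per-subject substreams mean enlarging the cohort never
#'   changes earlier subjects.
#' @export
setClass("CohortSpec",
  representation(nPerClass = "integer", volumeShape = "integer",
                 voxelSize = "numeric", atrophyRegions = "list",
                 noiseSD = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nPerClass < 1L) return("'nPerClass' must be a positive integer")
  if (length(object@volumeShape) != 3L || any(object@volumeShape < 4L))
    return("'volumeShape' must be a triple of voxel counts >= 4")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("'voxelSize' must be a positive triple")
  if (object@noiseSD < 0) return("'noiseSD' must be nonnegative")
  for (i in seq_along(object@atrophyRegions)) {
    r <- object@atrophyRegions[[i]]
    if (!all(c("center", "radius", "effect") %in% names(r)))
      return(sprintf("atrophyRegions[[%d]] needs 'center', 'radius', 'effect'", i))
    if (length(r$center) != 3L ||
        any(r$center < 1) || any(r$center > object@volumeShape))
      return(sprintf("atrophyRegions[[%d]]$center lies outside 'volumeShape'", i))
    if (r$radius <= 0)
      return(sprintf("atrophyRegions[[%d]]$radius must be positive", i))
    if (r$effect < 0 || r$effect > 1)
      return(sprintf("atrophyRegions[[%d]]$effect must be in [0, 1]", i))
  }
  TRUE
})

#' Construct a CohortSpec
#'
#' @param nPerClass subjects per class (the reference design is 49 + 49).
#' @param volumeShape voxel counts per axis.
#' @param voxelSize voxel edge lengths in mm.
#' @param atrophyRegions list of `list(center, radius, effect)` spheres.
#' @param noiseSD additive i.i.d. Gaussian noise SD per voxel.
#' @param seed master seed.
#' @return A [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(nPerClass = 5, volumeShape = c(16, 16, 16),
#'                    atrophyRegions = list(list(center = c(8, 8, 8),
#'                                               radius = 3, effect = 0.25)))
#' @export
cohortSpec <- function(nPerClass = 49L, volumeShape = c(32L, 32L, 32L),
                       voxelSize = c(1, 1, 1),
                       atrophyRegions = list(), noiseSD = 0.05, seed = 1L) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("CohortSpec", nPerClass = as.integer(nPerClass),
      volumeShape = as.integer(volumeShape), voxelSize = as.numeric(voxelSize),
      atrophyRegions = atrophyRegions, noiseSD = as.numeric(noiseSD),
      seed = as.integer(seed))
}

#' Specification of a synthetic two-class feature cloud
#'
#' Low-dimensional stand-in for reduced VBM feature vectors: either two
#' isotropic Gaussian blobs with centers `separation` apart along the
#' first axis, or the standard interleaved two-moons pattern embedded in
#' the first two of `dimension` axes (remaining axes pure noise;
#' `separation` is ignored for moons).
#'
#' @slot nPerClass positive integer per class.
#' @slot dimension positive integer feature dimension.
#' @slot geometry `"gaussian_blobs"` or `"two_moons"`.
#' @slot separation center distance for blobs.
#' @slot noiseSD nonnegative noise standard deviation.
#' @slot seed integer master seed.
#' @export
setClass("FeatureCloudSpec",
  representation(nPerClass = "integer", dimension = "integer",
                 geometry = "character", separation = "numeric",
                 noiseSD = "numeric", seed = "integer"))

setValidity("FeatureCloudSpec", function(object) {
  if (object@nPerClass < 1L) return("'nPerClass' must be positive")
  if (object@dimension < 1L) return("'dimension' must be positive")
  if (!object@geometry %in% c("gaussian_blobs", "two_moons"))
    return("'geometry' must be 'gaussian_blobs' or 'two_moons'")
  if (object@geometry == "two_moons" && object@dimension < 2L)
    return("'dimension' must be >= 2 for two_moons")
  if (object@noiseSD < 0) return("'noiseSD' must be nonnegative")
  TRUE
})

#' Construct a FeatureCloudSpec
#'
#' @param nPerClass,dimension,geometry,separation,noiseSD,seed see
#'   [FeatureCloudSpec-class].
#' @return A [FeatureCloudSpec-class].
#' @export
featureCloudSpec <- function(nPerClass = 25L, dimension = 2L,
                             geometry = c("gaussian_blobs", "two_moons"),
                             separation = 3, noiseSD = 0.5, seed = 1L) {
  geometry <- match.arg(geometry)
  new("FeatureCloudSpec", nPerClass = as.integer(nPerClass),
      dimension = as.integer(dimension), geometry = geometry,
      separation = as.numeric(separation), noiseSD = as.numeric(noiseSD),
      seed = as.integer(seed))
}

# Smooth ellipsoidal brain template: 0.8 inside an ellipsoid at 80% of
# the field of view, 0 outside, softened by one Gaussian smoothing pass
# (FWHM of two voxel widths) so the 0.1 mask threshold has a soft edge
# to act on.
brainTemplate <- function(shape, voxelSize) {
  ctr <- (shape + 1) / 2
  semi <- 0.4 * shape
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  r2 <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
        ((g$z - ctr[3]) / semi[3])^2
  tmpl <- array(ifelse(r2 <= 1, 0.8, 0), dim = shape)
  vol <- GMVolume(tmpl, voxelSize = voxelSize, subjectID = "template")
  smoothGaussian(vol, fwhm = 2 * min(voxelSize))@data
}

sphereMask <- function(shape, center, radius) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, dim = shape)
}

#' Generate a synthetic two-class GM volume cohort
#'
#' Class "NC" subjects are the template plus noise; class "AD" subjects
#' additionally have GM reduced by each region's effect inside that
#' region, before noise. Values are clipped to \[0, 1\]. Subjects are
#' returned NC block first, then AD, with labels in the same order.
#'
#' @param spec a [CohortSpec-class].
#' @return A list with `volumes` (list of [GMVolume-class]) and `labels`
#'   (character vector, `"NC"`/`"AD"`).
#' @examples
#' ch <- generateVolumeCohort(cohortSpec(nPerClass = 3,
#'     volumeShape = c(12, 12, 12),
#'     atrophyRegions = list(list(center = c(6, 6, 6), radius = 2,
#'                                effect = 0.3))))
#' table(ch$labels)
#' @export
generateVolumeCohort <- function(spec) {
  stopIfNot(is(spec, "CohortSpec"), "'spec' must be a CohortSpec")
  validObject(spec)
  shape <- spec@volumeShape
  tmpl <- brainTemplate(shape, spec@voxelSize)
  atrophied <- tmpl
  for (r in spec@atrophyRegions)
    atrophied[sphereMask(shape, r$center, r$radius)] <-
      atrophied[sphereMask(shape, r$center, r$radius)] - r$effect
  makeSubject <- function(base, classIdx, i) {
    id <- sprintf("%s%03d", c("NC", "AD")[classIdx], i)
    vals <- base
    if (spec@noiseSD > 0)
      vals <- vals + withSeed(deriveSeed(spec@seed, classIdx * 1000000L + i),
                              array(stats::rnorm(length(base), sd = spec@noiseSD),
                                    dim = shape))
    GMVolume(pmin(pmax(vals, 0), 1), voxelSize = spec@voxelSize, subjectID = id)
  }
  vols <- c(lapply(seq_len(spec@nPerClass), function(i) makeSubject(tmpl, 1L, i)),
            lapply(seq_len(spec@nPerClass), function(i) makeSubject(atrophied, 2L, i)))
  list(volumes = vols,
       labels = rep(c("NC", "AD"), each = spec@nPerClass))
}

#' Generate a synthetic two-class feature cloud
#'
#' @param spec a [FeatureCloudSpec-class].
#' @return A list with `features` (a [FeatureMatrix-class],
#'   `2 * nPerClass` rows) and `labels` (character, `"A"`/`"B"`).
#' @examples
#' fc <- generateFeatureCloud(featureCloudSpec(nPerClass = 10, separation = 4))
#' dim(featureValues(fc$features))
#' @export
generateFeatureCloud <- function(spec) {
  stopIfNot(is(spec, "FeatureCloudSpec"), "'spec' must be a FeatureCloudSpec")
  validObject(spec)
  n <- spec@nPerClass
  d <- spec@dimension
  X <- withSeed(deriveSeed(spec@seed, 1L), {
    if (spec@geometry == "gaussian_blobs") {
      centers <- rbind(c(-spec@separation / 2, rep(0, d - 1)),
                       c(+spec@separation / 2, rep(0, d - 1)))
      pts <- matrix(stats::rnorm(2 * n * d, sd = spec@noiseSD), ncol = d)
      pts + centers[rep(1:2, each = n), , drop = FALSE]
    } else {
      t1 <- stats::runif(n, 0, pi)
      t2 <- stats::runif(n, 0, pi)
      xy <- rbind(cbind(cos(t1), sin(t1)),
                  cbind(1 - cos(t2), 0.5 - sin(t2)))
      pts <- matrix(0, 2 * n, d)
      pts[, 1:2] <- xy
      pts + matrix(stats::rnorm(2 * n * d, sd = spec@noiseSD), ncol = d)
    }
  })
  labels <- rep(c("A", "B"), each = n)
  ids <- sprintf("%s%03d", labels, c(seq_len(n), seq_len(n)))
  list(features = FeatureMatrix(X, subjectIDs = ids), labels = labels)
}

#' Write a volume cohort to disk
#'
#' One NIfTI file per subject plus a `labels.csv` (subject_id,label).
#'
#' @param cohort result of [generateVolumeCohort()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeVolumeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cohort$volumes, function(v) {
    p <- file.path(dir, paste0(v@subjectID, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(v@data, pixdim = v@voxelSize), p)
    p
  }, character(1))
  labcsv <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(subject_id = vapply(cohort$volumes,
                                                  function(v) v@subjectID,
                                                  character(1)),
                              label = cohort$labels),
                   labcsv, row.names = FALSE, quote = FALSE)
  invisible(c(paths, labcsv))
}

#' Read a volume cohort from disk
#'
#' Reads every `.nii`/`.nii.gz` under `dir` and, if present, the
#' `labels.csv` sidecar.
#'
#' @param dir directory written by [writeVolumeCohort()] (or compatible).
#' @return A list with `volumes` and `labels` (NULL when no sidecar).
#' @export
readVolumeCohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  stopIfNot(length(files) >= 1L, sprintf("no NIfTI files found under '%s'", dir))
  vols <- lapply(files, function(f) {
    img <- RNifti::readNifti(f)
    GMVolume(array(as.numeric(img), dim = dim(img)),
             voxelSize = RNifti::pixdim(img)[1:3],
             subjectID = sub("\\.nii(\\.gz)?$", "", basename(f)))
  })
  labels <- NULL
  labcsv <- file.path(dir, "labels.csv")
  if (file.exists(labcsv)) {
    lab <- utils::read.csv(labcsv, stringsAsFactors = FALSE)
    labels <- lab$label[match(vapply(vols, function(v) v@subjectID, character(1)),
                              lab$subject_id)]
  }
  list(volumes = vols, labels = labels)
}
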