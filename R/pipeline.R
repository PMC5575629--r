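# End-to-end orchestration: volumes -> smoothing -> mask -> t-map ->
# clusters -> features -> PCA -> sigma cross-validation -> repeated
# random-split evaluation.

#' Run the full volume-to-metrics pipeline
#'
#' Applies the complete analysis to a registered GM cohort with known
#' diagnoses: isotropic smoothing, group mask, voxelwise two-sample
#' t-map, suprathreshold cluster extraction, feature assembly from the
#' unsmoothed volumes, PCA with cumulative-energy dimension selection,
#' kernel-bandwidth cross-validation, and repeated random-split
#' evaluation of label propagation.
#'
#' By default the t-map uses every subject's diagnosis (the protocol of
#' the reference experiment, which is transductive but lets test labels
#' influence feature selection); pass `tTestSubjects` to restrict the
#' group contrast to a training subset and avoid that leakage.
#'
#' @param volumes list of registered [GMVolume-class] objects.
#' @param labels diagnosis per subject (two classes).
#' @param fwhm smoothing kernel FWHM in mm (default 10).
#' @param maskThreshold GM mask cut-off on the mean volume (default 0.1).
#' @param pThreshold uncorrected voxelwise p cut-off (default 0.05).
#' @param extentThreshold minimum cluster extent minus one (default 0).
#' @param connectivity3D cluster connectivity, 6/18/26 (default 6).
#' @param tail t-test tail, `"two.sided"` (default) or `"less"`.
#' @param energy PCA cumulative-energy level (default 0.99).
#' @param sigmaGrid candidate bandwidths for cross-validation.
#' @param trainSize,nRuns evaluation protocol (defaults 25 and 40).
#' @param seed master seed driving the CV pool and all split draws.
#' @param positiveClass diseased label (default `"AD"`).
#' @param tTestSubjects optional integer indices of the subjects whose
#'   diagnoses define the t-test groups (default: all).
#' @param sigma fixed bandwidth; skips cross-validation when given.
#' @return A list with all intermediate objects: `mask`, `tmap`,
#'   `clusters`, `features`, `pca`, `dim`, `reduced`, `cv`, `sigma`,
#'   `evaluation`.
#' @export
runVolumePipeline <- function(volumes, labels, fwhm = 10, maskThreshold = 0.1,
                              pThreshold = 0.05, extentThreshold = 0L,
                              connectivity3D = 6L, tail = "two.sided",
                              energy = 0.99, sigmaGrid = c(0.05, 0.1, 0.25, 0.5, 1, 2, 5),
                              trainSize = 25L, nRuns = 40L, seed = 1L,
                              positiveClass = "AD", tTestSubjects = NULL,
                              sigma = NULL) {
  labels <- as.character(labels)
  stopIfNot(length(labels) == length(volumes), "one label per volume required")
  classes <- sort(unique(labels))
  stopIfNot(length(classes) == 2L, "exactly two classes required")
  smoothed <- lapply(volumes, smoothGaussian, fwhm = fwhm)
  mask <- makeGMMask(smoothed, threshold = maskThreshold)
  sub <- if (is.null(tTestSubjects)) seq_along(volumes) else as.integer(tTestSubjects)
  grpPos <- smoothed[sub[labels[sub] == positiveClass]]
  grpNeg <- smoothed[sub[labels[sub] != positiveClass]]
  tmap <- voxelwiseTTest(grpPos, grpNeg, mask, tail = tail)
  clusters <- extractClusters(tmap, pThreshold = pThreshold,
                              extentThreshold = extentThreshold,
                              connectivity = connectivity3D)
  stopIfNot(nClusters(clusters) >= 1L,
            "no clusters survived thresholding: no features to extract")
  features <- assembleFeatures(volumes, clusters)
  pca <- fitPCA(features)
  d <- selectDimension(pca, energy = energy)
  reduced <- pcaTransform(pca, features, d = d)
  cv <- NULL
  if (is.null(sigma)) {
    cv <- crossValidateSigma(reduced, labels, sigmaGrid = sigmaGrid,
                             seed = seed)
    sigma <- cv$bestSigma
  }
  evaluation <- repeatedSplitEvaluation(reduced, labels, sigma = sigma,
                                        trainSize = trainSize, nRuns = nRuns,
                                        seed = seed,
                                        positiveClass = positiveClass)
  list(mask = mask, tmap = tmap, clusters = clusters, features = features,
       pca = pca, dim = d, reduced = reduced, cv = cv, sigma = sigma,
       evaluation = evaluation)
}

#' Write a feature matrix as CSV with a JSON sidecar
#'
#' The CSV has a `subject_id` column followed by one column per
#' feature; the sidecar records extraction parameters and the voxel
#' index map so a feature file is self-describing.
#'
#' @param features a [FeatureMatrix-class].
#' @param path output CSV path (`.json` sidecar written alongside).
#' @param params named list of extraction parameters to record.
#' @return Invisibly, the CSV path.
#' @export
writeFeatureCSV <- function(features, path, params = list()) {
  df <- data.frame(subject_id = features@subjectIDs,
                   as.data.frame(features@values, row.names = NULL),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(params = params, voxel_index = features@voxelIndex),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV written by [writeFeatureCSV()] (first column
#'   `subject_id`).
#' @return A [FeatureMatrix-class].
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  FeatureMatrix(as.matrix(df[, -1, drop = FALSE]),
                subjectIDs = as.character(df[[1]]))
}
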