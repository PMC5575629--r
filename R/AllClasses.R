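#' @import methods
NULL

#' Gray-matter probability volume
#'
#' A 3-D scalar field of gray-matter probability/density for one subject,
#' with voxel size metadata. Values are unitless probabilities in \[0, 1\].
#' Volumes are assumed spatially registered: within a cohort all volumes
#' must share the same array dimensions and voxel size.
#'
#' @slot data 3-D numeric array of GM probability.
#' @slot voxelSize positive numeric triple, voxel edge lengths in mm.
#' @slot subjectID character scalar identifying the subject.
#' @export
setClass("GMVolume",
  representation(data = "array", voxelSize = "numeric", subjectID = "character"))

setValidity("GMVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("'data' must be a 3-D array")
  if (!all(is.finite(object@data)))
    return("'data' contains non-finite values")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("'voxelSize' must be a positive numeric triple")
  if (length(object@subjectID) != 1L)
    return("'subjectID' must be a single string")
  TRUE
})

#' Construct a GMVolume
#'
#' @param data 3-D numeric array of GM probabilities.
#' @param voxelSize voxel edge lengths in mm (length-1 value recycled to 3).
#' @param subjectID subject identifier.
#' @return A [GMVolume-class] object.
#' @examples
#' v <- GMVolume(array(0.5, c(4, 4, 4)), voxelSize = 1, subjectID = "s1")
#' @export
GMVolume <- function(data, voxelSize = c(1, 1, 1), subjectID = "subject") {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("GMVolume", data = data, voxelSize = as.numeric(voxelSize),
      subjectID = as.character(subjectID))
}

#' Binary gray-matter analysis mask
#'
#' Marks voxels retained for voxelwise statistics: those whose mean GM
#' probability across the cohort exceeds `threshold` (default 0.1).
#'
#' @slot mask 3-D logical array.
#' @slot threshold numeric scalar used to build the mask.
#' @export
setClass("GMMask", representation(mask = "array", threshold = "numeric"))

setValidity("GMMask", function(object) {
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    return("'mask' must be a 3-D logical array")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    return("'threshold' must be a finite scalar")
  TRUE
})

#' Voxelwise two-sample t-map
#'
#' Pooled-variance two-sample t statistics and p-values per in-mask voxel.
#' Out-of-mask voxels are `NA` and excluded downstream.
#'
#' @slot t 3-D numeric array of t statistics (`NA` outside the mask).
#' @slot p 3-D numeric array of p-values in \[0, 1\] (`NA` outside the mask).
#' @slot df integer degrees of freedom (n1 + n2 - 2).
#' @slot tail character, `"two.sided"` or `"less"` (first group < second).
#' @slot nDegenerate integer count of in-mask voxels with zero pooled variance.
#' @export
setClass("TMap",
  representation(t = "array", p = "array", df = "integer", tail = "character",
                 nDegenerate = "integer"))

setValidity("TMap", function(object) {
  if (!identical(dim(object@t), dim(object@p)))
    return("'t' and 'p' must have identical dimensions")
  inp <- object@p[!is.na(object@p)]
  if (length(inp) && (min(inp) < 0 || max(inp) > 1))
    return("'p' values must lie in [0, 1]")
  if (object@df < 1L) return("'df' must be >= 1")
  TRUE
})

#' Labeled suprathreshold clusters
#'
#' Connected components of suprathreshold voxels in a t-map, used as
#' spatial masks selecting feature voxel positions. Cluster ids are
#' contiguous from 1; each cluster's voxel list is sorted
#' lexicographically by (x, y, z) array index (1-based), and clusters
#' themselves are ordered by their lexicographically smallest voxel.
#'
#' @slot labels 3-D integer array; 0 = background, 1..K = cluster id.
#' @slot clusters list of K integer matrices (voxels x 3) of sorted
#'   voxel coordinates.
#' @slot connectivity integer, 6, 18 or 26.
#' @export
setClass("ClusterMaskSet",
  representation(labels = "array", clusters = "list", connectivity = "integer"))

setValidity("ClusterMaskSet", function(object) {
  k <- length(object@clusters)
  lab <- object@labels
  if (k > 0 && max(lab) != k)
    return("cluster ids must be contiguous from 1")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    return("'connectivity' must be 6, 18 or 26")
  TRUE
})

#' Subjects-by-features matrix
#'
#' The object consumed by PCA and the affinity graph. For VBM-derived
#' features, `voxelIndex` records the (cluster, x, y, z) provenance of
#' every column; for synthetic clouds or PCA scores it is an empty
#' data frame.
#'
#' @slot values numeric matrix, subjects in rows, features in columns.
#' @slot subjectIDs character vector, one id per row.
#' @slot voxelIndex data.frame with columns cluster, x, y, z (or empty).
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", subjectIDs = "character",
                 voxelIndex = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@values) != length(object@subjectIDs))
    return("one subject id per row required")
  if (nrow(object@voxelIndex) > 0 && nrow(object@voxelIndex) != ncol(object@values))
    return("'voxelIndex' must describe every column")
  if (anyDuplicated(object@subjectIDs))
    return("duplicate subject ids")
  TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix (subjects x features).
#' @param subjectIDs character vector of row identifiers; defaults to
#'   rownames or `s1..sn`.
#' @param voxelIndex optional data.frame mapping columns to voxels.
#' @return A [FeatureMatrix-class].
#' @export
FeatureMatrix <- function(values, subjectIDs = NULL, voxelIndex = NULL) {
  values <- as.matrix(values)
  if (is.null(subjectIDs))
    subjectIDs <- if (!is.null(rownames(values))) rownames(values)
                  else paste0("s", seq_len(nrow(values)))
  if (is.null(voxelIndex))
    voxelIndex <- data.frame(cluster = integer(), x = integer(),
                             y = integer(), z = integer())
  rownames(values) <- subjectIDs
  new("FeatureMatrix", values = values, subjectIDs = as.character(subjectIDs),
      voxelIndex = voxelIndex)
}

#' Principal component model
#'
#' Centered (optionally standardized) PCA fitted by singular value
#' decomposition. Components are stored as a d x m orthonormal matrix;
#' explained variances use the 1/(n-1) convention and are sorted
#' descending. Component signs are fixed by forcing each component's
#' largest-magnitude loading positive.
#'
#' @slot center length-m column means.
#' @slot scale length-m column scales (all 1 unless standardized).
#' @slot components d x m orthonormal loading matrix (rows = components).
#' @slot explainedVariance length-d nonincreasing nonnegative vector.
#' @export
setClass("PCAModel",
  representation(center = "numeric", scale = "numeric",
                 components = "matrix", explainedVariance = "numeric"))

setValidity("PCAModel", function(object) {
  ev <- object@explainedVariance
  if (nrow(object@components) != length(ev))
    return("one explained variance per component required")
  if (ncol(object@components) != length(object@center))
    return("'center' length must equal the feature dimension")
  if (is.unsorted(rev(ev))) return("'explainedVariance' must be nonincreasing")
  if (any(ev < 0)) return("'explainedVariance' must be nonnegative")
  TRUE
})

#' Gaussian-kernel affinity matrix
#'
#' Symmetric nonnegative subject-by-subject similarity,
#' w_ij = exp(-||v_i - v_j||^2 / (2 sigma^2)) for connected pairs and for
#' i = j (so the diagonal is exactly 1), zero otherwise. Connectivity is
#' either the full graph or a symmetrized k-nearest-neighbor graph.
#'
#' @slot A n x n symmetric numeric matrix with entries in \[0, 1\].
#' @slot sigma positive kernel bandwidth.
#' @slot connectivity `"full"` or `"knn"`.
#' @slot k integer neighbor count (`NA` for full connectivity).
#' @export
setClass("AffinityMatrix",
  representation(A = "matrix", sigma = "numeric", connectivity = "character",
                 k = "integer"))

setValidity("AffinityMatrix", function(object) {
  A <- object@A
  if (nrow(A) != ncol(A)) return("'A' must be square")
  if (max(abs(A - t(A))) > 1e-12) return("'A' must be symmetric")
  if (any(A < 0) || any(A > 1)) return("affinities must lie in [0, 1]")
  if (max(abs(diag(A) - 1)) > 0) return("diagonal self-weights must equal 1")
  if (object@sigma <= 0) return("'sigma' must be positive")
  TRUE
})

#' Column-stochastic transition matrix
#'
#' T_ij = w_ij / sum_k w_kj: each column of the affinity matrix is
#' normalized by its sum, so every column of T sums to 1. Rows/columns
#' are ordered with the l labeled subjects first, defining the block
#' partition T = \[TLL TLU; TUL TUU\] used by the closed-form solver.
#'
#' @slot T n x n nonnegative matrix with unit column sums.
#' @slot nLabeled integer l, the number of leading labeled subjects.
#' @slot normalization `"column"` (the printed definition) or `"row"`
#'   (compatibility mode).
#' @export
setClass("TransitionMatrix",
  representation(T = "matrix", nLabeled = "integer", normalization = "character"),
  prototype(normalization = "column"))

setValidity("TransitionMatrix", function(object) {
  Tm <- object@T
  if (nrow(Tm) != ncol(Tm)) return("'T' must be square")
  if (any(Tm < 0)) return("'T' must be nonnegative")
  if (!object@normalization %in% c("column", "row"))
    return("'normalization' must be 'column' or 'row'")
  sums <- if (object@normalization == "column") colSums(Tm) else rowSums(Tm)
  if (max(abs(sums - 1)) > 1e-10)
    return("normalized sums of 'T' must equal 1 (tolerance 1e-10)")
  l <- object@nLabeled
  if (l < 1L || l >= nrow(Tm))
    return("'nLabeled' must satisfy 1 <= l < n")
  TRUE
})

#' Soft label state
#'
#' The n x c matrix Y of class membership scores, with labeled rows
#' clamped one-hot and unlabeled rows initialized uniform. Labeled
#' subjects occupy the first l rows, matching the transition-matrix
#' block partition.
#'
#' @slot Y n x c nonnegative matrix.
#' @slot labeledMask logical length-n vector, TRUE for the first l rows.
#' @slot classNames length-c character vector.
#' @export
setClass("LabelState",
  representation(Y = "matrix", labeledMask = "logical", classNames = "character"))

setValidity("LabelState", function(object) {
  Y <- object@Y
  if (length(object@labeledMask) != nrow(Y))
    return("'labeledMask' length must equal nrow(Y)")
  if (length(object@classNames) != ncol(Y))
    return("one class name per column required")
  l <- sum(object@labeledMask)
  if (l < 1L) return("at least one labeled row required")
  if (!all(object@labeledMask[seq_len(l)]))
    return("labeled rows must come first")
  YL <- Y[object@labeledMask, , drop = FALSE]
  if (any(abs(rowSums(YL) - 1) > 1e-12) || !all(YL %in% c(0, 1)))
    return("labeled rows must be one-hot")
  if (any(Y < 0)) return("'Y' must be nonnegative")
  TRUE
})

#' Result of label propagation
#'
#' Final soft labels, hard predictions for the unlabeled rows (per-row
#' argmax, exact ties broken toward the lowest class index), and solver
#' diagnostics.
#'
#' @slot Y n x c final soft-label matrix (rows sum to 1).
#' @slot labeledMask logical length-n, TRUE for clamped rows.
#' @slot classNames length-c character vector.
#' @slot predicted character vector of length n - l (unlabeled rows, in order).
#' @slot nIterations integer (0 for the closed form).
#' @slot converged logical.
#' @slot method `"iterative"` or `"closed_form"`.
#' @export
setClass("PropagationResult",
  representation(Y = "matrix", labeledMask = "logical",
                 classNames = "character", predicted = "character",
                 nIterations = "integer", converged = "logical",
                 method = "character"))

setValidity("PropagationResult", function(object) {
  if (length(object@predicted) != sum(!object@labeledMask))
    return("one prediction per unlabeled row required")
  if (!object@method %in% c("iterative", "closed_form"))
    return("unknown 'method'")
  TRUE
})

#' Binary classification metrics
#'
#' Confusion counts and the derived percentages. Sensitivity is the
#' recall of the positive (diseased) class, specificity the recall of
#' the negative class.
#'
#' @slot TP,FP,TN,FN integer confusion counts.
#' @slot accuracy,sensitivity,specificity percentages in \[0, 100\].
#' @slot positiveClass character scalar.
#' @export
setClass("ClassMetrics",
  representation(TP = "integer", FP = "integer", TN = "integer", FN = "integer",
                 accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", positiveClass = "character"))
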