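# Accessors and show methods for the central classes.

#' @rdname FeatureMatrix-class
#' @param object,x a morphoprop object.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @export
setGeneric("subjectIDs", function(x) standardGeneric("subjectIDs"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("subjectIDs", "FeatureMatrix", function(x) x@subjectIDs)

#' @rdname FeatureMatrix-class
#' @export
setGeneric("voxelIndex", function(x) standardGeneric("voxelIndex"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("voxelIndex", "FeatureMatrix", function(x) x@voxelIndex)

#' @rdname GMVolume-class
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname GMVolume-class
#' @export
setMethod("volumeData", "GMVolume", function(x) x@data)

#' @rdname GMVolume-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname GMVolume-class
#' @export
setMethod("voxelSize", "GMVolume", function(x) x@voxelSize)

#' @rdname GMMask-class
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname GMMask-class
#' @export
setMethod("maskArray", "GMMask", function(x) x@mask)

#' @rdname ClusterMaskSet-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterMaskSet-class
#' @export
setMethod("clusterLabels", "ClusterMaskSet", function(x) x@labels)

#' @rdname ClusterMaskSet-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ClusterMaskSet-class
#' @export
setMethod("nClusters", "ClusterMaskSet", function(x) length(x@clusters))

#' @rdname AffinityMatrix-class
#' @export
setGeneric("affinity", function(x) standardGeneric("affinity"))

#' @rdname AffinityMatrix-class
#' @export
setMethod("affinity", "AffinityMatrix", function(x) x@A)

#' @rdname TransitionMatrix-class
#' @export
setGeneric("transition", function(x) standardGeneric("transition"))

#' @rdname TransitionMatrix-class
#' @export
setMethod("transition", "TransitionMatrix", function(x) x@T)

#' @rdname TransitionMatrix-class
#' @export
setGeneric("nLabeled", function(x) standardGeneric("nLabeled"))

#' @rdname TransitionMatrix-class
#' @export
setMethod("nLabeled", "TransitionMatrix", function(x) x@nLabeled)

#' Blocks of the transition matrix
#'
#' Returns the TLL, TLU, TUL, TUU blocks induced by the labeled-first
#' ordering.
#'
#' @param x a [TransitionMatrix-class].
#' @return A named list of four matrices.
#' @export
transitionBlocks <- function(x) {
  stopIfNot(is(x, "TransitionMatrix"), "'x' must be a TransitionMatrix")
  l <- x@nLabeled
  n <- nrow(x@T)
  L <- seq_len(l); U <- seq.int(l + 1L, n)
  list(TLL = x@T[L, L, drop = FALSE], TLU = x@T[L, U, drop = FALSE],
       TUL = x@T[U, L, drop = FALSE], TUU = x@T[U, U, drop = FALSE])
}

#' @rdname PropagationResult-class
#' @export
setGeneric("predictedLabels", function(x) standardGeneric("predictedLabels"))

#' @rdname PropagationResult-class
#' @export
setMethod("predictedLabels", "PropagationResult", function(x) x@predicted)

#' @rdname PropagationResult-class
#' @export
setGeneric("softLabels", function(x) standardGeneric("softLabels"))

#' @rdname PropagationResult-class
#' @export
setMethod("softLabels", "PropagationResult", function(x) x@Y)

#' @rdname PCAModel-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname PCAModel-class
#' @export
setMethod("explainedVariance", "PCAModel", function(x) x@explainedVariance)

#' @rdname PCAModel-class
#' @export
setGeneric("pcaComponents", function(x) standardGeneric("pcaComponents"))

#' @rdname PCAModel-class
#' @export
setMethod("pcaComponents", "PCAModel", function(x) x@components)

#' @rdname ClassMetrics-class
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname ClassMetrics-class
#' @export
setMethod("metricValues", "ClassMetrics", function(x)
  c(accuracy = x@accuracy, sensitivity = x@sensitivity,
    specificity = x@specificity))

setMethod("show", "GMVolume", function(object) {
  cat(sprintf("GMVolume '%s': %s voxels, %s mm, GM in [%.3f, %.3f]\n",
              object@subjectID, paste(dim(object@data), collapse = "x"),
              paste(signif(object@voxelSize, 3), collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "GMMask", function(object) {
  cat(sprintf("GMMask: %d / %d voxels in mask (mean GM > %g)\n",
              sum(object@mask), length(object@mask), object@threshold))
})

setMethod("show", "TMap", function(object) {
  cat(sprintf("TMap: df = %d, tail = %s, %d in-mask voxels (%d degenerate)\n",
              object@df, object@tail, sum(!is.na(object@t)),
              object@nDegenerate))
})

setMethod("show", "ClusterMaskSet", function(object) {
  sizes <- vapply(object@clusters, nrow, integer(1))
  cat(sprintf("ClusterMaskSet: %d cluster(s), %d voxels total, %d-connectivity\n",
              length(sizes), sum(sizes), object@connectivity))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d subjects x %d features%s\n",
              nrow(object@values), ncol(object@values),
              if (nrow(object@voxelIndex)) " (voxel-indexed)" else ""))
})

setMethod("show", "PCAModel", function(object) {
  ev <- object@explainedVariance
  cat(sprintf("PCAModel: %d components over %d features; PC1 %.1f%% of variance\n",
              length(ev), ncol(object@components),
              if (sum(ev) > 0) 100 * ev[1] / sum(ev) else NA_real_))
})

setMethod("show", "AffinityMatrix", function(object) {
  cat(sprintf("AffinityMatrix: %d nodes, sigma = %g, %s%s\n",
              nrow(object@A), object@sigma, object@connectivity,
              if (identical(object@connectivity, "knn"))
                sprintf("(k = %d)", object@k) else ""))
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d nodes (%d labeled), column-stochastic\n",
              nrow(object@T), object@nLabeled))
})

setMethod("show", "PropagationResult", function(object) {
  cat(sprintf("PropagationResult (%s): %d labeled + %d unlabeled, %s after %d iteration(s)\n",
              object@method, sum(object@labeledMask),
              sum(!object@labeledMask),
              if (object@converged) "converged" else "NOT converged",
              object@nIterations))
})

setMethod("show", "ClassMetrics", function(object) {
  cat(sprintf(paste0("ClassMetrics (positive = %s): accuracy %.2f%%, ",
                     "sensitivity %.2f%%, specificity %.2f%% ",
                     "[TP %d FP %d TN %d FN %d]\n"),
              object@positiveClass, object@accuracy, object@sensitivity,
              object@specificity, object@TP, object@FP, object@TN, object@FN))
})
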