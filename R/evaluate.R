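# Experimental protocol: metrics, kernel-bandwidth cross-validation,
# repeated random training splits, and a dimension sweep.

#' Binary classification metrics
#'
#' Confusion counts and percentages with the diseased class as
#' positive: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/n, all reported on a 0-100 scale.
#'
#' @param predicted,truth equal-length label vectors over two classes.
#' @param positiveClass the positive (diseased) label, default `"AD"`.
#' @return A [ClassMetrics-class]. Sensitivity (or specificity) is
#'   `NaN`, with a warning, when the truth lacks the corresponding
#'   class.
#' @examples
#' computeMetrics(c("AD", "AD", "NC"), c("AD", "NC", "NC"))
#' @export
computeMetrics <- function(predicted, truth, positiveClass = "AD") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopIfNot(length(predicted) == length(truth) && length(truth) > 0,
            "'predicted' and 'truth' must be equal-length nonempty vectors")
  pos <- truth == positiveClass
  TP <- sum(predicted == positiveClass & pos)
  FN <- sum(predicted != positiveClass & pos)
  FP <- sum(predicted == positiveClass & !pos)
  TN <- sum(predicted != positiveClass & !pos)
  if (TP + FN == 0)
    warning("positive class absent from 'truth': sensitivity undefined")
  if (TN + FP == 0)
    warning("negative class absent from 'truth': specificity undefined")
  new("ClassMetrics", TP = TP, FP = FP, TN = TN, FN = FN,
      accuracy = 100 * (TP + TN) / length(truth),
      sensitivity = 100 * TP / (TP + FN),
      specificity = 100 * TN / (TN + FP),
      positiveClass = positiveClass)
}

#' Cross-validate the kernel bandwidth sigma
#'
#' Draws a pool of `cvPoolSize` subjects (default 30) at random,
#' partitions it into `nFolds` disjoint groups of `foldSize` (default 6
#' groups of 5), and for each candidate sigma scores each fold by
#' propagating the remaining pool subjects' labels to it. The sigma
#' with the highest mean fold accuracy wins; ties break toward the
#' smaller sigma. Candidates must lie in the open interval (0, 10).
#' A sigma so small that the kernel underflows and disconnects the
#' graph (making the closed-form solve singular) scores `NA` for the
#' affected folds and is never selected.
#'
#' @param features a [FeatureMatrix-class] (typically PCA scores).
#' @param labels ground-truth labels for all subjects.
#' @param sigmaGrid candidate bandwidths, each in (0, 10).
#' @param nFolds,foldSize,cvPoolSize fold geometry;
#'   `nFolds * foldSize` must equal `cvPoolSize`.
#' @param seed integer seed for the pool draw and partition.
#' @param method,connectivity,k passed to [propagateLabels()].
#' @return A list: `bestSigma`, `scores` (data.frame sigma x mean
#'   accuracy), `foldAccuracy` (matrix sigma x fold), `pool` (row
#'   indices used), `folds` (the disjoint validation groups).
#' @export
crossValidateSigma <- function(features, labels,
                               sigmaGrid = c(0.05, 0.1, 0.25, 0.5, 1, 2, 5),
                               nFolds = 6L, foldSize = 5L, cvPoolSize = 30L,
                               seed = 1L, method = "closed_form",
                               connectivity = "full", k = NULL) {
  stopIfNot(is(features, "FeatureMatrix"), "'features' must be a FeatureMatrix")
  labels <- as.character(labels)
  n <- nrow(features@values)
  stopIfNot(length(labels) == n && !anyNA(labels),
            "ground-truth labels required for every subject")
  stopIfNot(length(sigmaGrid) >= 1L, "'sigmaGrid' must be nonempty")
  stopIfNot(all(sigmaGrid > 0 & sigmaGrid < 10),
            "sigma candidates must lie in (0, 10)")
  stopIfNot(nFolds * foldSize == cvPoolSize,
            "'nFolds' * 'foldSize' must equal 'cvPoolSize'")
  stopIfNot(n >= cvPoolSize, "not enough subjects for the CV pool")
  pool <- withSeed(deriveSeed(seed, 17L), sample.int(n, cvPoolSize))
  folds <- split(pool, rep(seq_len(nFolds), each = foldSize))
  acc <- matrix(NA_real_, length(sigmaGrid), nFolds,
                dimnames = list(paste0("sigma=", sigmaGrid), NULL))
  for (si in seq_along(sigmaGrid)) {
    for (fi in seq_len(nFolds)) {
      val <- folds[[fi]]
      train <- setdiff(pool, val)
      sub <- c(train, val)
      partial <- labels[sub]
      partial[seq.int(length(train) + 1L, length(sub))] <- NA
      fm <- FeatureMatrix(features@values[sub, , drop = FALSE],
                          subjectIDs = features@subjectIDs[sub])
      out <- tryCatch(
        propagateLabels(fm, partial, sigma = sigmaGrid[si],
                        method = method, connectivity = connectivity,
                        k = k, classNames = sort(unique(labels))),
        error = function(e) NULL)
      acc[si, fi] <- if (is.null(out)) NA_real_
                     else mean(out$predicted == labels[val]) * 100
    }
  }
  meanAcc <- rowMeans(acc)
  stopIfNot(any(!is.na(meanAcc)),
            "every sigma candidate failed: the graph is disconnected at all bandwidths")
  best <- sigmaGrid[order(-meanAcc, sigmaGrid, na.last = TRUE)[1]]
  list(bestSigma = best,
       scores = data.frame(sigma = sigmaGrid, accuracy = meanAcc,
                           row.names = NULL),
       foldAccuracy = acc, pool = pool, folds = folds)
}

#' Repeated random-split evaluation
#'
#' Draws `nRuns` random training subsets of `trainSize` subjects
#' (stratified half-and-half by class by default), propagates their
#' labels to the remaining subjects, and averages accuracy, sensitivity
#' and specificity over runs. Per-run seeds derive from the master seed
#' by run index, so results are reproducible and independent of run
#' count. A draw whose training set misses a class is redrawn (logged),
#' preserving `nRuns`.
#'
#' @param features a [FeatureMatrix-class].
#' @param labels ground-truth labels for all subjects.
#' @param sigma kernel bandwidth to use throughout.
#' @param trainSize labeled subjects per run (default 25).
#' @param nRuns number of random splits (default 40).
#' @param seed master seed.
#' @param stratify draw half the training set from each class.
#' @param positiveClass passed to [computeMetrics()].
#' @param method,connectivity,k passed to [propagateLabels()].
#' @return A list: `mean` and `sd` (named vectors over the three
#'   metrics), `runs` (data.frame of per-run metrics), `perRun` (list of
#'   [ClassMetrics-class]).
#' @export
repeatedSplitEvaluation <- function(features, labels, sigma, trainSize = 25L,
                                    nRuns = 40L, seed = 1L, stratify = TRUE,
                                    positiveClass = "AD",
                                    method = "closed_form",
                                    connectivity = "full", k = NULL) {
  stopIfNot(is(features, "FeatureMatrix"), "'features' must be a FeatureMatrix")
  labels <- as.character(labels)
  n <- nrow(features@values)
  stopIfNot(length(labels) == n && !anyNA(labels),
            "ground-truth labels required for every subject")
  stopIfNot(trainSize >= 2L && trainSize < n,
            "'trainSize' must satisfy 2 <= trainSize < n")
  stopIfNot(nRuns >= 1L, "'nRuns' must be >= 1")
  classes <- sort(unique(labels))
  perRun <- vector("list", nRuns)
  drawTrain <- function(runSeed) {
    withSeed(runSeed, {
      if (stratify && length(classes) == 2L) {
        i1 <- which(labels == classes[1]); i2 <- which(labels == classes[2])
        n1 <- trainSize %/% 2L
        c(sample(i1, min(n1, length(i1))),
          sample(i2, min(trainSize - n1, length(i2))))
      } else sample.int(n, trainSize)
    })
  }
  for (r in seq_len(nRuns)) {
    attempt <- 0L
    repeat {
      train <- drawTrain(deriveSeed(seed, 100L * r + attempt))
      if (all(classes %in% labels[train])) break
      attempt <- attempt + 1L
      message("run ", r, ": training draw missed a class, redrawing")
    }
    partial <- labels
    partial[-train] <- NA
    out <- propagateLabels(features, partial, sigma = sigma, method = method,
                           connectivity = connectivity, k = k,
                           classNames = classes)
    perRun[[r]] <- computeMetrics(out$predicted, labels[-train],
                                  positiveClass = positiveClass)
  }
  runs <- do.call(rbind, lapply(seq_len(nRuns), function(r) {
    m <- perRun[[r]]
    data.frame(run = r, accuracy = m@accuracy, sensitivity = m@sensitivity,
               specificity = m@specificity)
  }))
  met <- c("accuracy", "sensitivity", "specificity")
  list(mean = vapply(met, function(x) mean(runs[[x]]), numeric(1)),
       sd = vapply(met, function(x) stats::sd(runs[[x]]), numeric(1)),
       runs = runs, perRun = perRun)
}

#' Accuracy as a function of PCA dimension
#'
#' Runs [repeatedSplitEvaluation()] at each requested embedding
#' dimension with identical seeds, so rows differ only in the
#' dimension. Dimensions beyond the PCA rank are skipped with a
#' warning.
#'
#' @param model a fitted [PCAModel-class].
#' @param features the full-dimension [FeatureMatrix-class] the model
#'   was fitted on.
#' @param labels ground-truth labels.
#' @param dims integer vector of dimensions to try.
#' @param sigma kernel bandwidth.
#' @param ... passed to [repeatedSplitEvaluation()].
#' @return data.frame with columns dim, accuracy, sensitivity,
#'   specificity (means over runs).
#' @export
dimensionSweep <- function(model, features, labels, dims, sigma, ...) {
  stopIfNot(is(model, "PCAModel"), "'model' must be a PCAModel")
  rank <- nrow(model@components)
  keep <- dims <= rank
  if (any(!keep))
    warning("skipping dimension(s) beyond the PCA rank: ",
            paste(dims[!keep], collapse = ", "))
  dims <- dims[keep]
  rows <- lapply(dims, function(d) {
    red <- pcaTransform(model, features, d = d)
    ev <- repeatedSplitEvaluation(red, labels, sigma = sigma, ...)
    data.frame(dim = d, accuracy = ev$mean["accuracy"],
               sensitivity = ev$mean["sensitivity"],
               specificity = ev$mean["specificity"], row.names = NULL)
  })
  do.call(rbind, rows)
}
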