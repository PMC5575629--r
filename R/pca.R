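# PCA dimension reduction with the cumulative-energy selection rule.

#' Fit a PCA model
#'
#' Centered PCA computed by singular value decomposition of the
#' (optionally standardized) data matrix — numerically stable when the
#' feature dimension far exceeds the number of subjects. All
#' min(n - 1, m) components are retained; explained variances use the
#' 1/(n - 1) convention. Signs are made deterministic by forcing the
#' largest-magnitude loading of each component positive.
#'
#' @param features a [FeatureMatrix-class] with n >= 2 finite rows.
#' @param standardize scale columns to unit variance before the fit
#'   (default FALSE: centering only).
#' @return A [PCAModel-class].
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' fitPCA(FeatureMatrix(X))
#' @export
fitPCA <- function(features, standardize = FALSE) {
  stopIfNot(is(features, "FeatureMatrix"), "'features' must be a FeatureMatrix")
  X <- features@values
  stopIfNot(nrow(X) >= 2L, "PCA needs at least 2 subjects")
  stopIfNot(all(is.finite(X)), "feature matrix contains non-finite values")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- rep(1, ncol(X))
  if (standardize) {
    scl <- apply(X, 2, stats::sd)
    stopIfNot(all(scl > 0), "cannot standardize constant features")
    Xc <- sweep(Xc, 2, scl, "/")
  }
  if (max(abs(Xc)) == 0)
    stop("constant feature matrix: all variances are zero", call. = FALSE)
  k <- min(nrow(X) - 1L, ncol(X))
  sv <- svd(Xc, nu = 0, nv = k)
  ev <- (sv$d[seq_len(k)]^2) / (nrow(X) - 1)
  comp <- t(sv$v)
  # fix sign: largest-|loading| entry of each component positive
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  new("PCAModel", center = ctr, scale = scl, components = comp,
      explainedVariance = ev)
}

#' Select the embedding dimension by cumulative energy
#'
#' Returns the smallest d whose leading components carry strictly more
#' than `energy` of the total variance (the reference configuration is
#' energy = 0.99). `energy = 1` returns the full rank.
#'
#' @param model a [PCAModel-class].
#' @param energy fraction of total variance to exceed, in (0, 1].
#' @return Integer dimension d.
#' @examples
#' # spectrum 0.6, 0.3, 0.095, 0.004, 0.001: three components exceed 99%
#' m <- new("PCAModel", center = numeric(5), scale = rep(1, 5),
#'          components = diag(5),
#'          explainedVariance = c(0.6, 0.3, 0.095, 0.004, 0.001))
#' selectDimension(m, 0.99)  # 3
#' @export
selectDimension <- function(model, energy = 0.99) {
  stopIfNot(is(model, "PCAModel"), "'model' must be a PCAModel")
  stopIfNot(energy > 0 && energy <= 1, "'energy' must be in (0, 1]")
  frac <- cumsum(model@explainedVariance) / sum(model@explainedVariance)
  d <- which(frac > energy)[1]
  if (is.na(d)) d <- length(frac)
  as.integer(d)
}

#' Project features onto the leading principal components
#'
#' Centers (and rescales, if the model standardized) the input and
#' projects onto the first d components. At full rank the projection is
#' an isometry of the centered data.
#'
#' @param model a [PCAModel-class].
#' @param features a [FeatureMatrix-class] with matching columns.
#' @param d number of components to keep (default: full rank).
#' @return A [FeatureMatrix-class] of scores (n x d, columns `PC1..PCd`).
#' @export
pcaTransform <- function(model, features, d = nrow(model@components)) {
  stopIfNot(is(model, "PCAModel"), "'model' must be a PCAModel")
  stopIfNot(is(features, "FeatureMatrix"), "'features' must be a FeatureMatrix")
  d <- as.integer(d)
  stopIfNot(d >= 1L && d <= nrow(model@components),
            "'d' exceeds the model rank")
  X <- features@values
  stopIfNot(ncol(X) == length(model@center),
            "feature dimension does not match the model")
  Xc <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  scores <- Xc %*% t(model@components[seq_len(d), , drop = FALSE])
  colnames(scores) <- paste0("PC", seq_len(d))
  FeatureMatrix(scores, subjectIDs = features@subjectIDs)
}
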