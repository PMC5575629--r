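# Affinity graph and transition matrix over subjects in feature space.

#' Gaussian-kernel affinity matrix
#'
#' Edge weights w_ij = exp(-||v_i - v_j||^2 / (2 sigma^2)) between
#' connected subjects; the self-weight is exp(0) = 1, so the diagonal is
#' exactly 1. Under `"full"` connectivity every pair is connected; under
#' `"knn"` an edge survives iff i is among j's k nearest neighbors or
#' vice versa (symmetrized), all other off-diagonal weights are 0.
#'
#' @param features a [FeatureMatrix-class] (or bare numeric matrix).
#' @param sigma positive kernel bandwidth, in feature-space distance
#'   units.
#' @param connectivity `"full"` (default) or `"knn"`.
#' @param k neighbor count for `"knn"`, 1 <= k < n.
#' @return An [AffinityMatrix-class].
#' @examples
#' X <- FeatureMatrix(matrix(rnorm(10), 5, 2))
#' affinity(buildAffinity(X, sigma = 1))
#' @export
buildAffinity <- function(features, sigma, connectivity = c("full", "knn"),
                          k = NULL) {
  connectivity <- match.arg(connectivity)
  checkScalar(sigma, "sigma", positive = TRUE)
  X <- if (is(features, "FeatureMatrix")) features@values else as.matrix(features)
  n <- nrow(X)
  stopIfNot(n >= 2L, "need at least 2 subjects")
  d2 <- as.matrix(stats::dist(X))^2
  A <- exp(-d2 / (2 * sigma^2))
  diag(A) <- 1
  if (connectivity == "knn") {
    stopIfNot(!is.null(k) && k >= 1 && k < n, "'k' must satisfy 1 <= k < n")
    k <- as.integer(k)
    keep <- matrix(FALSE, n, n)
    for (j in seq_len(n)) {
      nb <- order(d2[, j])            # self first (distance 0)
      nb <- setdiff(nb, j)[seq_len(k)]
      keep[nb, j] <- TRUE
    }
    keep <- keep | t(keep)
    diag(keep) <- TRUE
    A[!keep] <- 0
  } else k <- NA_integer_
  A <- (A + t(A)) / 2  # remove last-bit asymmetry from dist()
  dimnames(A) <- NULL
  new("AffinityMatrix", A = A, sigma = as.numeric(sigma),
      connectivity = connectivity, k = k)
}

#' Column-normalized transition matrix
#'
#' T_ij = w_ij / sum_k w_kj: each affinity column is divided by its sum,
#' so every column of T sums to 1. The self-loop guarantees positive
#' column sums. Rows/columns must already be ordered with the l labeled
#' subjects first; `l` fixes the TLL/TLU/TUL/TUU block partition.
#'
#' @param A an [AffinityMatrix-class].
#' @param l number of labeled subjects (leading rows/columns), 1 <= l < n.
#' @param rowNormalize normalize rows instead of columns — the
#'   convention of most label-propagation expositions, offered for
#'   comparison (default FALSE: column normalization).
#' @return A [TransitionMatrix-class].
#' @export
buildTransition <- function(A, l, rowNormalize = FALSE) {
  stopIfNot(is(A, "AffinityMatrix"), "'A' must be an AffinityMatrix")
  n <- nrow(A@A)
  l <- as.integer(l)
  stopIfNot(l >= 1L && l < n, "'l' must satisfy 1 <= l < n")
  Tm <- if (rowNormalize) A@A / rowSums(A@A)
        else sweep(A@A, 2, colSums(A@A), "/")
  new("TransitionMatrix", T = Tm, nLabeled = l,
      normalization = if (rowNormalize) "row" else "column")
}

#' Row-stochastic random-walk matrix
#'
#' P = D^-1 A, the classical random-walk transition matrix (D the
#' diagonal degree matrix d_i = sum_j A_ij). Provided for diagnostics;
#' the propagation solver uses the column-normalized
#' [buildTransition()] matrix instead.
#'
#' @param A an [AffinityMatrix-class].
#' @return A row-stochastic numeric matrix.
#' @export
randomWalkMatrix <- function(A) {
  stopIfNot(is(A, "AffinityMatrix"), "'A' must be an AffinityMatrix")
  A@A / rowSums(A@A)
}

#' Degree vector of an affinity graph
#'
#' d_i = sum_j A_ij; always >= 1 because of the unit self-loop.
#'
#' @param A an [AffinityMatrix-class].
#' @return Numeric vector of node degrees.
#' @export
nodeDegrees <- function(A) {
  stopIfNot(is(A, "AffinityMatrix"), "'A' must be an AffinityMatrix")
  rowSums(A@A)
}
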