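# Clamped label propagation: the iterative algorithm (replace Y by TY,
# row-normalize, re-clamp the labeled rows) and its closed-form harmonic
# solution YU = (I - TUU)^-1 TUL YL.

#' Initialize the soft-label matrix
#'
#' Builds the n x c matrix Y from a partial label vector: labeled rows
#' (non-NA entries, which must come first) are one-hot, unlabeled rows
#' are uniform 1/c. A warning is issued when a class has no labeled
#' example — propagation can then never predict it.
#'
#' @param labels character (or factor) vector with `NA` for unlabeled
#'   subjects; all labeled entries must precede the unlabeled ones.
#' @param classNames optional class universe (default: sorted unique
#'   labels observed).
#' @return A [LabelState-class].
#' @examples
#' initLabelState(c("AD", "NC", NA, NA))
#' @export
initLabelState <- function(labels, classNames = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  lab <- !is.na(labels)
  stopIfNot(sum(lab) >= 1L, "at least one labeled subject required")
  stopIfNot(all(lab == (seq_len(n) <= sum(lab))),
            "labeled subjects must come first; reorder before building the graph")
  if (is.null(classNames)) classNames <- sort(unique(labels[lab]))
  stopIfNot(all(labels[lab] %in% classNames),
            "labels outside 'classNames'")
  missing <- setdiff(classNames, labels[lab])
  if (length(missing))
    warning("class(es) without labeled examples will never be predicted: ",
            paste(missing, collapse = ", "))
  c <- length(classNames)
  Y <- matrix(1 / c, n, c, dimnames = list(NULL, classNames))
  Y[lab, ] <- 0
  Y[cbind(which(lab), match(labels[lab], classNames))] <- 1
  new("LabelState", Y = Y, labeledMask = lab, classNames = classNames)
}

# Row-argmax with ties broken toward the lowest class index.
argmaxLabels <- function(Y, classNames) classNames[max.col(Y, ties.method = "first")]

rowNormalize <- function(Y) {
  s <- rowSums(Y)
  stopIfNot(all(s > 0), "a row of Y became all-zero during propagation")
  Y / s
}

#' Iterative clamped label propagation
#'
#' Repeats (Y <- T Y; normalize each row to sum 1; reset the labeled
#' rows to their one-hot state) until the largest absolute elementwise
#' change falls below `tol` or `maxIter` is reached.
#'
#' @param Tmat a [TransitionMatrix-class].
#' @param state a [LabelState-class] whose labeled rows match
#'   `nLabeled(Tmat)`.
#' @param tol convergence tolerance on max |change| (default 1e-8).
#' @param maxIter iteration cap (default 10000).
#' @return A [PropagationResult-class].
#' @export
propagateIterative <- function(Tmat, state, tol = 1e-8, maxIter = 10000L) {
  stopIfNot(is(Tmat, "TransitionMatrix"), "'Tmat' must be a TransitionMatrix")
  stopIfNot(is(state, "LabelState"), "'state' must be a LabelState")
  stopIfNot(nrow(state@Y) == nrow(Tmat@T), "size mismatch between T and Y")
  stopIfNot(sum(state@labeledMask) == Tmat@nLabeled,
            "labeled counts of T and Y disagree")
  checkScalar(tol, "tol", positive = TRUE)
  Y <- state@Y
  lab <- state@labeledMask
  YL <- Y[lab, , drop = FALSE]
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    Ynew <- rowNormalize(Tmat@T %*% Y)
    Ynew[lab, ] <- YL
    if (max(abs(Ynew - Y)) < tol) {
      Y <- Ynew
      converged <- TRUE
      break
    }
    Y <- Ynew
  }
  new("PropagationResult", Y = Y, labeledMask = lab,
      classNames = state@classNames,
      predicted = argmaxLabels(Y[!lab, , drop = FALSE], state@classNames),
      nIterations = iter, converged = converged, method = "iterative")
}

#' Closed-form label propagation
#'
#' Solves the propagation fixed point by a direct linear solve instead
#' of iterating. Two variants are offered:
#'
#' * `"printed"` (default): YU = (I - TUU)^-1 TUL YL on the
#'   column-normalized transition matrix, with the unlabeled rows then
#'   normalized to probability rows.
#' * `"harmonic"`: the exact fixed point of the iterative algorithm.
#'   Because each iteration row-normalizes Y, iterating Y <- TY with
#'   row normalization is algebraically identical to iterating
#'   Y <- TbarY without it, where Tbar = T / rowSums(T); the harmonic
#'   variant therefore solves YU = (I - TbarUU)^-1 TbarUL YL and agrees
#'   elementwise with [propagateIterative()] at convergence.
#'
#' The two variants coincide when TUU = 0 (after row normalization) and
#' on symmetric configurations, and differ by a small amount otherwise;
#' predicted labels only diverge for subjects whose top-two class
#' scores are closer than that difference. Both require the spectral
#' radius of the unlabeled-block matrix to be below 1, which holds
#' whenever unlabeled subjects retain some connectivity to labeled
#' ones.
#'
#' @param Tmat a [TransitionMatrix-class].
#' @param state a [LabelState-class].
#' @param variant `"printed"` or `"harmonic"` (see above).
#' @return A [PropagationResult-class] (with `nIterations = 0`).
#' @export
propagateClosedForm <- function(Tmat, state,
                                variant = c("printed", "harmonic")) {
  variant <- match.arg(variant)
  stopIfNot(is(Tmat, "TransitionMatrix"), "'Tmat' must be a TransitionMatrix")
  stopIfNot(is(state, "LabelState"), "'state' must be a LabelState")
  stopIfNot(nrow(state@Y) == nrow(Tmat@T), "size mismatch between T and Y")
  stopIfNot(sum(state@labeledMask) == Tmat@nLabeled,
            "labeled counts of T and Y disagree")
  Tuse <- Tmat
  if (variant == "harmonic")
    Tuse <- new("TransitionMatrix", T = Tmat@T / rowSums(Tmat@T),
                nLabeled = Tmat@nLabeled, normalization = "row")
  bl <- transitionBlocks(Tuse)
  lab <- state@labeledMask
  YL <- state@Y[lab, , drop = FALSE]
  rad <- max(Mod(eigen(bl$TUU, only.values = TRUE)$values))
  if (rad >= 1 - 1e-12)
    stop("spectral radius of TUU is ", signif(rad, 6),
         " >= 1: unlabeled subjects are disconnected from labeled ones; ",
         "increase sigma, change k, or use the iterative solver", call. = FALSE)
  I <- diag(nrow(bl$TUU))
  YU <- tryCatch(solve(I - bl$TUU, bl$TUL %*% YL),
                 error = function(e)
                   stop("(I - TUU) is numerically singular: ",
                        conditionMessage(e), call. = FALSE))
  Y <- state@Y
  Y[!lab, ] <- rowNormalize(YU)
  new("PropagationResult", Y = Y, labeledMask = lab,
      classNames = state@classNames,
      predicted = argmaxLabels(Y[!lab, , drop = FALSE], state@classNames),
      nIterations = 0L, converged = TRUE, method = "closed_form")
}

#' Decode hard labels from soft scores
#'
#' Per-row argmax over a soft-label matrix (or the unlabeled rows of a
#' [PropagationResult-class]); exact ties go to the lowest class index,
#' with a message when that rule fires.
#'
#' @param x a [PropagationResult-class] or a numeric score matrix.
#' @param classNames class names (taken from `x` when it is a result).
#' @return Character label vector.
#' @export
decodeLabels <- function(x, classNames = NULL) {
  if (is(x, "PropagationResult")) {
    Y <- x@Y[!x@labeledMask, , drop = FALSE]
    classNames <- x@classNames
  } else {
    Y <- as.matrix(x)
    stopIfNot(!is.null(classNames), "'classNames' required for a bare matrix")
  }
  ties <- apply(Y, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties))
    message(sum(ties), " tie(s) broken toward the lowest class index")
  argmaxLabels(Y, classNames)
}

#' Propagate labels over a feature matrix (high level)
#'
#' Convenience wrapper handling subject ordering: subjects may arrive in
#' any order with `NA` marking unlabeled ones; the function permutes
#' labeled subjects first, builds the affinity graph and transition
#' matrix, runs the chosen solver, and returns predictions in the
#' original subject order.
#'
#' @param features a [FeatureMatrix-class].
#' @param labels character vector with `NA` for unlabeled subjects
#'   (any order).
#' @param sigma Gaussian kernel bandwidth.
#' @param method `"closed_form"` (default) or `"iterative"`.
#' @param connectivity,k graph connectivity, see [buildAffinity()].
#' @param classNames optional class universe.
#' @param ... passed to the solver (`tol`, `maxIter`).
#' @return A list: `predicted` (named character vector over unlabeled
#'   subjects, original order), `scores` (their soft labels), `result`
#'   (the [PropagationResult-class] in internal order).
#' @export
propagateLabels <- function(features, labels, sigma,
                            method = c("closed_form", "iterative"),
                            connectivity = "full", k = NULL,
                            classNames = NULL, ...) {
  method <- match.arg(method)
  stopIfNot(is(features, "FeatureMatrix"), "'features' must be a FeatureMatrix")
  labels <- as.character(labels)
  stopIfNot(length(labels) == nrow(features@values),
            "one label (or NA) per subject required")
  ord <- order(is.na(labels))  # stable: labeled first, original order kept
  X <- FeatureMatrix(features@values[ord, , drop = FALSE],
                     subjectIDs = features@subjectIDs[ord])
  A <- buildAffinity(X, sigma = sigma, connectivity = connectivity, k = k)
  Tm <- buildTransition(A, l = sum(!is.na(labels)))
  state <- initLabelState(labels[ord], classNames = classNames)
  res <- if (method == "iterative") propagateIterative(Tm, state, ...)
         else propagateClosedForm(Tm, state, ...)
  unlabIDs <- X@subjectIDs[!state@labeledMask]
  pred <- stats::setNames(res@predicted, unlabIDs)
  scores <- res@Y[!state@labeledMask, , drop = FALSE]
  rownames(scores) <- unlabIDs
  origUnlab <- features@subjectIDs[is.na(labels)]
  list(predicted = pred[origUnlab],
       scores = scores[origUnlab, , drop = FALSE], result = res)
}
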