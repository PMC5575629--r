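# Clamped label propagation: initialization, both solvers, decoding.

test_that("label-state initialization is one-hot for labeled, uniform for unlabeled", {
  st <- initLabelState(c("A", "B", NA, NA))
  expect_equal(st@Y, matrix(c(1, 0, 0.5, 0.5, 0, 1, 0.5, 0.5), 4, 2,
                            dimnames = list(NULL, c("A", "B"))))
  expect_error(initLabelState(c(NA, NA)), "labeled")
  expect_error(initLabelState(c(NA, "A")), "first")
  expect_warning(initLabelState(c("A", NA), classNames = c("A", "B")),
                 "never be predicted")
})

test_that("a class with no labeled example is never predicted", {
  set.seed(15)
  X <- FeatureMatrix(matrix(rnorm(20), 10, 2))
  labels <- c("A", "A", rep(NA, 8))
  suppressWarnings({
    out <- propagateLabels(X, labels, sigma = 1, classNames = c("A", "B"))
  })
  expect_true(all(out$predicted == "A"))
})

test_that("with a single labeled node all unlabeled nodes adopt its class", {
  set.seed(16)
  X <- FeatureMatrix(matrix(rnorm(12), 6, 2))
  labels <- c("A", rep(NA, 5))
  for (m in c("iterative", "closed_form")) {
    suppressWarnings(out <- propagateLabels(X, labels, sigma = 1, method = m,
                                            classNames = c("A", "B")))
    expect_true(all(out$predicted == "A"))
  }
})

test_that("clamped rows are identical before and after propagation", {
  set.seed(17)
  inst <- randomInstance(3, 15, 6)
  st <- initLabelState(inst$labels[order(is.na(inst$labels))],
                       classNames = inst$classNames)
  A <- buildAffinity(FeatureMatrix(featureValues(inst$features)[order(is.na(inst$labels)), ]),
                     sigma = 1.5)
  Tm <- buildTransition(A, l = sum(!is.na(inst$labels)))
  res <- propagateIterative(Tm, st)
  l <- sum(st@labeledMask)
  expect_identical(res@Y[1:l, ], st@Y[1:l, ])
  expect_true(res@converged)
  # fixed point: rerunning from the output changes nothing
  st2 <- new("LabelState", Y = res@Y, labeledMask = st@labeledMask,
             classNames = st@classNames)
  res2 <- propagateIterative(Tm, st2)
  expect_lt(max(abs(res2@Y - res@Y)), 1e-7)
})

test_that("with TUU = 0 the printed closed form reduces to TUL YL", {
  # self-loops always give TUU a positive diagonal, so a TUU = 0
  # configuration is constructed directly as a column-stochastic matrix
  Tm <- new("TransitionMatrix",
            T = rbind(c(0.5, 0.1, 0.6, 0.3),
                      c(0.3, 0.6, 0.4, 0.7),
                      c(0.2, 0.0, 0.0, 0.0),
                      c(0.0, 0.3, 0.0, 0.0)),
            nLabeled = 2L)
  bl <- transitionBlocks(Tm)
  expect_true(all(bl$TUU == 0))
  st <- initLabelState(c("A", "B", NA, NA))
  res <- propagateClosedForm(Tm, st)
  direct <- bl$TUL %*% st@Y[1:2, ]
  expect_equal(res@Y[3:4, ], direct / rowSums(direct), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the labeled-unlabeled-labeled chain resolves to (0.5, 0.5), tie to the first class", {
  a <- 0.35
  A <- matrix(0, 3, 3); diag(A) <- 1
  A[1, 3] <- A[3, 1] <- a      # ordering: L1, L2, U
  A[2, 3] <- A[3, 2] <- a
  Aff <- new("AffinityMatrix", A = A, sigma = 1, connectivity = "knn", k = 1L)
  Tm <- buildTransition(Aff, l = 2)
  st <- initLabelState(c("AD", "NC", NA))
  for (variant in c("printed", "harmonic")) {
    res <- propagateClosedForm(Tm, st, variant = variant)
    expect_equal(res@Y[3, ], c(AD = 0.5, NC = 0.5), tolerance = 1e-12)
  }
  expect_message(lab <- decodeLabels(propagateClosedForm(Tm, st)), "tie")
  expect_identical(lab, "AD")
})

test_that("the harmonic closed form equals the iterative fixed point elementwise", {
  set.seed(18)
  for (i in 1:10) {
    inst <- randomInstance(sample(2:4, 1), sample(10:25, 1), 6)
    conn <- if (i %% 2) "full" else "knn"
    k <- if (conn == "knn") 5 else NULL
    cf <- propagateLabels(inst$features, inst$labels, sigma = 1.5,
                          method = "closed_form", variant = "harmonic",
                          connectivity = conn, k = k,
                          classNames = inst$classNames)
    it <- propagateLabels(inst$features, inst$labels, sigma = 1.5,
                          method = "iterative", tol = 1e-12,
                          connectivity = conn, k = k,
                          classNames = inst$classNames)
    expect_true(it$result@converged)
    expect_equal(cf$scores, it$scores, tolerance = 1e-8)
    expect_identical(cf$predicted, it$predicted)
  }
})

test_that("a disconnected unlabeled block makes the closed form fail loudly", {
  A <- diag(3)                      # no edges at all
  Aff <- new("AffinityMatrix", A = A, sigma = 1, connectivity = "knn", k = 1L)
  Tm <- buildTransition(Aff, l = 1)
  st <- suppressWarnings(initLabelState(c("A", NA, NA), classNames = c("A", "B")))
  expect_error(suppressWarnings(propagateClosedForm(Tm, st)), "spectral radius")
})

test_that("decoding takes the row argmax with ties to the lowest class index", {
  Y <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))
  expect_message(lab <- decodeLabels(Y, classNames = c("AD", "NC")), "tie")
  expect_identical(lab, c("AD", "AD", "NC"))
})

test_that("predictions are equivariant under permuting the input subjects", {
  set.seed(19)
  inst <- randomInstance(2, 14, 5)
  out <- propagateLabels(inst$features, inst$labels, sigma = 1.5)
  perm <- sample(14)
  fmP <- FeatureMatrix(featureValues(inst$features)[perm, ],
                       subjectIDs = subjectIDs(inst$features)[perm])
  outP <- propagateLabels(fmP, inst$labels[perm], sigma = 1.5)
  expect_identical(outP$predicted[names(out$predicted)], out$predicted)
})

test_that("well-separated two-Gaussian clouds with 25% labels classify at 99%+ over 20 seeds", {
  accs <- vapply(1:20, function(s) {
    fc <- generateFeatureCloud(featureCloudSpec(nPerClass = 20, dimension = 2,
                                                separation = 6, noiseSD = 1,
                                                seed = 100 + s))
    partial <- fc$labels
    partial[-c(1:5, 21:25)] <- NA
    out <- propagateLabels(fc$features, partial, sigma = 1.5)
    mean(out$predicted == fc$labels[is.na(partial)])
  }, numeric(1))
  expect_gte(mean(accs) * 100, 99)
})
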