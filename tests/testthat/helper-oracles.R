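# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: flood fill by explicit BFS, t statistics
# via stats::t.test, components compared as voxel partitions.

# BFS flood fill over a 3-D logical array; returns an integer label
# array (component numbering arbitrary).
bfsFloodFill <- function(supra, connectivity) {
  d <- dim(supra)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1),
               , drop = FALSE]
  lab <- array(0L, d)
  nextId <- 0L
  idx <- which(supra)
  for (start in idx) {
    if (lab[start] > 0L) next
    nextId <- nextId + 1L
    queue <- start
    lab[start] <- nextId
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cc <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- cc + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (supra[lin] && lab[lin] == 0L) {
          lab[lin] <- nextId
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# Canonical form of a labeling: list of sorted linear-index sets,
# ordered by smallest member, so two labelings can be compared as
# partitions regardless of id numbering.
partitionOf <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  comps <- lapply(ids, function(k) sort(which(lab == k)))
  comps[order(vapply(comps, min, integer(1)))]
}

# Tiny GM cohort with prescribed per-subject voxel values at one site
# and a constant elsewhere (keeps the mask nonempty).
volumesWithVoxel <- function(values, at = c(2, 2, 2), shape = c(4, 4, 4),
                             background = 0.5) {
  lapply(seq_along(values), function(i) {
    a <- array(background, shape)
    a[at[1], at[2], at[3]] <- values[i]
    GMVolume(a, subjectID = paste0("s", i))
  })
}

# Random two-class labeled instance for propagation tests: c classes on
# simplex-vertex centers, every class represented among the labeled
# (leading) subjects.
randomInstance <- function(nClasses, n, nLabeled, separation = 4, noise = 1) {
  centers <- diag(nClasses) * separation / sqrt(2)
  cls <- sample(rep(seq_len(nClasses), length.out = n))
  X <- centers[cls, , drop = FALSE] +
    matrix(rnorm(n * nClasses, sd = noise), n, nClasses)
  lead <- vapply(seq_len(nClasses), function(k) which(cls == k)[1], integer(1))
  labIdx <- unique(c(lead, sample.int(n, nLabeled)))[seq_len(nLabeled)]
  labIdx <- labIdx[!is.na(labIdx)]
  labels <- rep(NA_character_, n)
  labels[labIdx] <- paste0("C", cls[labIdx])
  list(features = FeatureMatrix(X), labels = labels, truth = paste0("C", cls),
       classNames = paste0("C", seq_len(nClasses)))
}

# TMap wrapper around a given p-value array (t filled consistently).
tmapFromP <- function(pArr, df = 10L) {
  new("TMap", t = array(1 - pArr, dim(pArr)), p = pArr, df = df,
      tail = "two.sided", nDegenerate = 0L)
}
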