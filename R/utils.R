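# Internal helpers: seed substreams and argument checking.

# Derive a reproducible substream seed from a master seed and a counter.
# Lehmer-style mixing keeps results in the 32-bit signed range and makes
# substreams independent of how many are drawn, so enlarging a cohort
# never reshuffles earlier subjects.
deriveSeed <- function(seed, index) {
  m <- 2147483629
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(index) * 7919 + 1) %% m)
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

checkScalar <- function(x, name, positive = FALSE) {
  stopIfNot(length(x) == 1L && is.finite(x), sprintf("'%s' must be a finite scalar", name))
  if (positive) stopIfNot(x > 0, sprintf("'%s' must be positive", name))
  invisible(x)
}

# Stack a list of GMVolume into a voxels x subjects matrix after checking
# shape/voxel-size consistency. Errors name the offending subject.
cohortMatrix <- function(volumes) {
  stopIfNot(length(volumes) >= 1L, "at least one volume required")
  ref <- dim(volumes[[1]]@data)
  vox <- volumes[[1]]@voxelSize
  for (v in volumes) {
    if (!identical(dim(v@data), ref))
      stop(sprintf("volume '%s' has dimensions (%s), expected (%s)",
                   v@subjectID, paste(dim(v@data), collapse = ","),
                   paste(ref, collapse = ",")), call. = FALSE)
    if (max(abs(v@voxelSize - vox)) > 1e-9)
      stop(sprintf("volume '%s' has a different voxel size", v@subjectID),
           call. = FALSE)
  }
  m <- vapply(volumes, function(v) as.numeric(v@data), numeric(prod(ref)))
  attr(m, "volDim") <- ref
  m
}
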