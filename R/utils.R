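# Internal helpers shared across modules.

#' Row-major strict upper triangle of a square matrix
#'
#' Returns entries (1,2), (1,3), ..., (1,n), (2,3), ... as a vector, the
#' ordering used for connectivity feature vectors.
#' @param m square matrix
#' @return numeric vector of length n(n-1)/2
#' @export
upperTriRowMajor <- function(m) {
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric matrix from a row-major upper-triangle vector
#' @param v vector of length n(n-1)/2
#' @param labels node labels (length n)
#' @param diag value placed on the diagonal
#' @export
symmetricFromUpperTri <- function(v, labels, diag = 1) {
  n <- length(labels)
  stopifnot(length(v) == n * (n - 1) / 2)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  base::diag(m) <- diag
  m
}

# Deterministic per-subject RNG substream: one master seed spawns
# independent streams keyed by group and within-group index, so adding
# subjects to one group never perturbs existing subjects. Kept < 2^31.
subjectSeed <- function(seed, group, k) {
  g <- if (identical(group, "NVLD")) 0L else 1L
  (abs(as.integer(seed)) %% 1048576L) * 1024L + g * 524288L + as.integer(k)
}

isSymmetricTol <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
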