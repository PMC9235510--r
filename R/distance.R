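# Tanimoto similarity, dataset diversity, and Tanimoto-kernel maximum mean
# discrepancy (MMD) between labeled dataset partitions.
#
# For binary fingerprint vectors x, y the Tanimoto coefficient
#   T(x, y) = <x, y> / (||x||^2 + ||y||^2 - <x, y>)
# coincides with the set formulation |x n y| / |x u y|. The empirical MMD
# between fingerprint samples {x_i} (n) and {y_j} (m) with kernel k = T is
#   1/(n(n-1)) sum_{i != j} k(x_i, x_j)
#   - 2/(nm)   sum_{i, j}   k(x_i, y_j)
#   + 1/(m(m-1)) sum_{i != j} k(y_i, y_j),
# the unbiased estimator: it can be negative and is not exactly zero for
# X = X; values are reported as-is, without clamping.

#' Tanimoto similarity of two binary vectors
#'
#' @param x,y binary 0/1 vectors of equal length, not both all-zero.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(x, y) {
  stopifnot(length(x) == length(y))
  dot <- sum(x * y)
  den <- sum(x * x) + sum(y * y) - dot
  if (den == 0) stop("Tanimoto undefined: both vectors all-zero")
  dot / den
}

# All pairwise Tanimoto similarities between the rows of two binary matrices.
.tanimoto_cross <- function(A, B) {
  dot <- tcrossprod(A, B)
  na <- rowSums(A * A)
  nb <- rowSums(B * B)
  den <- outer(na, nb, "+") - dot
  if (any(den == 0)) stop("Tanimoto undefined: all-zero fingerprint present")
  dot / den
}

#' Mean pairwise Tanimoto distance within a fingerprint set
#'
#' Dataset diversity: the mean of (1 - T) over all unordered distinct pairs.
#'
#' @param fps binary fingerprint matrix, one molecule per row (n >= 2).
#' @return diversity in \[0, 1\].
#' @export
diversity <- function(fps) {
  fps <- as.matrix(fps)
  n <- nrow(fps)
  if (n < 2L) stop("diversity needs >= 2 fingerprints")
  S <- .tanimoto_cross(fps, fps)
  mean(1 - S[upper.tri(S)])
}

#' Tanimoto-kernel maximum mean discrepancy between two fingerprint sets
#'
#' Unbiased empirical MMD with the Tanimoto similarity as kernel; see the
#' file header for the estimator. Symmetric in its arguments and possibly
#' negative.
#'
#' @param X,Y binary fingerprint matrices (rows = molecules, n, m >= 2, same
#'   number of columns).
#' @return the MMD estimate (a real number, not clamped at zero).
#' @export
mmd <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- nrow(Y)
  if (n < 2L || m < 2L) stop("mmd needs >= 2 fingerprints per set")
  stopifnot(ncol(X) == ncol(Y))
  Kxx <- .tanimoto_cross(X, X)
  Kyy <- .tanimoto_cross(Y, Y)
  Kxy <- .tanimoto_cross(X, Y)
  (sum(Kxx) - sum(diag(Kxx))) / (n * (n - 1)) -
    2 * sum(Kxy) / (n * m) +
    (sum(Kyy) - sum(diag(Kyy))) / (m * (m - 1))
}

#' Pairwise MMD matrix over dataset partitions
#'
#' @param partitions named list of binary fingerprint matrices.
#' @return symmetric matrix of MMD values; the diagonal holds each
#'   partition's self-MMD under the unbiased estimator (not forced to zero).
#' @export
partition_matrix <- function(partitions) {
  stopifnot(is.list(partitions), length(partitions) >= 2L)
  nm <- names(partitions)
  if (is.null(nm)) nm <- paste0("P", seq_along(partitions))
  k <- length(partitions)
  M <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in i:k) {
      v <- mmd(partitions[[i]], partitions[[j]])
      M[i, j] <- v
      M[j, i] <- v
    }
  }
  M
}
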