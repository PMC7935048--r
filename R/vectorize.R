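#' Pair index for C components
#'
#' Deterministic ordering of the C(C-1)/2 unordered component pairs:
#' (1,2), (1,3), ..., (1,C), (2,3), ... — i < j, lexicographic (row-major
#' upper triangle). All pairwise trajectories, centroids and vectorized
#' connectivity matrices in the package use this ordering.
#'
#' @param n_components Number of components C (>= 2).
#' @return Integer matrix with columns `i`, `j`, one row per pair.
#' @export
pair_index <- function(n_components) {
  if (n_components < 2) stop("need at least 2 components")
  pr <- t(utils::combn(n_components, 2L))
  colnames(pr) <- c("i", "j")
  pr
}

#' Vectorize a symmetric connectivity matrix
#'
#' Extracts the upper triangle (i < j) in row-major order; inverse of
#' [devectorize_fnc()].
#'
#' @param m Symmetric numeric matrix.
#' @param tol Maximum allowed asymmetry |m - t(m)|.
#' @return Numeric vector of length C(C-1)/2.
#' @export
vectorize_fnc <- function(m, tol = 1e-10) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m)), na.rm = TRUE) > tol)
    stop("matrix is not symmetric within tolerance ", tol)
  m[pair_index(nrow(m))]
}

#' Rebuild a connectivity matrix from its pair vector
#'
#' @param v Pair vector of length C(C-1)/2 in [pair_index()] order.
#' @param diag_value Value for the diagonal: `NA` (default; centroids carry no
#'   diagonal) or e.g. `1` for a correlation matrix.
#' @return Symmetric C x C matrix.
#' @export
devectorize_fnc <- function(v, diag_value = NA_real_) {
  p <- length(v)
  cc <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(cc - round(cc)) > 1e-8)
    stop("length ", p, " is not C(C-1)/2 for any integer C")
  cc <- as.integer(round(cc))
  m <- matrix(diag_value, cc, cc)
  idx <- pair_index(cc)
  m[idx] <- v
  m[idx[, 2:1, drop = FALSE]] <- v
  m
}
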