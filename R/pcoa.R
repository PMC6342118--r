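#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Gower double-centering of `-D^2/2` followed by eigen-decomposition.
#' Axes with eigenvalues above `tol * max(eigenvalue)` are retained and
#' scaled by the square root of their eigenvalue, so that for a Euclidean
#' `D` the pairwise distances of the retained coordinates reproduce `D`.
#' Negative-eigenvalue axes (non-Euclidean part) are discarded.
#'
#' @param D symmetric `n x n` dissimilarity matrix, zero diagonal.
#' @param tol relative eigenvalue tolerance (default `1e-10`).
#' @return list of class `pcoa_result`: `coords` (`n x m`),
#'   `eigenvalues` (all `n`), `retained` (indices of kept axes).
#' @export
pcoa <- function(D, tol = 1e-10) {
  D <- as.matrix(D)
  check_dist_matrix(D, "D")
  G <- gower_center(D)
  eig <- eigen(G, symmetric = TRUE)
  lam <- eig$values
  if (max(lam) <= 0) stop("all eigenvalues <= 0: degenerate dissimilarity")
  keep <- which(lam > tol * max(lam))
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lam[keep]), length(keep))
  structure(list(coords = coords, eigenvalues = lam, retained = keep),
            class = "pcoa_result")
}

# Gower-centered matrix: -(I - 11'/n) (D^2/2) (I - 11'/n)
gower_center <- function(D) {
  A <- -0.5 * D^2
  rm_ <- rowMeans(A); gm <- mean(A)
  sweep(sweep(A, 1L, rm_), 2L, rm_) + gm
}
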