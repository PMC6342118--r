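#' Moran's eigenvector map basis from a distance matrix
#'
#' Builds the PCNM-lineage MEM basis: distances above the truncation
#' threshold `t` are replaced by `4t`, the modified matrix is
#' Gower-centered as `-(D*)^2/2`, and its eigen-decomposition yields
#' spatial eigenvectors. Eigenvectors with `|eigenvalue| > tol * max` are
#' retained; positive eigenvalues describe positive spatial
#' autocorrelation (broad-to-fine scales in decreasing order), negative
#' eigenvalues negative autocorrelation. The default truncation is the
#' longest edge of the minimum spanning tree of `D`, guaranteeing a
#' connected neighbour graph.
#'
#' @param D symmetric distance matrix (geographic meters or cost units).
#' @param truncation `"auto"` (MST longest edge) or a positive number. A
#'   user-supplied value under which the neighbour graph is disconnected is
#'   an error.
#' @param tol relative eigenvalue tolerance (default `1e-10`).
#' @param source tag recorded on the basis (`"euclidean"` or `"cost"`).
#' @return object of class `mem_basis`: `vectors` (`n x k`, orthonormal
#'   columns summing to ~0), `values` (length `k`, decreasing), `class`
#'   (`"positive"`/`"negative"` per vector), `truncation`, `source`.
#' @export
mem_basis <- function(D, truncation = "auto", tol = 1e-10,
                      source = "euclidean") {
  D <- as.matrix(D)
  check_dist_matrix(D, "D")
  n <- nrow(D)
  if (identical(truncation, "auto")) {
    t0 <- mst_longest_edge(D)
  } else {
    t0 <- as.numeric(truncation)
    if (!is.finite(t0) || t0 <= 0) stop("truncation must be positive")
    adj <- D <= t0
    diag(adj) <- FALSE
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    if (comp$no > 1L)
      stop("neighbour graph disconnected at truncation ", t0, ": ",
           comp$no, " components")
  }
  Dstar <- ifelse(D <= t0, D, 4 * t0)
  diag(Dstar) <- 0
  G <- gower_center(Dstar)
  eig <- eigen(G, symmetric = TRUE)
  lam <- eig$values
  keep <- which(abs(lam) > tol * max(abs(lam)))
  ord <- keep[order(lam[keep], decreasing = TRUE)]
  structure(list(vectors = eig$vectors[, ord, drop = FALSE],
                 values = lam[ord],
                 class = ifelse(lam[ord] > 0, "positive", "negative"),
                 truncation = t0, source = source, n = n),
            class = "mem_basis")
}

#' @export
print.mem_basis <- function(x, ...) {
  cat("mem_basis (", x$source, "): ", sum(x$class == "positive"),
      " positive + ", sum(x$class == "negative"),
      " negative eigenvectors, n = ", x$n,
      ", truncation = ", signif(x$truncation, 5), "\n", sep = "")
  invisible(x)
}

# longest edge of the minimum spanning tree of a distance matrix
mst_longest_edge <- function(D) {
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  m <- igraph::mst(g, weights = igraph::E(g)$weight)
  max(igraph::E(m)$weight)
}

#' Euclidean distance matrix from planar coordinates
#' @param xy `n x 2` matrix of projected coordinates (meters).
#' @return `n x n` symmetric matrix.
#' @export
euclidean_distance <- function(xy) {
  as.matrix(stats::dist(xy))
}
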