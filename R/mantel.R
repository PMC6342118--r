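#' Mantel test of matrix association
#'
#' Pearson correlation between the upper triangles of two symmetric
#' zero-diagonal dissimilarity matrices; significance by simultaneously
#' permuting rows and columns of `D2`, with a one-sided p-value for
#' `r_perm >= r_obs` and the `(k+1)/(n_perm+1)` correction.
#'
#' @param D1,D2 symmetric `n x n` matrices with zero diagonals.
#' @param n_perm number of permutations (default 999).
#' @return list of class `mantel_result`: `r`, `p`, `n`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999L) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- nrow(D1)
  if (!isTRUE(all.equal(dim(D1), dim(D2))) || ncol(D1) != n)
    stop("matrices must be square and of equal size")
  check_dist_matrix(D1, "D1"); check_dist_matrix(D2, "D2")
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  if (stats::sd(v1) == 0 || stats::sd(D2[ut]) == 0)
    stop("constant distance matrix: Mantel correlation undefined")
  r <- stats::cor(v1, D2[ut])
  p <- NA_real_
  if (n_perm > 0L) {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      if (stats::cor(v1, D2[perm, perm][ut]) >= r - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  structure(list(r = r, p = p, n = n, n_perm = n_perm),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %s (n = %d, %d permutations)\n",
              x$r, format.pval(x$p), x$n, x$n_perm))
  invisible(x)
}

check_dist_matrix <- function(D, name) {
  if (any(abs(diag(D)) > 1e-12))
    stop(name, ": diagonal must be zero")
  if (any(abs(D - t(D)) > 1e-8))
    stop(name, ": matrix must be symmetric")
  invisible(TRUE)
}

#' Mantel correlogram
#'
#' Profiles spatial autocorrelation of a genetic dissimilarity against
#' geographic distance: pairs are binned into distance classes
#' (equal-frequency by default) and, for each class, a Mantel statistic is
#' computed between `Dgen` and the class-membership indicator matrix. The
#' sign is flipped so that positive `r` means genetic similarity within the
#' class (positive autocorrelation). Per-class p-values are corrected by a
#' progressive Holm rule in increasing-distance order. Classes with fewer
#' than `min_pairs` pairs are merged into their lower neighbour with a
#' warning.
#'
#' @param Dgeo,Dgen symmetric `n x n` matrices (geographic meters; genetic).
#' @param n_classes number of distance classes (>= 2).
#' @param n_perm permutations per class (default 999).
#' @param breaks `"equal_freq"` (default) or `"equal_width"`.
#' @param min_pairs minimum pairs per class (default 20).
#' @return data frame of class `mantel_correlogram`: `upper` (class upper
#'   bound, meters), `n_pairs`, `r`, `p`, `p_holm`.
#' @export
mantel_correlogram <- function(Dgeo, Dgen, n_classes = 10L, n_perm = 999L,
                               breaks = c("equal_freq", "equal_width"),
                               min_pairs = 20L) {
  breaks <- match.arg(breaks)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  Dgeo <- as.matrix(Dgeo); Dgen <- as.matrix(Dgen)
  check_dist_matrix(Dgeo, "Dgeo"); check_dist_matrix(Dgen, "Dgen")
  n <- nrow(Dgeo)
  ut <- upper.tri(Dgeo)
  d <- Dgeo[ut]
  brk <- if (breaks == "equal_freq")
    unique(stats::quantile(d, probs = seq(0, 1, length.out = n_classes + 1L)))
  else seq(min(d), max(d), length.out = n_classes + 1L)
  brk[1] <- min(d) - 1e-9
  cls <- cut(d, brk, labels = FALSE)

  # merge small classes downward
  repeat {
    sizes <- tabulate(cls, nbins = max(cls))
    small <- which(sizes > 0L & sizes < min_pairs)
    if (!length(small) || length(unique(cls)) <= 1L) break
    s <- small[1]
    nb <- if (s > 1L) s - 1L else min(cls[cls > s])
    warning("distance class ", s, " has ", sizes[s],
            " pairs; merged into neighbour")
    cls[cls == s] <- nb
    cls <- match(cls, sort(unique(cls)))
  }
  klev <- sort(unique(cls))
  vgen <- Dgen[ut]
  res <- data.frame(upper = numeric(0), n_pairs = integer(0),
                    r = numeric(0), p = numeric(0))
  for (k in klev) {
    ind <- matrix(0, n, n)
    ind[ut][cls == k] <- 1
    ind <- ind + t(ind)
    vind <- ind[ut]
    if (stats::sd(vind) == 0) {          # degenerate single-class case
      res <- rbind(res, data.frame(upper = max(d[cls == k]),
                                   n_pairs = sum(cls == k), r = NA_real_,
                                   p = NA_real_))
      next
    }
    r <- -stats::cor(vind, vgen)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      rp <- -stats::cor(ind[perm, perm][ut], vgen)
      if (abs(rp) >= abs(r) - 1e-12) cnt <- cnt + 1L
    }
    res <- rbind(res, data.frame(upper = max(d[cls == k]),
                                 n_pairs = sum(cls == k), r = r,
                                 p = (cnt + 1) / (n_perm + 1)))
  }
  # progressive Holm in increasing-distance order (Legendre & Legendre)
  m <- nrow(res)
  res$p_holm <- vapply(seq_len(m), function(i)
    max(stats::p.adjust(res$p[seq_len(i)], method = "holm")[i], res$p[i]),
    0)
  class(res) <- c("mantel_correlogram", "data.frame")
  res
}
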