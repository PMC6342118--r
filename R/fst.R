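#' Pairwise multilocus Weir-Cockerham F_ST
#'
#' Estimates theta (Weir & Cockerham 1984) for every pair of groups:
#' per-allele, per-locus variance components a (among populations),
#' b (among individuals within populations) and c (within individuals)
#' are summed over alleles and loci, and the multilocus estimate is
#' `sum(a) / sum(a + b + c)`. Significance is assessed by permuting
#' individuals between the two groups; `p = (#{theta_perm >= theta_obs} + 1)
#' / (n_perm + 1)`.
#'
#' @param x a [genotype_table()].
#' @param groups optional labels (defaults to `x$group`).
#' @param n_perm permutations per pair (default 999); 0 skips the test.
#' @return list of class `fst_matrix`: `groups`, `theta` (symmetric matrix,
#'   zero diagonal), `p` (matrix, `NA` diagonal).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
weir_cockerham_fst <- function(x, groups = NULL, n_perm = 999L) {
  g <- gt_groups(x, groups)
  glev <- unique(g)
  if (length(glev) < 2L) stop("need at least 2 groups")
  small <- names(which(table(g) < 2L))
  if (length(small))
    stop("group(s) with < 2 individuals: ", paste(small, collapse = ", "))
  k <- length(glev)
  theta <- matrix(0, k, k, dimnames = list(glev, glev))
  pmat <- matrix(NA_real_, k, k, dimnames = list(glev, glev))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    rows <- which(g %in% glev[c(i, j)])
    sub <- x$alleles[rows, , , drop = FALSE]
    gg <- g[rows]
    th <- wc_theta(sub, gg)
    theta[i, j] <- theta[j, i] <- th
    if (n_perm > 0L) {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        if (wc_theta(sub, sample(gg)) >= th) cnt <- cnt + 1L
      }
      pmat[i, j] <- pmat[j, i] <- (cnt + 1) / (n_perm + 1)
    }
  }
  structure(list(groups = glev, theta = theta, p = pmat, n_perm = n_perm),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Pairwise Weir-Cockerham theta:\n")
  print(round(x$theta, 4))
  if (x$n_perm > 0L) {
    cat("permutation p (", x$n_perm, " perms):\n", sep = "")
    print(round(x$p, 4))
  }
  invisible(x)
}

# multilocus theta from an n x L x 2 allele array and group labels;
# variance components per W&C (1984) eq. 2-4, summed over alleles and loci
wc_theta <- function(alleles, g) {
  glev <- unique(g)
  r <- length(glev)
  num <- 0; den <- 0
  L <- dim(alleles)[2]
  for (l in seq_len(L)) {
    A1 <- alleles[, l, 1L]; A2 <- alleles[, l, 2L]
    ok <- !is.na(A1)
    if (!any(ok)) next
    gg <- g[ok]; A1 <- A1[ok]; A2 <- A2[ok]
    ni <- as.numeric(table(factor(gg, glev)))
    if (sum(ni > 0L) < 2L) next
    use <- ni > 0
    glev_l <- glev[use]; ni <- ni[use]; rl <- length(ni)
    nbar <- mean(ni)
    nc <- (rl * nbar - sum(ni^2) / (rl * nbar)) / (rl - 1)
    allele_set <- sort(unique(c(A1, A2)))
    gi <- match(gg, glev_l)
    for (al in allele_set) {
      cnt <- tabulate(gi[A1 == al], rl) + tabulate(gi[A2 == al], rl)
      p_i <- cnt / (2 * ni)
      het_i <- tabulate(gi[(A1 == al) != (A2 == al)], rl) / ni
      pbar <- sum(ni * p_i) / (rl * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((rl - 1) * nbar)
      hbar <- sum(ni * het_i) / (rl * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (rl - 1) / rl * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (rl - 1) / rl * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) return(0)
  num / den
}
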