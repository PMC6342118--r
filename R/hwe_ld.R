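#' Exact Hardy-Weinberg probability test (Monte Carlo)
#'
#' The probability test of Haldane/Levene: conditional on the observed
#' allele counts, the p-value is the total probability of genotype tables
#' whose conditional probability is less than or equal to that of the
#' observed table. The null distribution is sampled by shuffling the 2n
#' gene copies and re-pairing them (`n_mc` tables); the estimate carries
#' the usual `(k+1)/(n_mc+1)` correction.
#'
#' @param x a [genotype_table()].
#' @param group group label to test (`NULL` = all individuals).
#' @param locus locus name or index.
#' @param n_mc number of Monte-Carlo tables (>= 100).
#' @return the p-value. Monomorphic loci return `p = 1` by convention.
#' @export
hwe_exact_test <- function(x, group = NULL, locus, n_mc = 1999L) {
  if (n_mc < 100L) stop("n_mc < 100 gives an unstable estimate")
  rows <- if (is.null(group)) seq_len(n_ind(x)) else
    which(gt_groups(x, NULL) == group)
  l <- if (is.character(locus)) match(locus, x$loci) else as.integer(locus)
  if (is.na(l)) stop("unknown locus")
  a1 <- x$alleles[rows, l, 1L]; a2 <- x$alleles[rows, l, 2L]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  genes <- c(a1, a2)
  if (length(unique(genes)) < 2L) return(1)
  n <- length(a1)
  obs <- hwe_log_prob(a1, a2)
  cnt <- 0L
  for (b in seq_len(n_mc)) {
    perm <- sample(genes)
    lp <- hwe_log_prob(perm[seq_len(n)], perm[n + seq_len(n)])
    if (lp <= obs + 1e-9) cnt <- cnt + 1L
  }
  (cnt + 1) / (n_mc + 1)
}

# log conditional probability of the genotype table given allele counts
# (Levene 1949): log[ n! 2^h / prod(n_jk!) ] (the allele-count term is
# constant under the conditioning and omitted)
hwe_log_prob <- function(a1, a2) {
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  tab <- table(paste(lo, hi))
  h <- sum(lo != hi)
  lgamma(length(a1) + 1) + h * log(2) - sum(lgamma(as.numeric(tab) + 1))
}

#' Linkage-equilibrium permutation test for a pair of loci
#'
#' The statistic is the G-statistic (likelihood-ratio chi-square) of the
#' contingency table of unordered genotype classes at the two loci,
#' computed over individuals complete at both. The null distribution is
#' obtained by permuting one locus's genotypes among individuals.
#'
#' @param x a [genotype_table()].
#' @param group group label (`NULL` = all individuals).
#' @param locus_pair two locus names or indices.
#' @param n_perm permutations (default 999).
#' @return list with `G`, `p`, `n`.
#' @export
ld_permutation_test <- function(x, group = NULL, locus_pair, n_perm = 999L) {
  rows <- if (is.null(group)) seq_len(n_ind(x)) else
    which(gt_groups(x, NULL) == group)
  li <- vapply(locus_pair, function(l)
    if (is.character(l)) match(l, x$loci) else as.integer(l), 0L)
  if (any(is.na(li)) || length(li) != 2L) stop("locus_pair must name 2 loci")
  gclass <- function(l) {
    a1 <- x$alleles[rows, l, 1L]; a2 <- x$alleles[rows, l, 2L]
    paste(pmin(a1, a2), pmax(a1, a2))
  }
  g1 <- gclass(li[1]); g2 <- gclass(li[2])
  ok <- !grepl("NA", g1) & !grepl("NA", g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L)
    stop("both loci need >= 2 genotype classes in the group")
  G <- g_stat(g1, g2)
  cnt <- 0L
  for (b in seq_len(n_perm)) if (g_stat(g1, sample(g2)) >= G - 1e-12)
    cnt <- cnt + 1L
  list(G = G, p = (cnt + 1) / (n_perm + 1), n = length(g1))
}

# G = 2 sum O log(O/E) over cells of the two-way table
g_stat <- function(f1, f2) {
  tab <- table(f1, f2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  O <- as.numeric(tab); E <- as.numeric(E)
  nz <- O > 0
  2 * sum(O[nz] * log(O[nz] / E[nz]))
}

#' Holm sequential Bonferroni correction
#'
#' Step-down Holm procedure: with m p-values sorted ascending, reject while
#' `p_(i) <= alpha / (m - i + 1)`. The rejection set is always a prefix of
#' the sorted order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha familywise error rate (default 0.05).
#' @return logical vector of rejection flags, aligned with `pvals`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm") <= alpha
}
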