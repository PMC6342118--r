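#' Per-group, per-locus allele frequencies
#'
#' Missing genotypes are excluded from the denominators; frequencies are
#' over observed alleles only and sum to one per locus per group. A locus
#' with no complete genotype in a group is reported as `NULL` (absent) for
#' that group.
#'
#' @param x a [genotype_table()].
#' @param groups optional per-individual labels (defaults to `x$group`).
#' @return nested list: `result[[group]][[locus]]` is a named numeric vector
#'   of frequencies (names = allele codes), or `NULL` if the locus has no
#'   data in the group. Attribute `n_genes` holds the gene counts
#'   (2 x complete genotypes) as a group x locus matrix.
#' @export
allele_frequencies <- function(x, groups = NULL) {
  g <- gt_groups(x, groups)
  glev <- unique(g)
  if (any(!table(g) >= 1L)) stop("empty group")
  L <- n_loci(x)
  ngenes <- matrix(0L, length(glev), L, dimnames = list(glev, x$loci))
  out <- stats::setNames(vector("list", length(glev)), glev)
  for (gi in seq_along(glev)) {
    rows <- which(g == glev[gi])
    res <- stats::setNames(vector("list", L), x$loci)
    for (l in seq_len(L)) {
      al <- c(x$alleles[rows, l, 1L], x$alleles[rows, l, 2L])
      al <- al[!is.na(al)]
      ngenes[gi, l] <- length(al)
      if (length(al)) {
        tab <- table(al)
        res[[l]] <- stats::setNames(as.numeric(tab) / length(al), names(tab))
      }
    }
    out[[gi]] <- res
  }
  attr(out, "n_genes") <- ngenes
  out
}
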