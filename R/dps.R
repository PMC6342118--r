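#' Proportion-of-shared-alleles genetic distance (Dps)
#'
#' For each pair of individuals, the proportion of shared alleles is the
#' summed multiset intersection of their allele pairs over loci complete in
#' both, divided by twice the number of such loci; the dissimilarity is
#' `D = 1 - PSA` (Bowcock et al. 1994). This is the default individual
#' genetic distance of MEM-based spatial genetic analysis.
#'
#' @param x a [genotype_table()].
#' @return `n x n` symmetric matrix of class `genetic_distance` with zero
#'   diagonal and entries in `[0, 1]`; attribute `method = "Dps"`.
#' @export
dps_distance <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  n <- n_ind(x); L <- n_loci(x)
  if (n < 2L) stop("need n >= 2")
  shared <- matrix(0, n, n)
  complete <- matrix(0, n, n)
  for (l in seq_len(L)) {
    a1 <- x$alleles[, l, 1L]; a2 <- x$alleles[, l, 2L]
    ok <- !is.na(a1)
    if (!any(ok)) next
    # shared alleles between unordered pairs {a1i,a2i} and {a1j,a2j}:
    # max over the two alignments equals the multiset intersection size
    e11 <- outer(a1, a1, "=="); e22 <- outer(a2, a2, "==")
    e12 <- outer(a1, a2, "=="); e21 <- outer(a2, a1, "==")
    s <- pmax(e11 + e22, e12 + e21)
    okp <- outer(ok, ok, "&")
    s[!okp] <- 0
    shared <- shared + s
    complete <- complete + okp
  }
  if (any(complete[upper.tri(complete)] == 0)) {
    w <- which(complete == 0 & upper.tri(complete), arr.ind = TRUE)
    stop("pair(s) with zero jointly complete loci: ",
         paste(apply(utils::head(w, 5L), 1L, function(r)
           paste0(x$id[r[1]], "/", x$id[r[2]])), collapse = ", "))
  }
  D <- 1 - shared / (2 * complete)
  diag(D) <- 0
  dimnames(D) <- list(x$id, x$id)
  structure(D, method = "Dps", class = c("genetic_distance", "matrix"))
}
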