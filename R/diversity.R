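#' Genetic diversity summary per group
#'
#' Per-locus and per-group expected heterozygosity with the unbiased
#' small-sample correction (`He = 2n/(2n-1) * (1 - sum p^2)`, Nei 1978),
#' observed heterozygosity, allele counts, allelic richness rarefied to the
#' smallest per-locus gene count across groups (hypergeometric rarefaction,
#' El Mousadik & Petit 1996), and the inbreeding coefficient
#' `F_IS = 1 - Ho/He`. Multilocus values combine loci by summing the
#' heterozygosity components before taking the ratio. The `F_IS` p-value is
#' two-sided, from permuting the 2n gene copies among individuals within
#' the group.
#'
#' @param x a [genotype_table()].
#' @param groups optional labels (defaults to `x$group`).
#' @param n_perm permutations for the F_IS test (default 999); 0 skips it.
#' @param rarefy_to gene count for rarefaction; default the minimum
#'   per-locus complete-gene count over groups. Loci where that minimum is
#'   below 2 genes are dropped from A_r with a warning.
#' @return list of class `diversity_summary` with per-group data frames
#'   (`per_locus`) and a `multilocus` data frame (He, Ho, A_mean, Ar_mean,
#'   Fis, p_Fis, n).
#' @export
diversity_stats <- function(x, groups = NULL, n_perm = 999L,
                            rarefy_to = NULL) {
  g <- gt_groups(x, groups)
  glev <- unique(g)
  L <- n_loci(x)

  # complete-genotype gene counts per group x locus
  ngenes <- matrix(0L, length(glev), L, dimnames = list(glev, x$loci))
  for (gi in seq_along(glev)) {
    rows <- g == glev[gi]
    ngenes[gi, ] <- 2L * colSums(!is.na(x$alleles[rows, , 1L, drop = FALSE]))
  }
  gmin <- if (is.null(rarefy_to)) apply(ngenes, 2L, min) else
    rep_len(as.integer(rarefy_to), L)
  drop_ar <- gmin < 2L
  if (any(drop_ar))
    warning("rarefaction size < 2 genes; A_r dropped for locus/loci: ",
            paste(x$loci[drop_ar], collapse = ", "))

  per_locus <- stats::setNames(vector("list", length(glev)), glev)
  multi <- data.frame()
  for (gi in seq_along(glev)) {
    rows <- which(g == glev[gi])
    he <- ho <- ar <- rep(NA_real_, L)
    A <- rep(NA_integer_, L)
    nl <- integer(L)
    for (l in seq_len(L)) {
      a1 <- x$alleles[rows, l, 1L]; a2 <- x$alleles[rows, l, 2L]
      ok <- !is.na(a1)
      nl[l] <- sum(ok)
      if (!nl[l]) next
      al <- c(a1[ok], a2[ok])
      tab <- table(al)
      p <- as.numeric(tab) / length(al)
      n <- nl[l]
      he[l] <- if (n > 0) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA
      ho[l] <- mean(a1[ok] != a2[ok])
      A[l] <- length(tab)
      if (!drop_ar[l])
        ar[l] <- rarefied_richness(as.integer(tab), gmin[l])
    }
    per_locus[[gi]] <- data.frame(locus = x$loci, n = nl, He = he, Ho = ho,
                                  A = A, Ar = ar,
                                  Fis = ifelse(he > 0, 1 - ho / he, NA))
    ok <- !is.na(he) & he > 0
    He_m <- sum(he[ok]); Ho_m <- sum(ho[ok])
    fis <- 1 - Ho_m / He_m
    p_fis <- NA_real_
    if (n_perm > 0L && is.finite(fis)) {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        fperm <- fis_permuted(x$alleles[rows, , , drop = FALSE])
        if (is.finite(fperm) && abs(fperm) >= abs(fis)) cnt <- cnt + 1L
      }
      p_fis <- (cnt + 1) / (n_perm + 1)
    }
    multi <- rbind(multi, data.frame(
      group = glev[gi], n = length(rows),
      He = He_m / sum(ok), Ho = Ho_m / sum(ok),
      A_mean = mean(A, na.rm = TRUE), Ar_mean = mean(ar, na.rm = TRUE),
      Fis = fis, p_Fis = p_fis))
  }
  structure(list(per_locus = per_locus, multilocus = multi,
                 rarefy_to = gmin), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("Multilocus diversity by group:\n")
  print(x$multilocus, digits = 3, row.names = FALSE)
  invisible(x)
}

# expected number of distinct alleles in a sample of g genes drawn without
# replacement from counts `cnt` (hypergeometric rarefaction)
rarefied_richness <- function(cnt, g) {
  N <- sum(cnt)
  if (g > N) g <- N
  # 1 - choose(N - Na, g)/choose(N, g), via lchoose for stability
  sum(1 - exp(lchoose(N - cnt, g) - lchoose(N, g)))
}

# multilocus Fis after shuffling gene copies among individuals within group
fis_permuted <- function(alleles) {
  L <- dim(alleles)[2]
  He <- 0; Ho <- 0; used <- 0L
  for (l in seq_len(L)) {
    a1 <- alleles[, l, 1L]; a2 <- alleles[, l, 2L]
    ok <- !is.na(a1)
    n <- sum(ok)
    if (n < 1L) next
    genes <- sample(c(a1[ok], a2[ok]))
    b1 <- genes[seq_len(n)]; b2 <- genes[n + seq_len(n)]
    tab <- table(genes)
    p <- as.numeric(tab) / (2 * n)
    he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    if (he > 0) {
      He <- He + he; Ho <- Ho + mean(b1 != b2); used <- used + 1L
    }
  }
  if (!used || He == 0) return(NA_real_)
  1 - Ho / He
}
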