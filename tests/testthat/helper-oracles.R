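# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (loops, explicit formulas, dense algebra)
# so they share no code path with the package implementation.

# number of loci at which two individuals' unordered allele pairs differ,
# counting loci missing in either sample as mismatches
oracle_mismatch_count <- function(tab, i, j) {
  L <- n_loci(tab)
  mism <- 0L
  for (l in seq_len(L)) {
    a <- sort(tab$alleles[i, l, ]); b <- sort(tab$alleles[j, l, ])
    if (length(a) < 2 || length(b) < 2) { mism <- mism + 1L; next }
    if (anyNA(tab$alleles[i, l, ]) || anyNA(tab$alleles[j, l, ])) {
      mism <- mism + 1L
    } else if (!all(a == b)) mism <- mism + 1L
  }
  mism
}

# Weir & Cockerham (1984) theta, written as a direct loop transcription of
# the published variance-component formulas
oracle_wc_theta <- function(tab, groups) {
  glev <- unique(groups)
  num <- 0; den <- 0
  for (l in seq_len(n_loci(tab))) {
    a1 <- tab$alleles[, l, 1]; a2 <- tab$alleles[, l, 2]
    keep <- !is.na(a1)
    g <- groups[keep]; x1 <- a1[keep]; x2 <- a2[keep]
    pops <- unique(g)
    ni <- sapply(pops, function(p) sum(g == p))
    if (sum(ni > 0) < 2) next
    r <- length(pops)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (al in unique(c(x1, x2))) {
      p_i <- sapply(pops, function(p) {
        gi <- g == p
        (sum(x1[gi] == al) + sum(x2[gi] == al)) / (2 * sum(gi))
      })
      h_i <- sapply(pops, function(p) {
        gi <- g == p
        mean((x1[gi] == al) != (x2[gi] == al))
      })
      pbar <- sum(ni * p_i) / (r * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) -
                                  (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# pairwise 1 - proportion of shared alleles, multiset intersection by
# explicit allele-by-allele matching with removal
oracle_dps <- function(tab) {
  n <- n_ind(tab)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    shared <- 0; loci <- 0
    for (l in seq_len(n_loci(tab))) {
      a <- tab$alleles[i, l, ]; b <- tab$alleles[j, l, ]
      if (anyNA(a) || anyNA(b)) next
      loci <- loci + 1
      pool <- as.vector(b)
      for (x in a) {
        hit <- match(x, pool)
        if (!is.na(hit)) { shared <- shared + 1; pool <- pool[-hit] }
      }
    }
    D[i, j] <- D[j, i] <- 1 - shared / (2 * loci)
  }
  D
}

# explicit Gower double centering via the centering matrix
gower_double_center_oracle <- function(D) {
  n <- nrow(D)
  H <- diag(n) - matrix(1 / n, n, n)
  H %*% (-0.5 * D^2) %*% H
}

# dense MEM construction: explicit centering matrix and base eigen()
oracle_mem <- function(D, truncation) {
  n <- nrow(D)
  Dstar <- D
  Dstar[Dstar > truncation] <- 4 * truncation
  diag(Dstar) <- 0
  H <- diag(n) - matrix(1 / n, n, n)
  G <- H %*% (-0.5 * Dstar^2) %*% H
  eigen((G + t(G)) / 2, symmetric = TRUE)
}

# O(V^2) Dijkstra over an 8-connected cost grid, built independently of
# the package's graph construction
oracle_cost_dist <- function(cost, cell_size, from_rc, to_rc) {
  nr <- nrow(cost); nc <- ncol(cost)
  V <- nr * nc
  id <- function(r, c) (c - 1) * nr + r
  dist <- rep(Inf, V)
  done <- rep(FALSE, V)
  dist[id(from_rc[1], from_rc[2])] <- 0
  moves <- cbind(r = c(-1, 1, 0, 0, -1, -1, 1, 1),
                 c = c(0, 0, -1, 1, -1, 1, -1, 1))
  for (it in seq_len(V)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    ur <- ((u - 1) %% nr) + 1; uc <- ((u - 1) %/% nr) + 1
    for (m in seq_len(8)) {
      vr <- ur + moves[m, 1]; vc <- uc + moves[m, 2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      v <- id(vr, vc)
      w <- (cost[ur, uc] + cost[vr, vc]) / 2 * cell_size *
        if (m > 4) sqrt(2) else 1
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist[id(to_rc[1], to_rc[2])]
}

# expected distinct alleles over all subsets of g genes, by enumeration
oracle_rarefaction <- function(genes, g) {
  subs <- utils::combn(length(genes), g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# small genotype table built from a character matrix like "101/102"
make_gt <- function(geno, xy = NULL, ...) {
  n <- nrow(geno); L <- ncol(geno)
  arr <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    if (is.na(geno[i, l])) next
    parts <- as.integer(strsplit(geno[i, l], "/")[[1]])
    arr[i, l, ] <- parts
  }
  genotype_table(id = sprintf("i%02d", seq_len(n)), alleles = arr,
                 xy = xy, ...)
}

# deterministic random genotype table at Hardy-Weinberg
random_gt <- function(n, L = 9, n_alleles = 6, seed = 1, miss = 0) {
  set.seed(seed)
  arr <- array(sample(seq(11, by = 1, length.out = n_alleles),
                      n * L * 2, replace = TRUE), c(n, L, 2))
  if (miss > 0) {
    drop <- which(matrix(runif(n * L) < miss, n, L), arr.ind = TRUE)
    for (k in seq_len(nrow(drop))) arr[drop[k, 1], drop[k, 2], ] <- NA
  }
  genotype_table(id = sprintf("i%03d", seq_len(n)), alleles = arr,
                 xy = cbind(runif(n), runif(n)))
}
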