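test_that("allele frequencies match direct counting", {
  tab <- make_gt(rbind(c("1/1"), c("1/2")), group = c("g", "g"))
  af <- allele_frequencies(tab)
  expect_equal(af$g$L1, c("1" = 0.75, "2" = 0.25))
  # all-missing locus flagged absent
  tab2 <- make_gt(rbind(c("1/1", NA), c("1/2", NA)), group = c("g", "g"))
  af2 <- allele_frequencies(tab2)
  expect_null(af2$g$L2)
  # exhaustive enumeration oracle on a larger fixture
  tab3 <- random_gt(20, L = 4, seed = 11, miss = 0.15)
  af3 <- allele_frequencies(tab3, groups = rep("all", 20))
  for (l in 1:4) {
    genes <- c(tab3$alleles[, l, 1], tab3$alleles[, l, 2])
    genes <- genes[!is.na(genes)]
    cnt <- sapply(sort(unique(genes)), function(a) sum(genes == a))
    expect_equal(unname(af3$all[[l]]),
                 unname(cnt / sum(cnt)))
    expect_equal(sum(af3$all[[l]]), 1)
  }
})

test_that("Weir-Cockerham theta agrees with the independent oracle", {
  # identical groups: the estimator is slightly negative by construction
  # (s2 = 0 makes the among-population component a = -(pq - h/4)/(n-1));
  # implementation must agree with the independent oracle exactly
  tab <- random_gt(20, L = 6, seed = 2)
  tab$alleles[11:20, , ] <- tab$alleles[1:10, , ]
  g <- rep(c("A", "B"), each = 10)
  fst <- weir_cockerham_fst(tab, groups = g, n_perm = 0)
  expect_lte(fst$theta["A", "B"], 0)
  expect_gt(fst$theta["A", "B"], -0.1)
  expect_equal(fst$theta["A", "B"], oracle_wc_theta(tab, g),
               tolerance = 1e-12, ignore_attr = TRUE)

  # divergent allele frequencies: match the loop-transcribed 1984 formulas
  set.seed(31)
  arr <- array(NA_integer_, c(20, 5, 2))
  for (l in 1:5) {
    arr[1:10, l, ] <- sample(c(11L, 12L), 20, TRUE, prob = c(0.9, 0.1))
    arr[11:20, l, ] <- sample(c(11L, 12L, 13L), 20, TRUE,
                              prob = c(0.2, 0.5, 0.3))
  }
  tab2 <- genotype_table(sprintf("i%d", 1:20), arr)
  fst2 <- weir_cockerham_fst(tab2, groups = g, n_perm = 0)
  expect_equal(fst2$theta["A", "B"], oracle_wc_theta(tab2, g),
               tolerance = 1e-10)
  # theta invariant to allele relabeling
  relab <- tab2
  relab$alleles[] <- relab$alleles + 500L
  fst3 <- weir_cockerham_fst(relab, groups = g, n_perm = 0)
  expect_equal(fst3$theta, fst2$theta, tolerance = 1e-12)
})

test_that("fst permutation p-values detect real differentiation", {
  sim <- simulate_population(sim_config(n_individuals = 80,
                                        scenario = "ibr",
                                        barrier_multiplier = 10,
                                        seed = 8))
  tab <- sim$table
  set.seed(1)
  fst <- weir_cockerham_fst(tab, n_perm = 99)
  expect_gt(fst$theta[1, 2], 0)
  expect_lte(fst$p[1, 2], 0.05)
  expect_error(weir_cockerham_fst(tab, groups = c("A", rep("B", 79))),
               "< 2 individuals")
})

test_that("diversity statistics use the unbiased estimator", {
  # monomorphic locus
  mono <- make_gt(cbind(rep("7/7", 5)), group = rep("g", 5))
  dv <- diversity_stats(mono, n_perm = 0)
  expect_equal(dv$per_locus$g$He, 0)
  expect_equal(dv$per_locus$g$Ho, 0)
  expect_equal(dv$per_locus$g$A, 1L)

  # five AB heterozygotes: He = 0.5 * 10/9, Ho = 1, Fis < 0
  het <- make_gt(cbind(rep("1/2", 5)), group = rep("g", 5))
  set.seed(5)
  dvh <- diversity_stats(het, n_perm = 199)
  expect_equal(dvh$per_locus$g$He, 0.5 * 10 / 9, tolerance = 1e-12)
  expect_equal(dvh$per_locus$g$Ho, 1)
  expect_lt(dvh$multilocus$Fis, 0)

  # rarefied richness equals exhaustive subsampling on a 6-individual
  # fixture
  tab <- random_gt(6, L = 2, n_alleles = 4, seed = 13)
  g <- rep("g", 6)
  dv6 <- diversity_stats(tab, groups = g, n_perm = 0, rarefy_to = 6)
  for (l in 1:2) {
    genes <- c(tab$alleles[, l, 1], tab$alleles[, l, 2])
    expect_equal(dv6$per_locus$g$Ar[l], oracle_rarefaction(genes, 6),
                 tolerance = 1e-10)
  }
  expect_true(all(dv6$per_locus$g$Ar <= dv6$per_locus$g$A))
})

test_that("HWE probability test behaves at its extremes", {
  mono <- make_gt(cbind(rep("7/7", 10)), group = rep("g", 10))
  expect_equal(hwe_exact_test(mono, "g", 1, n_mc = 200), 1)
  # 50 heterozygotes: massive heterozygote excess
  het <- make_gt(cbind(rep("1/2", 50)), group = rep("g", 50))
  set.seed(2)
  expect_lt(hwe_exact_test(het, "g", 1, n_mc = 999), 0.001 + 1e-9)
  expect_error(hwe_exact_test(het, "g", 1, n_mc = 50), "unstable")
})

test_that("HWE test p-values are ~uniform under the null", {
  set.seed(42)
  ps <- replicate(120, {
    tab <- random_gt(60, L = 1, n_alleles = 4,
                     seed = sample.int(1e6, 1))
    hwe_exact_test(tab, group = NULL, locus = 1, n_mc = 199)
  })
  # MC p-values are discrete, so ties are expected; the KS statistic is
  # still a valid summary of gross non-uniformity
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("linkage test statistic matches the hand G formula", {
  # 2x2 genotype-class fixture
  g1 <- c(rep("1/1", 6), rep("1/2", 4))
  g2 <- c(rep("3/3", 5), rep("3/4", 5))
  tab <- make_gt(cbind(g1, g2))
  set.seed(3)
  res <- ld_permutation_test(tab, locus_pair = c(1, 2), n_perm = 99)
  O <- table(g1, g2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  G_hand <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
  expect_equal(res$G, G_hand, tolerance = 1e-12)

  # perfectly linked loci attain the permutation lower bound
  tabl <- random_gt(40, L = 1, n_alleles = 5, seed = 77)
  arr <- array(NA_integer_, c(40, 2, 2))
  arr[, 1, ] <- tabl$alleles[, 1, ]
  arr[, 2, ] <- tabl$alleles[, 1, ] + 100L
  linked <- genotype_table(tabl$id, arr)
  set.seed(4)
  resl <- ld_permutation_test(linked, locus_pair = c(1, 2), n_perm = 199)
  expect_equal(resl$p, 1 / 200)
})

test_that("Holm step-down rejects the documented prefix", {
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.2), alpha = 0.05),
               c(TRUE, TRUE, FALSE))
  expect_equal(holm_bonferroni(rep(1, 5)), rep(FALSE, 5))
  expect_equal(holm_bonferroni(0.04), TRUE)
  expect_equal(holm_bonferroni(0.06), FALSE)
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})
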