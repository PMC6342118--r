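test_that("GENEPOP files decode POP blocks, alleles and missing codes", {
  gp <- c("toy microsat data",
          "LocA", "LocB",
          "POP",
          "a1 , 0101 0102",
          "a2 , 0102 0000",
          "POP",
          "b1 , 0303 0304",
          "b2 , 0304 0303")
  f <- withr::local_tempfile(lines = gp, fileext = ".gen")
  tab <- read_genepop(f)
  expect_equal(n_ind(tab), 4L)
  expect_equal(n_loci(tab), 2L)
  expect_equal(tab$loci, c("LocA", "LocB"))
  expect_equal(unique(tab$group), c("POP1", "POP2"))
  # "0000" decodes to a fully missing genotype
  expect_true(all(is.na(tab$alleles[2, 2, ])))
  expect_equal(tab$alleles[1, 1, ], c(1L, 1L))
  expect_equal(tab$alleles[3, 2, ], c(3L, 4L))
})

test_that("GENEPOP parser rejects malformed rows with line numbers", {
  bad <- c("title", "L1", "L2", "L3", "POP", "x1 , 0101 0202")
  f <- withr::local_tempfile(lines = bad, fileext = ".gen")
  expect_error(read_genepop(f), "2 genotype fields but 3 loci")
  mixed <- c("title", "L1", "L2", "POP", "x1 , 0101 010101")
  f2 <- withr::local_tempfile(lines = mixed, fileext = ".gen")
  expect_error(read_genepop(f2), "4 \\(2-digit\\) or 6 \\(3-digit\\)")
})

test_that("delimited genotype tables round-trip exactly", {
  tab <- random_gt(10, L = 9, seed = 3, miss = 0.1)
  tab$sex <- rep(c("F", "M"), 5)
  tab$xy <- round(tab$xy * 1e5, 6)   # 6-decimal meters, the stored precision
  tab$xy[3, 1] <- NA
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(tab, f)
  back <- read_genotype_table(f)
  expect_identical(back$alleles, tab$alleles)
  expect_equal(back$xy, tab$xy, tolerance = 1e-12)
  expect_identical(back$id, tab$id)
  expect_identical(back$sex, tab$sex)
})

test_that("table reader rejects duplicated ids and non-integer alleles", {
  hdr <- "id\tsex\tx\ty\tL1_1\tL1_2"
  f <- withr::local_tempfile(
    lines = c(hdr, "a\tF\t0\t0\t1\t2", "a\tM\t1\t1\t3\t4"))
  expect_error(read_genotype_table(f), "duplicated id")
  f2 <- withr::local_tempfile(
    lines = c(hdr, "a\tF\t0\t0\tA\t2"))
  expect_error(read_genotype_table(f2), "non-integer allele")
})

test_that("half-missing genotypes are rejected at construction", {
  arr <- array(1L, c(2, 1, 2))
  arr[1, 1, 2] <- NA
  expect_error(genotype_table(c("a", "b"), arr), "half-missing")
})

test_that("duplicate matching applies the 8-of-9 threshold exactly", {
  base <- random_gt(1, L = 9, seed = 5)
  a <- base$alleles[1, , ]
  perturb <- function(g, loci) {   # change the allele pair at given loci
    for (l in loci) g[l, ] <- g[l, ] + 100L
    g
  }
  arr <- array(NA_integer_, c(3, 9, 2))
  arr[1, , ] <- a
  arr[2, , ] <- perturb(a, 1)       # differs at 1 locus: 8/9 match
  arr[3, , ] <- perturb(a, 8:9)     # differs at 2 loci from both others
  tab <- genotype_table(c("s1", "s2", "s3"), arr,
                        xy = cbind(c(0, 2, 10), c(0, 2, 10)))
  md <- match_duplicates(tab, min_matching_loci = 8)
  expect_equal(md$report$n_unique, 2L)
  expect_equal(md$report$cluster_map[1], md$report$cluster_map[2])
  expect_false(md$report$cluster_map[1] == md$report$cluster_map[3])
  # merged representative carries the member centroid
  expect_equal(md$table$xy[1, ], c(x = 1, y = 1))
  # agreement with the exhaustive pairwise mismatch oracle
  expect_equal(oracle_mismatch_count(tab, 1, 2), 1L)
  expect_equal(oracle_mismatch_count(tab, 1, 3), 2L)
})

test_that("identical genotypes always merge and missing loci do not count", {
  tab <- random_gt(2, L = 9, seed = 7)
  tab$alleles[2, , ] <- tab$alleles[1, , ]
  md <- match_duplicates(tab)
  expect_equal(md$report$n_unique, 1L)
  # set one locus missing in one copy: 8 matching loci still merges,
  # a second missing locus (7 matches) does not
  tab$alleles[2, 1, ] <- NA
  expect_equal(match_duplicates(tab)$report$n_unique, 1L)
  tab$alleles[2, 2, ] <- NA
  expect_equal(match_duplicates(tab)$report$n_unique, 2L)
  # unless missing loci are treated as uninformative
  expect_equal(match_duplicates(tab, ignore_missing = TRUE)$report$n_unique,
               1L)
})

test_that("duplicate matching is idempotent and order-invariant", {
  # short panmictic run keeps founder diversity high, so the only
  # 8-of-9 matches are the planted ones
  sim <- simulate_population(sim_config(n_individuals = 60, seed = 21,
                                        scenario = "panmixia",
                                        n_generations = 20,
                                        duplicate_rate = 0.2))
  md <- match_duplicates(sim$table)
  expect_equal(md$report$n_unique, 60L)
  md2 <- match_duplicates(md$table)
  expect_equal(md2$report$n_unique, md$report$n_unique)
  expect_identical(md2$table$alleles, md$table$alleles)
  set.seed(99)
  perm <- sample(n_ind(sim$table))
  mdp <- match_duplicates(sim$table[perm])
  expect_equal(mdp$report$n_unique, md$report$n_unique)
})

test_that("matching with fewer loci than the threshold errors", {
  tab <- random_gt(3, L = 5, seed = 1)
  expect_error(match_duplicates(tab, min_matching_loci = 8), "exceeds")
})
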