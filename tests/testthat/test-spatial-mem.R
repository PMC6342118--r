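test_that("Dps distance counts shared alleles per multiset convention", {
  expect_equal(dps_distance(make_gt(rbind("1/2", "1/2")))[1, 2], 0)
  expect_equal(dps_distance(make_gt(rbind("1/2", "3/4")))[1, 2], 1)
  # single locus AB vs AC shares 1 of 2 alleles
  expect_equal(dps_distance(make_gt(rbind("1/2", "1/3")))[1, 2], 0.5)
  # heterozygote order must not matter
  expect_equal(dps_distance(make_gt(rbind("2/1", "1/2")))[1, 2], 0)
  # full-matrix agreement with the brute-force pair oracle
  tab <- random_gt(15, L = 5, seed = 17, miss = 0.1)
  expect_equal(unclass(dps_distance(tab)), oracle_dps(tab),
               ignore_attr = TRUE, tolerance = 1e-12)
  # a pair with no jointly complete locus is an error
  tab2 <- random_gt(3, L = 2, seed = 18)
  tab2$alleles[1, 1, ] <- NA
  tab2$alleles[2, 2, ] <- NA
  expect_error(dps_distance(tab2), "zero jointly complete")
})

test_that("principal coordinates reproduce Euclidean configurations", {
  set.seed(19)
  pts <- cbind(runif(5), runif(5))
  D <- euclidean_distance(pts)
  pc <- pcoa(D)
  expect_equal(as.matrix(dist(pc$coords)), D, ignore_attr = TRUE,
               tolerance = 1e-8)
  # points on a line: a single retained axis
  line <- cbind(c(0, 1, 2, 3.5), 0)
  pcl <- pcoa(euclidean_distance(line))
  expect_equal(length(pcl$retained), 1L)
  expect_equal(as.matrix(dist(pcl$coords)), euclidean_distance(line),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("non-Euclidean input drops negative axes to the best rank-m fit", {
  # violates the triangle inequality
  D <- matrix(c(0, 1, 1, 10,
                1, 0, 1, 1,
                1, 1, 0, 1,
                10, 1, 1, 0), 4, 4)
  pc <- pcoa(D)
  expect_true(any(pc$eigenvalues < 0))
  G <- gower_double_center_oracle(D)
  eig <- eigen(G, symmetric = TRUE)
  keep <- eig$values > 1e-10 * max(eig$values)
  best <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), sum(keep))
  expect_equal(as.matrix(dist(pc$coords)), as.matrix(dist(best)),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("MEM basis equals the dense eigen oracle on collinear points", {
  pts <- cbind(c(0, 1, 2, 3), 0)
  D <- euclidean_distance(pts)
  basis <- mem_basis(D)
  # truncation defaults to the longest MST edge (here 1)
  expect_equal(basis$truncation, 1)
  oracle <- oracle_mem(D, 1)
  keep <- abs(oracle$values) > 1e-10 * max(abs(oracle$values))
  expect_equal(sort(basis$values),
               sort(oracle$values[keep]), tolerance = 1e-8)
  for (k in seq_along(basis$values)) {
    v <- basis$vectors[, k]
    o <- oracle$vectors[, which(abs(oracle$values - basis$values[k]) <
                                  1e-8)[1]]
    expect_equal(abs(sum(v * o)), 1, tolerance = 1e-8)
  }
})

test_that("MEM eigenvectors are orthonormal, centered and at most n-1", {
  set.seed(20)
  xy <- cbind(runif(30), runif(30))
  basis <- mem_basis(euclidean_distance(xy))
  V <- basis$vectors
  expect_lte(ncol(V), 29L)
  expect_equal(crossprod(V), diag(ncol(V)), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(abs(colSums(V)) < 1e-8))
  expect_true(all(diff(basis$values) <= 1e-12))
  expect_error(mem_basis(euclidean_distance(xy), truncation = 1e-6),
               "disconnected")
})

test_that("positive MEM eigenvectors agree with vegan's PCNM", {
  skip_if_not_installed("vegan")
  set.seed(22)
  xy <- cbind(runif(25), runif(25))
  D <- euclidean_distance(xy)
  basis <- mem_basis(D)
  pcnm <- vegan::pcnm(dist(xy))
  pos <- which(basis$class == "positive")
  expect_equal(length(pos), length(pcnm$values[pcnm$values >
                                                 1e-10 * max(pcnm$values)]))
  expect_equal(basis$values[pos], pcnm$values[seq_along(pos)],
               tolerance = 1e-8)
  # vectors equal up to sign (pcnm returns unscaled eigenvectors)
  for (k in head(seq_along(pos), 5)) {
    expect_equal(abs(cor(basis$vectors[, pos[k]], pcnm$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
})

test_that("RDA fitted values equal per-column least squares", {
  set.seed(23)
  Y <- matrix(rnorm(60), 20, 3)
  X <- matrix(rnorm(40), 20, 2)
  fit <- rda_fit(Y, X)
  for (j in 1:3) {
    lmfit <- lm(Y[, j] ~ X)
    expect_equal(fit$fitted[, j],
                 unname(fitted(lmfit) - mean(Y[, j])), tolerance = 1e-10)
  }
  skip_if_not_installed("vegan")
  v <- vegan::rda(Y ~ X)
  expect_equal(fit$R2, unname(vegan::RsquareAdj(v)$r.squared),
               tolerance = 1e-10)
  expect_equal(fit$adjR2, unname(vegan::RsquareAdj(v)$adj.r.squared),
               tolerance = 1e-10)
})

test_that("forward selection recovers planted eigenvectors", {
  set.seed(24)
  recovered <- 0; fp_ok <- 0
  for (r in 1:25) {
    xy <- cbind(runif(80), runif(80))
    basis <- mem_basis(euclidean_distance(xy))
    pos <- which(basis$class == "positive")
    V <- basis$vectors[, pos[c(1, 4)]]
    sig <- V %*% c(1, 1)
    noise <- rnorm(80)
    noise <- residuals(lm(noise ~ sig))
    noise <- noise / sqrt(sum(noise^2)) * sqrt(sum(sig^2))
    Y <- sig + noise                       # construction R2 = 0.5
    fs <- forward_select(Y, basis, "positive", n_perm = 99)
    if (all(pos[c(1, 4)] %in% fs$selected)) recovered <- recovered + 1
    if (length(setdiff(fs$selected, pos[c(1, 4)])) <= 1) fp_ok <- fp_ok + 1
  }
  expect_gte(recovered, 23)   # both true vectors found in >= 90%
  expect_gte(fp_ok, 23)       # at most one false positive in >= 90%
})

test_that("forward selection on pure noise is empty at the gate rate", {
  set.seed(25)
  empty <- 0
  xy <- cbind(runif(60), runif(60))
  basis <- mem_basis(euclidean_distance(xy))
  for (r in 1:60) {
    Y <- rnorm(60)
    fs <- forward_select(Y, basis, "positive", n_perm = 99)
    if (!length(fs$selected)) empty <- empty + 1
  }
  expect_gte(empty / 60, 0.87)
})

test_that("a response equal to one basis vector is selected immediately", {
  set.seed(26)
  xy <- cbind(runif(40), runif(40))
  basis <- mem_basis(euclidean_distance(xy))
  pos <- which(basis$class == "positive")
  Y <- basis$vectors[, pos[2]]
  fs <- forward_select(Y, basis, "positive", n_perm = 99)
  expect_equal(fs$selected[1], pos[2])
})

test_that("mgquick output is invariant to rigid motions and row order", {
  sim <- simulate_population(sim_config(n_individuals = 70, seed = 27))
  tab <- sim$table
  set.seed(1); mg1 <- mgquick(tab, n_perm = 99)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  set.seed(1); mg2 <- mgquick(tab, xy = tab$xy %*% R + 100, n_perm = 99)
  expect_equal(mg1$adjR2, mg2$adjR2, tolerance = 1e-8)
  expect_equal(ncol(mg1$axes), ncol(mg2$axes))
  if (ncol(mg1$axes))
    expect_equal(abs(cor(mg1$axes[, 1], mg2$axes[, 1])), 1,
                 tolerance = 1e-6)
  perm <- sample(n_ind(tab))
  set.seed(1); mg3 <- mgquick(tab[perm], n_perm = 99)
  expect_equal(mg3$adjR2, mg1$adjR2, tolerance = 1e-6)
  if (ncol(mg1$axes))
    expect_equal(abs(cor(mg3$axes[, 1], mg1$axes[perm, 1])), 1,
                 tolerance = 1e-6)
})

test_that("spatial genetic axes are orthogonal with zero mean", {
  sim <- simulate_population(sim_config(n_individuals = 80, seed = 28))
  set.seed(2)
  mg <- mgquick(sim$table, n_perm = 99)
  expect_gt(ncol(mg$axes), 0)
  G <- crossprod(mg$axes)
  expect_equal(G - diag(diag(G)), matrix(0, ncol(G), ncol(G)),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(abs(colMeans(mg$axes)) < 1e-8))
  expect_equal(sum(mg$proportions), 1, tolerance = 1e-10)
})
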