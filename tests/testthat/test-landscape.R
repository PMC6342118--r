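test_that("line features burn a column at the feature cost", {
  xy <- cbind(c(5, 95), c(5, 95))
  s <- resistance_grid(xy, cell_size = 10, margin = 0)
  line <- list(list(type = "line", class = "roads",
                    coords = cbind(c(55, 55), c(-10, 110))))
  s <- rasterize_features(s, line, cost = 10)
  hit_cols <- which(apply(s$cost, 2, function(col) any(col == 10)))
  centers <- (seq_len(ncol(s$cost)) - 0.5) * 10 + s$origin[1]
  expect_true(all(abs(centers[hit_cols] - 55) <= 10 / 2 + 1e-9))
  expect_true(all(s$cost[, -hit_cols] == 1))
})

test_that("fire polygons outside 1964-2013 are not burned", {
  xy <- cbind(c(0, 100), c(0, 100))
  s <- resistance_grid(xy, cell_size = 10)
  old_fire <- list(list(type = "polygon", class = "fire", year = 1950L,
                        coords = cbind(c(10, 90, 90, 10),
                                       c(10, 10, 90, 90))))
  s1 <- rasterize_features(s, old_fire, cost = 50)
  expect_true(all(s1$cost == 1))
  recent <- old_fire
  recent[[1]]$year <- 2000L
  s2 <- rasterize_features(s, recent, cost = 50)
  expect_true(any(s2$cost == 50))
})

test_that("overlapping layers take the maximum cost", {
  xy <- cbind(c(0, 100), c(0, 100))
  s <- resistance_grid(xy, cell_size = 10)
  poly <- function(cl, cost) list(list(
    type = "polygon", class = cl,
    coords = cbind(c(20, 80, 80, 20), c(20, 20, 80, 80))))
  s <- rasterize_features(s, poly("water"), cost = 10)
  s <- rasterize_features(s, poly("roads"), cost = 100)
  inside <- s$cost[5, 5]
  expect_equal(inside, 100)
  expect_true(all(s$cost %in% c(1, 100)))
})

test_that("cost distances match the naive Dijkstra oracle", {
  set.seed(30)
  xy <- cbind(runif(6, 5, 195), runif(6, 5, 195))
  s <- resistance_grid(xy, cell_size = 10, margin = 1)
  # wall with a gap
  s$cost[, 10] <- 100
  s$cost[4, 10] <- 1
  D <- cost_distance_matrix(s, xy)
  idx <- memscape:::surface_cell_index(s, xy)
  for (i in 1:5) for (j in (i + 1):6) {
    d_oracle <- oracle_cost_dist(s$cost, s$cell_size,
                                 unname(idx[i, ]), unname(idx[j, ]))
    expect_equal(D[i, j], d_oracle, tolerance = 1e-8)
  }
  expect_equal(diag(D), rep(0, 6))
})

test_that("near-uniform grid distances stay within the 8-connectivity bound", {
  set.seed(31)
  xy <- cbind(runif(8, 2, 198), runif(8, 2, 198))
  s <- resistance_grid(xy, cell_size = 10)
  s$cost[1, 1] <- 2   # break exact uniformity so the grid solver runs
  D <- cost_distance_matrix(s, xy)
  centers <- memscape:::surface_cell_index(s, xy)
  cc <- cbind(s$origin[1] + (centers[, "col"] - 0.5) * s$cell_size,
              s$origin[2] + (centers[, "row"] - 0.5) * s$cell_size)
  E <- euclidean_distance(cc)
  off <- upper.tri(E)
  ratio <- D[off] / E[off]
  expect_true(all(ratio >= 1 - 1e-9))
  expect_true(all(ratio <= 1.09))
  # the 16-neighbour stencil tightens the metric bound
  D16 <- cost_distance_matrix(s, xy, neighborhood = 16)
  expect_true(all(D16[off] / E[off] <= 1.04 + 1e-9))
})

test_that("uniform surfaces use the exact continuum least-cost solution", {
  set.seed(32)
  xy <- cbind(runif(6, 2, 98), runif(6, 2, 98))
  s <- resistance_grid(xy, cell_size = 5)
  expect_equal(cost_distance_matrix(s, xy), euclidean_distance(xy),
               ignore_attr = TRUE, tolerance = 1e-12)
  s$cost[] <- 7
  expect_equal(cost_distance_matrix(s, xy), 7 * euclidean_distance(xy),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("variation-partition identities hold to 1e-10", {
  sim <- simulate_population(sim_config(n_individuals = 60, seed = 33,
                                        scenario = "ibr"))
  tab <- sim$table
  e <- sim$truth$config$extent
  bar <- list(list(type = "line", class = "roads",
                   coords = sim$truth$barrier))
  m <- landscape_model(bar, c(roads = 100), tab$xy, cell_size = e / 40,
                       road_buffer = 0)
  set.seed(1)
  vp <- mg_landscape(tab, m, n_perm = 49)
  expect_equal(vp$a + vp$b + vp$c, vp$abc, tolerance = 1e-10)
  expect_equal(vp$abc + vp$d, 1, tolerance = 1e-10)
  expect_true(all(c(vp$p_abc, vp$p_a, vp$p_c) > 0 &
                    c(vp$p_abc, vp$p_a, vp$p_c) <= 1, na.rm = TRUE))
})

test_that("scaling all costs leaves MEM structure and fractions unchanged", {
  sim <- simulate_population(sim_config(n_individuals = 50, seed = 34,
                                        scenario = "ibr"))
  tab <- sim$table
  e <- sim$truth$config$extent
  bar <- list(list(type = "line", class = "roads",
                   coords = sim$truth$barrier))
  m1 <- landscape_model(bar, c(roads = 10), tab$xy, cell_size = e / 30,
                        road_buffer = 0)
  m5 <- m1
  m5$surface$cost <- m1$surface$cost * 5
  D1 <- cost_distance_matrix(m1$surface, tab$xy)
  D5 <- cost_distance_matrix(m5$surface, tab$xy)
  expect_equal(D5, 5 * D1, tolerance = 1e-9)
  set.seed(2); v1 <- mg_landscape(tab, m1, n_perm = 0)
  set.seed(2); v5 <- mg_landscape(tab, m5, n_perm = 0)
  expect_equal(v1$abc, v5$abc, tolerance = 1e-8)
  expect_equal(v1$a, v5$a, tolerance = 1e-8)
})

test_that("the flat surface reproduces mgquick-style structure", {
  sim <- simulate_population(sim_config(n_individuals = 60, seed = 35))
  tab <- sim$table
  flat <- landscape_model(list(), setNames(numeric(0), character(0)),
                          tab$xy, cell_size = sim$truth$config$extent / 60)
  set.seed(3)
  vp <- mg_landscape(tab, flat, n_perm = 0)
  # uniform cost-1 distances equal the Euclidean block exactly, so the
  # two selections coincide and the whole signal is confounded
  expect_equal(vp$a, 0, tolerance = 1e-10)
  expect_equal(vp$c, 0, tolerance = 1e-10)
  expect_gt(vp$b, 0)
})

test_that("model_search ranks features and keeps the comparison rows", {
  sim <- simulate_population(sim_config(n_individuals = 50, seed = 36,
                                        scenario = "ibr"))
  tab <- sim$table
  e <- sim$truth$config$extent
  feats <- list(
    list(type = "line", class = "roads", coords = sim$truth$barrier),
    list(type = "polygon", class = "water",
         coords = cbind(c(0.6, 0.9, 0.9, 0.6) * e,
                        c(0.6, 0.6, 0.9, 0.9) * e)))
  set.seed(4)
  ms <- model_search(tab, feats, costs = c(10, 100), n_perm = 0,
                     cell_size = e / 30)
  expect_setequal(ms$table$model,
                  c("IBD", sprintf("roads(%g)", ms$best_costs["roads"]),
                    sprintf("water(%g)", ms$best_costs["water"]),
                    "roads+water"))
  expect_true(all(ms$best_costs %in% c(10, 100)))
  for (vp in ms$partitions) {
    expect_equal(vp$a + vp$b + vp$c, vp$abc, tolerance = 1e-10)
    expect_equal(vp$abc + vp$d, 1, tolerance = 1e-10)
  }
})

test_that("GeoJSON features round-trip deterministically", {
  fx <- make_landscape_fixture(extent = 1000, n_units = 5)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_features_geojson(fx$features, f)
  back <- read_features_geojson(f)
  expect_equal(length(back), length(fx$features))
  expect_equal(back[[1]]$class, "roads")
  expect_equal(back[[3]]$year, 1950L)
  expect_equal(back[[2]]$coords[1:4, 1], fx$features[[2]]$coords[1:4, 1],
               tolerance = 1e-6)
  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_features_geojson(fx$features, f2)
  expect_identical(readLines(f), readLines(f2))
})
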