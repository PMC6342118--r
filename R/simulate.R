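#' Simulation configuration
#'
#' Parameters of the spatially explicit forward-time microsatellite
#' simulator. Defaults describe a population of 200 individuals at fixed
#' uniform-random sites on a square landscape, 9 unlinked loci under
#' stepwise mutation, distance-limited mating with Gaussian dispersal
#' (sigma = 5% of the extent), and 100 non-overlapping generations.
#'
#' @param n_individuals number of occupied sites (default 200).
#' @param n_loci number of microsatellite loci (default 9).
#' @param extent landscape side length in meters (default 100000).
#' @param sigma dispersal scale in meters (default `0.05 * extent`).
#' @param mu stepwise mutation rate per allele per generation
#'   (default 5e-4; must be <= 0.01).
#' @param n_generations generations to run (default 100).
#' @param scenario `"ibd"`, `"ibr"` or `"panmixia"`.
#' @param barrier for `"ibr"`: a polyline matrix (vertices x 2) crossing
#'   the landscape (default a central vertical line), or `NULL`.
#' @param barrier_multiplier effective-distance multiplier for matings
#'   whose straight segment crosses the barrier (default 10; >= 1).
#' @param n_founder_alleles distinct founder alleles per locus
#'   (default 10).
#' @param duplicate_rate fraction of planted duplicate samples appended
#'   after the run (default 0), each a copy with one locus perturbed.
#' @param seed integer seed; mandatory for reproducible runs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 200L, n_loci = 9L, extent = 1e5,
                       sigma = 0.05 * extent, mu = 5e-4,
                       n_generations = 100L,
                       scenario = c("ibd", "ibr", "panmixia"),
                       barrier = NULL, barrier_multiplier = 10,
                       n_founder_alleles = 10L, duplicate_rate = 0,
                       seed = 1L) {
  scenario <- match.arg(scenario)
  if (mu < 0 || mu > 0.01) stop("mu must lie in [0, 0.01]")
  if (scenario != "panmixia" && sigma <= 0)
    stop("sigma must be positive unless panmictic")
  if (barrier_multiplier < 1) stop("barrier_multiplier must be >= 1")
  if (scenario == "ibr" && is.null(barrier))
    barrier <- cbind(c(extent / 2, extent / 2), c(-0.05, 1.05) * extent)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_loci = as.integer(n_loci), extent = extent,
                 sigma = sigma, mu = mu,
                 n_generations = as.integer(n_generations),
                 scenario = scenario, barrier = barrier,
                 barrier_multiplier = barrier_multiplier,
                 n_founder_alleles = as.integer(n_founder_alleles),
                 duplicate_rate = duplicate_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# allele state space: repeat counts bounded to [5, 50], reflecting
SIM_REPEAT_MIN <- 5L
SIM_REPEAT_MAX <- 50L

#' Simulate a spatially structured microsatellite population
#'
#' Forward-time simulation on fixed sites: each generation, the occupant
#' of every site draws two parents from the previous generation with
#' probability proportional to `exp(-d_eff^2 / (2 sigma^2))`, where
#' `d_eff` is the Euclidean inter-site distance multiplied by the barrier
#' multiplier when the straight segment between the sites crosses the
#' barrier (isolation by resistance); under panmixia parents are uniform.
#' Offspring inherit one uniformly chosen allele per parent per locus;
#' alleles mutate by +/-1 repeat with probability `mu`, reflecting at the
#' bounds [5, 50]. Founders are drawn at Hardy-Weinberg from
#' `n_founder_alleles` equifrequent alleles. Optional planted duplicates
#' (copies with a single perturbed locus and the same coordinates) are
#' appended for duplicate-matching studies.
#'
#' @param config a [sim_config()].
#' @return list with `table` (a [genotype_table()]; planted duplicates
#'   carry ids suffixed `_dup`) and `truth` (class `sim_truth`: `scenario`,
#'   `sigma`, `barrier`, `deme` (side of the barrier, `NA` without one),
#'   `n_planted_duplicates`, `config`).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals; L <- config$n_loci
  xy <- cbind(stats::runif(n, 0, config$extent),
              stats::runif(n, 0, config$extent))

  # mating kernel over fixed sites (rows: offspring site; cols: parent)
  if (config$scenario == "panmixia") {
    cum <- matrix(seq_len(n) / n, n, n, byrow = TRUE)
  } else {
    d <- as.matrix(stats::dist(xy))
    if (!is.null(config$barrier) && config$barrier_multiplier > 1) {
      cross <- matrix(FALSE, n, n)
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        if (segment_crosses_polyline(xy[i, ], xy[j, ], config$barrier)) {
          cross[i, j] <- cross[j, i] <- TRUE
        }
      }
      d[cross] <- d[cross] * config$barrier_multiplier
    }
    K <- exp(-d^2 / (2 * config$sigma^2))
    rs <- rowSums(K)
    if (any(rs <= 0) || any(!is.finite(rs)))
      stop("some site has no reachable parent mass; increase sigma or ",
           "shrink the extent")
    cum <- t(apply(K / rs, 1L, cumsum))
    cum[cum > 1] <- 1  # cumsum rounding guard; keeps rows non-decreasing
    cum[, n] <- 1
  }

  draw_parents <- function() {
    u <- stats::runif(n)
    # u recycles down columns, so entry (i, j) is compared against u[i]:
    # row count of cum[i, ] below u[i] indexes the sampled parent
    as.integer(rowSums(cum < u) + 1L)
  }

  # founders at HWE: equifrequent allele states centred in the bounds
  states <- seq(SIM_REPEAT_MIN + 5L,
                length.out = config$n_founder_alleles)
  alleles <- array(sample(states, n * L * 2L, replace = TRUE),
                   c(n, L, 2L))

  for (gen in seq_len(config$n_generations)) {
    p1 <- draw_parents(); p2 <- draw_parents()
    child <- array(NA_integer_, c(n, L, 2L))
    pick1 <- matrix(sample(2L, n * L, replace = TRUE), n, L)
    pick2 <- matrix(sample(2L, n * L, replace = TRUE), n, L)
    for (s in 1:2) {
      par_idx <- if (s == 1L) p1 else p2
      pick <- if (s == 1L) pick1 else pick2
      flat <- cbind(rep(par_idx, L), rep(seq_len(L), each = n),
                    as.vector(pick))
      child[, , s] <- matrix(alleles[flat], n, L)
    }
    mut <- matrix(stats::runif(n * L * 2L) < config$mu, n * L, 2L)
    if (any(mut)) {
      step <- sample(c(-1L, 1L), sum(mut), replace = TRUE)
      v <- as.vector(child)
      v[which(as.vector(mut))] <- v[which(as.vector(mut))] + step
      v[v < SIM_REPEAT_MIN] <- SIM_REPEAT_MIN + 1L
      v[v > SIM_REPEAT_MAX] <- SIM_REPEAT_MAX - 1L
      child <- array(v, dim(child))
    }
    alleles <- child
  }

  deme <- rep(NA_character_, n)
  if (!is.null(config$barrier)) {
    anchor <- xy[1, ]
    deme <- ifelse(vapply(seq_len(n), function(i)
      segment_crosses_polyline(anchor, xy[i, ], config$barrier), TRUE),
      "B", "A")
  }

  id <- sprintf("ind%03d", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  n_dup <- round(config$duplicate_rate * n)
  if (n_dup > 0L) {
    src <- sample(n, n_dup)
    dup_all <- alleles[src, , , drop = FALSE]
    for (k in seq_len(n_dup)) {
      l <- sample(L, 1L)
      a <- dup_all[k, l, ]
      a[1] <- if (a[1] < SIM_REPEAT_MAX) a[1] + 1L else a[1] - 1L
      dup_all[k, l, ] <- a
    }
    alleles <- abind_rows(alleles, dup_all)
    xy <- rbind(xy, xy[src, , drop = FALSE])
    id <- c(id, paste0(id[src], "_dup"))
    sex <- c(sex, sex[src])
    deme <- c(deme, deme[src])
  }

  table <- genotype_table(id = id, alleles = alleles, xy = xy, sex = sex,
                          group = if (!all(is.na(deme))) deme)
  truth <- structure(list(scenario = config$scenario, sigma = config$sigma,
                          barrier = config$barrier, deme = deme,
                          n_planted_duplicates = n_dup, config = config),
                     class = "sim_truth")
  list(table = table, truth = truth)
}

# rbind two n x L x 2 arrays along the first dimension
abind_rows <- function(a, b) {
  out <- array(NA_integer_, c(dim(a)[1] + dim(b)[1], dim(a)[2], 2L))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' Deterministic landscape and management-unit fixtures
#'
#' Generates vector features shaped like a study landscape: one road
#' polyline crossing the extent, one water-body polygon, two fire
#' polygons whose ignition years straddle the 1964-2013 filter window,
#' and candidate management-unit polygon sets (vertical strips, horizontal
#' strips, and a grid-like split), each with the same number of units.
#' Output is fully determined by the arguments, so repeated calls (and
#' [write_features_geojson()] exports) are byte-identical.
#'
#' @param extent landscape side length in meters (default 100000).
#' @param n_units units per management-unit scenario (default 5).
#' @return list with `features` (roads/water/fire feature list) and
#'   `mu_sets` (named list of polygon feature lists).
#' @export
make_landscape_fixture <- function(extent = 1e5, n_units = 5L) {
  e <- extent
  features <- list(
    list(type = "line", class = "roads",
         coords = cbind(c(0.45, 0.52, 0.55) * e, c(-0.05, 0.5, 1.05) * e)),
    list(type = "polygon", class = "water",
         coords = cbind(c(0.65, 0.85, 0.85, 0.65) * e,
                        c(0.15, 0.15, 0.4, 0.4) * e)),
    list(type = "polygon", class = "fire", year = 1950L,
         coords = cbind(c(0.1, 0.3, 0.3, 0.1) * e,
                        c(0.6, 0.6, 0.8, 0.8) * e)),
    list(type = "polygon", class = "fire", year = 2000L,
         coords = cbind(c(0.1, 0.25, 0.25, 0.1) * e,
                        c(0.1, 0.1, 0.3, 0.3) * e)))
  strip <- function(i, k, vertical) {
    lo <- (i - 1) / k; hi <- i / k
    if (vertical)
      cbind(c(lo, hi, hi, lo) * e, c(-0.01, -0.01, 1.01, 1.01) * e)
    else
      cbind(c(-0.01, 1.01, 1.01, -0.01) * e, c(lo, lo, hi, hi) * e)
  }
  mk_set <- function(vertical) lapply(seq_len(n_units), function(i)
    list(type = "polygon", unit_id = paste0("U", i),
         coords = strip(i, n_units, vertical)))
  # mixed set: one vertical split at the road, remaining horizontal strips
  mixed <- c(list(list(type = "polygon", unit_id = "U1",
                       coords = cbind(c(-0.01, 0.5, 0.5, -0.01) * e,
                                      c(-0.01, -0.01, 1.01, 1.01) * e))),
             lapply(seq_len(n_units - 1L), function(i) {
               lo <- (i - 1) / (n_units - 1L); hi <- i / (n_units - 1L)
               list(type = "polygon", unit_id = paste0("U", i + 1L),
                    coords = cbind(c(0.5, 1.01, 1.01, 0.5) * e,
                                   c(lo, lo, hi, hi) * e))
             }))
  list(features = features,
       mu_sets = list(vertical = mk_set(TRUE),
                      horizontal = mk_set(FALSE),
                      mixed = mixed))
}
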