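#' Build a landscape-resistance model from vector features
#'
#' Assembles a named [LandscapeModel]: a resistance surface with one layer
#' per feature class at its cost value. Roads are burned with a 500-m
#' buffer radius; fire polygons are filtered to ignition years 1964-2013.
#' An empty `layers` list yields the flat cost-1 surface (the pure
#' isolation-by-distance model).
#'
#' @param features list of features (see [read_features_geojson()]).
#' @param layers named numeric vector of costs per feature class, e.g.
#'   `c(roads = 100, water = 10)`; values conventionally in
#'   `{10, 50, 100}`.
#' @param xy sample coordinates defining the grid extent.
#' @param cell_size raster resolution (see [resistance_grid()]).
#' @param road_buffer buffer radius for road lines, meters (default 500).
#' @param fire_years ignition-year window (default 1964-2013).
#' @param name model name (default built from the layers).
#' @return list of class `landscape_model`: `name`, `layers`, `surface`.
#' @export
landscape_model <- function(features, layers, xy, cell_size = NULL,
                            road_buffer = 500, fire_years = c(1964L, 2013L),
                            name = NULL) {
  surface <- resistance_grid(xy, cell_size = cell_size)
  for (cl in names(layers)) {
    fs <- Filter(function(f) identical(f$class, cl), features)
    if (!length(fs)) stop("no features of class '", cl, "'")
    surface <- rasterize_features(
      surface, fs, cost = layers[[cl]],
      buffer = if (cl == "roads") road_buffer else 0,
      fire_years = fire_years)
  }
  if (is.null(name))
    name <- if (length(layers))
      paste(sprintf("%s(%g)", names(layers), layers), collapse = "+")
    else "IBD"
  structure(list(name = name, layers = layers, surface = surface),
            class = "landscape_model")
}

#' Partition genetic variation into landscape (IBR) and coordinate (IBD)
#' fractions
#'
#' The landscape MEM analysis: block `X1` holds eigenvectors
#' forward-selected from the least-cost-path distance matrix under the
#' resistance model, block `X2` eigenvectors selected from straight-line
#' Euclidean distances, and the response is the principal-coordinate
#' representation of the genetic distance. Adjusted-R2 fractions follow
#' [varpart2()]: `[a]` landscape-specific, `[c]` coordinate-specific,
#' `[b]` confounded, `[d]` residual, with `[abc]` the total spatially
#' explained variation.
#'
#' @param x a [genotype_table()].
#' @param model a [landscape_model()].
#' @param xy optional coordinates (default `x$xy`).
#' @param alpha forward-selection level (default 0.05).
#' @param n_perm permutations for selection and fraction tests
#'   (default 999; 0 skips the fraction tests and uses 199 for selection).
#' @param use_negative negative-class policy, see [mgquick()].
#' @param D optional precomputed genetic distance.
#' @param neighborhood grid connectivity for the least-cost solver, 8
#'   (default) or 16; see [cost_distance_matrix()].
#' @return a `variation_partition` (see [varpart2()]) with labels
#'   `c("landscape", "coordinates")` and attributes `model` (name) and
#'   `selections`.
#' @export
mg_landscape <- function(x, model, xy = NULL, alpha = 0.05, n_perm = 999L,
                         use_negative = "auto", D = NULL,
                         neighborhood = 8L) {
  stopifnot(inherits(x, "genotype_table"), inherits(model, "landscape_model"))
  if (is.null(xy)) xy <- x$xy
  xy <- as.matrix(xy)
  if (anyNA(xy)) stop("coordinates required for all individuals")
  if (is.null(D)) D <- dps_distance(x)
  Y <- pcoa(D)$coords
  n_sel <- if (n_perm > 0L) n_perm else 199L

  Dcost <- cost_distance_matrix(model$surface, xy,
                                neighborhood = neighborhood)
  basis1 <- mem_basis(Dcost, source = "cost")
  basis2 <- mem_basis(euclidean_distance(xy), source = "euclidean")
  # common random numbers: both blocks' forward selections consume the
  # same permutation stream, so identical bases give identical selections
  # (the flat cost-1 surface then collapses to the degenerate X1 == X2
  # case) and model contrasts are not polluted by Monte-Carlo noise
  crn_seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(crn_seed)
  fit1 <- mg_fit(Y, basis1, alpha = alpha, n_perm = n_sel,
                 use_negative = use_negative)
  set.seed(crn_seed)
  fit2 <- mg_fit(Y, basis2, alpha = alpha, n_perm = n_sel,
                 use_negative = use_negative)
  vp <- varpart2(Y, fit1$X, fit2$X, n_perm = n_perm,
                 labels = c("landscape", "coordinates"))
  attr(vp, "model") <- model$name
  attr(vp, "selections") <- list(landscape = fit1, coordinates = fit2)
  vp
}

#' Two-stage landscape model search
#'
#' Stage 1 tests each feature class (`roads`, `water`, `fire`) as a
#' univariate resistance model at each cost in `costs`, keeping the cost
#' that maximizes the landscape-specific fraction `[a]` (or `[abc]` with
#' `rank_by = "abc"`). Stage 2 runs the four combination models at the
#' kept costs plus the flat-surface IBD model, and returns all rows as a
#' results table.
#'
#' @param x a [genotype_table()].
#' @param features feature list with classes among roads/water/fire.
#' @param xy optional coordinates.
#' @param costs candidate cost values (default `c(10, 50, 100)`).
#' @param alpha,n_perm,use_negative,cell_size passed through.
#' @param rank_by `"a"` (default) or `"abc"`.
#' @return list of class `model_search`: `table` (data frame with columns
#'   model, abc, p_abc, a, p_a, c, p_c, b, d), `best_costs` (named
#'   vector), `partitions` (list of `variation_partition`).
#' @export
model_search <- function(x, features, xy = NULL,
                         costs = c(10, 50, 100), alpha = 0.05,
                         n_perm = 999L, use_negative = "auto",
                         cell_size = NULL, rank_by = c("a", "abc")) {
  rank_by <- match.arg(rank_by)
  if (is.null(xy)) xy <- x$xy
  xy <- as.matrix(xy)
  D <- dps_distance(x)
  classes <- intersect(c("roads", "water", "fire"),
                       unique(vapply(features, `[[`, "", "class")))
  if (!length(classes)) stop("no roads/water/fire features supplied")
  run <- function(layers, name = NULL) {
    m <- landscape_model(features, layers, xy, cell_size = cell_size,
                         name = name)
    mg_landscape(x, m, xy = xy, alpha = alpha, n_perm = n_perm,
                 use_negative = use_negative, D = D)
  }
  parts <- list()
  best_costs <- stats::setNames(numeric(0), character(0))
  for (cl in classes) {
    score <- -Inf; best <- costs[1]
    for (co in costs) {
      vp <- run(stats::setNames(co, cl))
      parts[[sprintf("%s(%g)", cl, co)]] <- vp
      s <- if (rank_by == "a") vp$a else vp$abc
      if (s > score) { score <- s; best <- co }
    }
    best_costs[cl] <- best
  }
  combos <- list()
  if (length(classes) >= 2L) {
    pairs <- utils::combn(classes, 2L, simplify = FALSE)
    combos <- c(pairs, if (length(classes) == 3L) list(classes))
  }
  for (cmb in combos) {
    layers <- best_costs[cmb]
    parts[[paste(cmb, collapse = "+")]] <- run(layers,
      name = paste(cmb, collapse = "+"))
  }
  parts[["IBD"]] <- run(stats::setNames(numeric(0), character(0)),
                        name = "IBD")
  # rows mirror the conventional layout: IBD, each feature at its kept
  # cost, then the combination models (all stage-1 runs stay in $partitions)
  rows <- c("IBD",
            sprintf("%s(%g)", names(best_costs), best_costs),
            vapply(combos, paste, "", collapse = "+"))
  tab <- do.call(rbind, lapply(rows, function(nm) {
    vp <- parts[[nm]]
    data.frame(model = nm, abc = vp$abc, p_abc = vp$p_abc, a = vp$a,
               p_a = vp$p_a, c = vp$c, p_c = vp$p_c, b = vp$b, d = vp$d)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, best_costs = best_costs, partitions = parts),
            class = "model_search")
}

#' @export
print.model_search <- function(x, ...) {
  cat("landscape model search (best costs:",
      paste(sprintf("%s=%g", names(x$best_costs), x$best_costs),
            collapse = ", "), ")\n")
  print(transform(x$table,
                  abc = round(abc, 3), a = round(a, 3), c = round(c, 3),
                  b = round(b, 3), d = round(d, 3)), row.names = FALSE)
  invisible(x)
}
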