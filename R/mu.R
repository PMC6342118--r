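#' Management-unit scenario
#'
#' A candidate partition of the sampled area into management units,
#' either as polygons (GeoJSON features with a `unit_id` property) or as a
#' precomputed per-individual membership vector.
#'
#' @param name scenario name.
#' @param polygons optional list of polygon features (each with
#'   `unit_id`).
#' @param membership optional character vector, one unit label per
#'   individual.
#' @return list of class `mu_scenario`: `name`, `polygons`, `membership`,
#'   `n_units`.
#' @export
mu_scenario <- function(name, polygons = NULL, membership = NULL) {
  if (is.null(polygons) && is.null(membership))
    stop("supply polygons or a membership vector")
  n_units <- if (!is.null(membership)) length(unique(membership))
             else length(unique(vapply(polygons, `[[`, "", "unit_id")))
  if (n_units < 2L) stop("a scenario needs >= 2 units")
  structure(list(name = name, polygons = polygons,
                 membership = if (!is.null(membership))
                   as.character(membership),
                 n_units = n_units),
            class = "mu_scenario")
}

#' Treatment-coded indicator matrix for unit membership
#'
#' Full-rank dummy coding: `k` units produce `k - 1` indicator columns,
#' with the lexicographically first unit as the reference. Units with no
#' members are dropped with a warning.
#'
#' @param membership character vector of unit labels.
#' @return `n x (k-1)` 0/1 matrix with column names `unit<label>`.
#' @export
dummy_code <- function(membership) {
  membership <- as.character(membership)
  lev <- sort(unique(membership))
  counts <- table(factor(membership, lev))
  if (any(counts == 0L)) {
    warning("unit(s) with 0 members dropped: ",
            paste(names(counts)[counts == 0L], collapse = ", "))
    lev <- lev[counts > 0L]
  }
  if (length(lev) < 2L) stop("need >= 2 non-empty units")
  out <- vapply(lev[-1L], function(u) as.numeric(membership == u),
                numeric(length(membership)))
  out <- matrix(out, nrow = length(membership),
                dimnames = list(NULL, paste0("unit", lev[-1L])))
  out
}

#' Assign individuals to management units
#'
#' Point-in-polygon assignment; a point contained in several polygons (a
#' shared boundary) goes to the polygon with the lowest index. Points
#' covered by no polygon go to the unit whose boundary is nearest when
#' `fallback = "nearest"` (the count of such points is reported via a
#' message), or raise an error when `fallback = "none"`.
#'
#' @param xy `n x 2` coordinates.
#' @param scenario a [mu_scenario()] with polygons (a scenario carrying a
#'   precomputed membership returns it unchanged).
#' @param fallback `"nearest"` (default) or `"none"`.
#' @return character vector of unit labels.
#' @export
assign_membership <- function(xy, scenario,
                              fallback = c("nearest", "none")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(scenario, "mu_scenario"))
  if (!is.null(scenario$membership)) {
    if (length(scenario$membership) != nrow(xy))
      stop("membership length != number of individuals")
    return(scenario$membership)
  }
  xy <- as.matrix(xy)
  n <- nrow(xy)
  unit <- rep(NA_character_, n)
  for (k in seq_along(scenario$polygons)) {
    f <- scenario$polygons[[k]]
    inside <- points_in_polygon(xy, as.matrix(f$coords))
    unit[is.na(unit) & inside] <- f$unit_id
  }
  un <- is.na(unit)
  if (any(un)) {
    if (fallback == "none")
      stop(sum(un), " point(s) outside all polygons")
    message(sum(un), " point(s) outside all polygons assigned to the ",
            "nearest unit")
    dists <- vapply(scenario$polygons, function(f)
      points_to_polygon_dist(xy[un, , drop = FALSE], as.matrix(f$coords)),
      numeric(sum(un)))
    dists <- matrix(dists, nrow = sum(un))
    unit[un] <- vapply(seq_len(sum(un)), function(i)
      scenario$polygons[[which.min(dists[i, ])]]$unit_id, "")
  }
  unit
}

#' Variation partitioning of a spatial genetic pattern between MU
#' boundaries and spatial proximity
#'
#' Evaluates how much of the spatial genetic pattern (by default the first
#' spatial genetic axis of a [mgquick()] run) is explained by the
#' dummy-coded unit membership of a management-unit scenario versus the
#' spatial proximity of individuals. Fractions: `[a]` MU-unique, `[b]`
#' space-unique, `[c]` shared, `[d]` residual, with `a + b + c + d = 1`
#' exactly.
#'
#' The spatial-proximity block defaults to a linear coordinate trend
#' (centered x, y). Using the same selected MEM eigenvectors that produced
#' the response axis (`space = "mem"`) is degenerate — the axis lies in
#' their span, so every scenario's unique fraction `[a]` collapses to zero
#' — and is offered only for completeness, with a warning.
#'
#' @param mg a `memgene_result` from [mgquick()] (provides the response
#'   axes, the selected spatial eigenvectors and the coordinates).
#' @param scenario a [mu_scenario()].
#' @param n_perm permutations (default 999).
#' @param response `"first_axis"` (default: the dominant spatial genetic
#'   pattern) or `"all_axes"`.
#' @param space spatial-proximity block: `"trend"` (default, linear
#'   coordinate trend) or `"mem"` (the mgquick-selected eigenvectors).
#' @param fallback passed to [assign_membership()].
#' @return list of class `mu_partition`: `scenario`, `n_units`, `a`, `b`,
#'   `c`, `d`, `p_a`, `p_b`, `p_abc`.
#' @export
mu_varpart <- function(mg, scenario, n_perm = 999L,
                       response = c("first_axis", "all_axes"),
                       space = c("trend", "mem"),
                       fallback = "nearest") {
  response <- match.arg(response)
  space <- match.arg(space)
  stopifnot(inherits(mg, "memgene_result"))
  if (!NCOL(mg$axes))
    stop("the mgquick run found no spatial genetic axes")
  Y <- if (response == "first_axis") mg$axes[, 1, drop = FALSE] else mg$axes
  membership <- assign_membership(mg$xy, scenario, fallback = fallback)
  X1 <- dummy_code(membership)
  if (space == "trend") {
    X2 <- scale(mg$xy, center = TRUE, scale = FALSE)
    colnames(X2) <- c("trend_x", "trend_y")
  } else {
    warning("space = \"mem\": the response axis lies in the span of the ",
            "selected eigenvectors; the MU-unique fraction [a] is zero ",
            "by construction")
    X2 <- mg$X
  }
  qr12 <- qr(cbind(scale(X1, scale = FALSE), scale(X2, scale = FALSE)))
  if (qr12$rank < qr(scale(X1, scale = FALSE))$rank +
      qr(scale(X2, scale = FALSE))$rank)
    warning("unit membership collinear with the spatial block; ",
            "the shared fraction absorbs the overlap")
  vp <- varpart2(Y, X1, X2, n_perm = n_perm, labels = c("MU", "space"))
  structure(list(scenario = scenario$name, n_units = scenario$n_units,
                 a = vp$a, b = vp$c, c = vp$b, d = vp$d,
                 p_a = vp$p_a, p_b = vp$p_c, p_abc = vp$p_abc,
                 response = response, membership = membership),
            class = "mu_partition")
}

#' @export
print.mu_partition <- function(x, ...) {
  cat(sprintf(
    "MU partition '%s' (%d units): [a] %.3f (p=%s)  [b] %.3f (p=%s)  [c] %.3f  [d] %.3f\n",
    x$scenario, x$n_units, x$a, format.pval(x$p_a), x$b,
    format.pval(x$p_b), x$c, x$d))
  invisible(x)
}

#' Rank management-unit scenarios
#'
#' Scenarios are comparable only when they delineate the same number of
#' units: extra dummy variables inflate explained variance and no penalty
#' exists. Mixed unit counts are a hard error unless `force = TRUE`
#' (warning). Ranking is by the MU-unique fraction `[a]`, ties broken by
#' the larger combined `[a] + [c]`.
#'
#' @param results list of `mu_partition` objects.
#' @param force compare despite unequal unit counts (default `FALSE`).
#' @return data frame ranked best-first: scenario, n_units, a, b, c, d,
#'   p_a, rank.
#' @export
compare_scenarios <- function(results, force = FALSE) {
  if (length(results) < 2L) stop("need >= 2 scenario results")
  stopifnot(all(vapply(results, inherits, TRUE, "mu_partition")))
  nu <- vapply(results, `[[`, 0L, "n_units")
  if (length(unique(nu)) > 1L) {
    msg <- paste0("scenarios delineate different numbers of units (",
                  paste(unique(nu), collapse = ", "),
                  "); only scenarios with the same number of units are ",
                  "directly comparable")
    if (!force) stop(msg) else warning(msg)
  }
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(scenario = r$scenario, n_units = r$n_units, a = r$a,
               b = r$b, c = r$c, d = r$d, p_a = r$p_a)))
  ord <- order(-df$a, -(df$a + df$c))
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
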