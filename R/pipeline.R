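#' Run the full analysis pipeline
#'
#' Orchestrates the analysis chain on one dataset: duplicate resolution ->
#' diversity / F_ST / isolation-by-distance tests -> MEM spatial genetic
#' regression (full set, then per user-supplied first-order group) ->
#' landscape model search -> management-unit scenario comparison. Each
#' stage writes a delimited table into `out_dir`, and a machine-readable
#' JSON summary (including the seed and package version) is written at the
#' end. Reruns with the same config and seed are bit-reproducible.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{genotypes}{path to a delimited genotype table
#'       ([read_genotype_table()]) or a `genotype_table` object.}
#'     \item{features}{optional: path to a GeoJSON feature file or a
#'       feature list (enables the landscape stage).}
#'     \item{mu_scenarios}{optional: named list of [mu_scenario()]s or
#'       GeoJSON paths (enables the MU stage).}
#'     \item{seed}{integer, mandatory.}
#'     \item{out_dir}{output directory.}
#'     \item{n_perm}{permutation count (default 999).}
#'     \item{alpha}{selection level (default 0.05).}
#'     \item{stages}{subset of `c("dedup", "stats", "ibd", "memgene",
#'       "landscape", "mu")` (default all applicable).}
#'     \item{cell_size}{optional raster resolution for the landscape
#'       stage.}
#'   }
#' @return invisibly, a list with the stage results and the path of the
#'   JSON summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config$seed is mandatory")
  seed <- as.integer(config$seed)
  n_perm <- if (is.null(config$n_perm)) 999L else as.integer(config$n_perm)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  out_dir <- if (is.null(config$out_dir)) stop("config$out_dir is mandatory")
             else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  if (is.null(stages))
    stages <- c("dedup", "stats", "ibd", "memgene",
                if (!is.null(config$features)) "landscape",
                if (!is.null(config$mu_scenarios)) "mu")
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  results <- list(seed = seed,
                  version = as.character(utils::packageVersion("memscape")))
  set.seed(seed)

  tab <- config$genotypes
  if (is.character(tab)) tab <- read_genotype_table(tab)
  stopifnot(inherits(tab, "genotype_table"))

  if ("dedup" %in% stages) {
    md <- run_stage("dedup", function() match_duplicates(tab))
    tab <- md$table
    results$dedup <- list(n_input = md$report$n_input,
                          n_unique = md$report$n_unique)
    write_genotype_table(tab, file.path(out_dir, "genotypes_unique.tsv"))
  }
  results$n <- n_ind(tab)

  D <- dps_distance(tab)
  Dgeo <- euclidean_distance(tab$xy)

  if ("stats" %in% stages) {
    results$stats <- run_stage("stats", function() {
      div <- diversity_stats(
        tab, groups = if (is.null(tab$group)) rep("all", n_ind(tab)),
        n_perm = n_perm)
      utils::write.table(div$multilocus,
                         file.path(out_dir, "diversity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out <- list(diversity = div$multilocus)
      if (!is.null(tab$group) && length(unique(tab$group)) >= 2L) {
        fst <- weir_cockerham_fst(tab, n_perm = n_perm)
        utils::write.table(
          data.frame(pair = outer(fst$groups, fst$groups, paste,
                                  sep = "/")[upper.tri(fst$theta)],
                     theta = fst$theta[upper.tri(fst$theta)],
                     p = fst$p[upper.tri(fst$p)]),
          file.path(out_dir, "fst.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        out$fst <- fst$theta
      }
      out
    })
  }

  if ("ibd" %in% stages) {
    results$ibd <- run_stage("ibd", function() {
      rows <- list(full = seq_len(n_ind(tab)))
      for (s in c("F", "M"))
        if (sum(tab$sex == s) >= 5L) rows[[s]] <- which(tab$sex == s)
      ibd <- do.call(rbind, lapply(names(rows), function(nm) {
        i <- rows[[nm]]
        mt <- mantel_test(Dgeo[i, i], D[i, i], n_perm = n_perm)
        data.frame(area = nm, r = mt$r, p = mt$p, n = mt$n)
      }))
      utils::write.table(ibd, file.path(out_dir, "ibd.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ibd
    })
  }

  mg <- NULL
  if ("memgene" %in% stages) {
    results$memgene <- run_stage("memgene", function() {
      mg <<- mgquick(tab, alpha = alpha, n_perm = n_perm, D = D)
      axes <- mg$axes
      if (NCOL(axes))
        utils::write.table(
          data.frame(id = tab$id, x = tab$xy[, 1], y = tab$xy[, 2],
                     axes = axes),
          file.path(out_dir, "memgene_axes.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      out <- list(full = list(adjR2 = mg$adjR2, R2 = mg$R2, p = mg$p,
                              n_axes = NCOL(axes),
                              proportions = mg$proportions))
      if (!is.null(tab$group)) {
        for (g in unique(tab$group)) {
          i <- which(tab$group == g)
          if (length(i) >= 10L) {
            mgg <- mgquick(tab[i], alpha = alpha, n_perm = n_perm)
            out[[paste0("group_", g)]] <-
              list(adjR2 = mgg$adjR2, p = mgg$p, n_axes = NCOL(mgg$axes))
          }
        }
      }
      out
    })
  }

  if ("landscape" %in% stages && !is.null(config$features)) {
    results$landscape <- run_stage("landscape", function() {
      feats <- config$features
      if (is.character(feats)) feats <- read_features_geojson(feats)
      ms <- model_search(tab, feats, n_perm = n_perm, alpha = alpha,
                         cell_size = config$cell_size)
      utils::write.table(ms$table, file.path(out_dir, "landscape.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(table = ms$table, best_costs = as.list(ms$best_costs))
    })
  }

  if ("mu" %in% stages && !is.null(config$mu_scenarios)) {
    results$mu <- run_stage("mu", function() {
      if (is.null(mg))
        mg <<- mgquick(tab, alpha = alpha, n_perm = n_perm, D = D)
      if (!NCOL(mg$axes))
        stop("no spatial genetic axes; MU comparison undefined")
      scs <- config$mu_scenarios
      parts <- lapply(names(scs), function(nm) {
        sc <- scs[[nm]]
        if (is.character(sc))
          sc <- mu_scenario(nm, polygons = read_features_geojson(sc))
        mu_varpart(mg, sc, n_perm = n_perm)
      })
      cmp <- compare_scenarios(parts)
      utils::write.table(cmp, file.path(out_dir, "mu_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cmp
    })
  }

  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  results$summary_path <- json_path
  invisible(results)
}
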