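#' Resolve duplicate genotypes from repeated sampling
#'
#' Non-invasively collected samples (e.g. fecal pellets) often yield the
#' same individual more than once. Two samples are called duplicates when
#' their unordered allele pairs agree at `min_matching_loci` or more loci
#' (default 8 of 9). Loci missing in either sample do not count as matches
#' unless `ignore_missing = TRUE`, in which case they are treated as
#' uninformative and counted as matching. Near-match chains are resolved by
#' transitive closure: connected components of the match graph collapse to
#' one unique individual, represented by the member with fewest missing
#' loci (ties broken by lowest input index). The representative's
#' coordinates are the centroid of the component members' coordinates.
#'
#' @param x a [genotype_table()] of raw samples.
#' @param min_matching_loci minimum number of matching loci to call a
#'   duplicate (default 8).
#' @param ignore_missing if `TRUE`, loci missing in either member of a pair
#'   count as matches instead of mismatches.
#' @return a list with elements `table` (deduplicated `genotype_table`) and
#'   `report` (class `match_report`): `n_input`, `n_unique`, `cluster_map`
#'   (input index -> unique index), and `mismatch_histogram`, the counts of
#'   merged pairs by number of mismatching loci.
#' @export
match_duplicates <- function(x, min_matching_loci = 8L,
                             ignore_missing = FALSE) {
  stopifnot(inherits(x, "genotype_table"))
  n <- n_ind(x); L <- n_loci(x)
  if (min_matching_loci > L)
    stop("min_matching_loci (", min_matching_loci, ") exceeds number of loci (",
         L, ")")

  # per-locus unordered genotype code; NA when missing
  a1 <- pmin(x$alleles[, , 1L], x$alleles[, , 2L])
  a2 <- pmax(x$alleles[, , 1L], x$alleles[, , 2L])
  stride <- max(a2, 1L, na.rm = TRUE) + 1L
  code <- a1 * stride + a2                       # n x L, NA = missing

  matches <- matrix(0L, n, n)
  for (l in seq_len(L)) {
    cl <- code[, l]
    eq <- outer(cl, cl, "==")
    if (ignore_missing) {
      eq[is.na(eq)] <- TRUE
    } else {
      eq[is.na(eq)] <- FALSE
    }
    matches <- matches + eq
  }
  diag(matches) <- 0L
  adj <- matches >= min_matching_loci

  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # renumber components by first appearance so output order is stable
  comp <- match(comp, unique(comp))
  k <- max(comp)

  n_missing <- rowSums(is.na(code))
  reps <- integer(k)
  for (cmp in seq_len(k)) {
    members <- which(comp == cmp)
    reps[cmp] <- members[which.min(n_missing[members])]
  }

  xy <- x$xy
  cent <- t(vapply(seq_len(k), function(cmp) {
    m <- comp == cmp
    c(mean(xy[m, 1], na.rm = TRUE), mean(xy[m, 2], na.rm = TRUE))
  }, numeric(2)))
  cent[is.nan(cent)] <- NA_real_

  out <- x[reps]
  out$xy <- cent
  colnames(out$xy) <- c("x", "y")

  # mismatch histogram over directly merged pairs (graph edges)
  ed <- igraph::as_edgelist(g, names = FALSE)
  mm <- if (nrow(ed)) table(factor(L - matches[ed], levels = 0:L))
        else table(factor(integer(), levels = 0:L))

  report <- structure(list(n_input = n, n_unique = k, cluster_map = comp,
                           mismatch_histogram = as.integer(mm),
                           min_matching_loci = as.integer(min_matching_loci),
                           ignore_missing = ignore_missing),
                      class = "match_report")
  list(table = out, report = report)
}

#' @export
print.match_report <- function(x, ...) {
  cat("match_report:", x$n_input, "samples ->", x$n_unique,
      "unique individuals\n")
  cat("  threshold:", x$min_matching_loci, "matching loci",
      if (x$ignore_missing) "(missing ignored)" else "(missing = mismatch)",
      "\n")
  nz <- which(x$mismatch_histogram > 0L) - 1L
  if (length(nz))
    cat("  merged-pair mismatches:",
        paste(sprintf("%d loci x %d", nz,
                      x$mismatch_histogram[nz + 1L]), collapse = ", "), "\n")
  invisible(x)
}
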