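#' Multilocus genotype table
#'
#' The central data container: `n` diploid individuals typed at `L`
#' codominant loci, with optional projected planar coordinates (meters),
#' sex, and a group label (e.g. genetic cluster or management unit).
#' Allele calls are positive integers (microsatellite repeat counts or
#' fragment sizes); missing data is `NA` in both slots of a locus —
#' half-missing genotypes are rejected.
#'
#' @param id character vector of individual identifiers (length `n`).
#' @param alleles integer array `n x L x 2` of allele codes; `NA` = missing.
#'   A matrix of `n x 2L` columns (two adjacent columns per locus) is also
#'   accepted.
#' @param xy optional numeric `n x 2` matrix of projected coordinates in
#'   meters; `NA` allowed.
#' @param sex optional character/factor with levels `F`, `M`, `U`
#'   (default all `U`).
#' @param group optional character vector of group labels.
#' @param loci optional character vector of locus names (default `L1..LL`).
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `id`, `alleles` (n x L x 2 integer array), `xy`, `sex`, `group`,
#'   `loci`.
#' @export
genotype_table <- function(id, alleles, xy = NULL, sex = NULL,
                           group = NULL, loci = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (n < 1L) stop("need at least one individual")
  if (is.matrix(alleles)) {
    if (ncol(alleles) %% 2L != 0L)
      stop("allele matrix must have two columns per locus")
    L <- ncol(alleles) %/% 2L
    a <- array(NA_integer_, c(n, L, 2L))
    a[, , 1L] <- as.integer(alleles[, seq(1L, 2L * L, by = 2L), drop = FALSE])
    a[, , 2L] <- as.integer(alleles[, seq(2L, 2L * L, by = 2L), drop = FALSE])
    alleles <- a
  }
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("'alleles' must be an n x L x 2 array")
  if (dim(alleles)[1] != n)
    stop("allele array rows (", dim(alleles)[1], ") != length(id) (", n, ")")
  storage.mode(alleles) <- "integer"
  L <- dim(alleles)[2]

  m1 <- matrix(is.na(alleles[, , 1L]), n, L)
  m2 <- matrix(is.na(alleles[, , 2L]), n, L)
  half <- xor(m1, m2)
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)
    stop("half-missing genotype(s), e.g. individual ", w[1, 1],
         " locus ", w[1, 2], "; both slots must be called or both missing")
  }
  if (any(alleles <= 0L, na.rm = TRUE))
    stop("allele codes must be positive integers (use NA for missing)")

  if (is.null(xy)) {
    xy <- matrix(NA_real_, n, 2L)
  } else {
    xy <- as.matrix(xy)
    storage.mode(xy) <- "double"
    if (nrow(xy) != n || ncol(xy) != 2L) stop("'xy' must be n x 2")
    if (any(is.infinite(xy))) stop("coordinates must be finite or NA")
  }
  colnames(xy) <- c("x", "y")

  if (is.null(sex)) sex <- rep("U", n)
  sex <- toupper(as.character(sex))
  sex[is.na(sex) | !sex %in% c("F", "M", "U")] <- "U"
  if (length(sex) != n) stop("'sex' must have length n")

  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != n) stop("'group' must have length n")
  }

  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  loci <- as.character(loci)
  if (length(loci) != L) stop("'loci' must have length L")
  dimnames(alleles) <- list(NULL, loci, NULL)

  structure(list(id = id, alleles = alleles, xy = xy, sex = sex,
                 group = group, loci = loci),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", n_ind(x), "individuals x", n_loci(x), "loci\n")
  cat("  loci:", paste(x$loci, collapse = ", "), "\n")
  miss <- mean(is.na(x$alleles[, , 1L]))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  if (!all(is.na(x$xy)))
    cat(sprintf("  extent: x [%.0f, %.0f], y [%.0f, %.0f] m\n",
                min(x$xy[, 1], na.rm = TRUE), max(x$xy[, 1], na.rm = TRUE),
                min(x$xy[, 2], na.rm = TRUE), max(x$xy[, 2], na.rm = TRUE)))
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of individuals / loci in a genotype table
#' @param x a `genotype_table`.
#' @return integer count.
#' @export
n_ind <- function(x) length(x$id)

#' @rdname n_ind
#' @export
n_loci <- function(x) dim(x$alleles)[2]

#' Subset individuals of a genotype table
#'
#' @param x a `genotype_table`.
#' @param i index vector over individuals (integer, logical, or ids).
#' @param ... ignored.
#' @export
`[.genotype_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  genotype_table(id = x$id[i],
                 alleles = x$alleles[i, , , drop = FALSE],
                 xy = x$xy[i, , drop = FALSE],
                 sex = x$sex[i],
                 group = if (!is.null(x$group)) x$group[i],
                 loci = x$loci)
}

# group labels with fallback; used by the popgen front-ends
gt_groups <- function(x, groups = NULL) {
  g <- if (is.null(groups)) x$group else as.character(groups)
  if (is.null(g)) stop("no group labels: supply 'groups' or set x$group")
  if (length(g) != n_ind(x)) stop("'groups' must have length n")
  g
}
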