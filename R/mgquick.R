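#' Spatial genetic regression on Moran's eigenvector maps
#'
#' The full MEM spatial-genetic pipeline for individual-based data:
#' proportion-of-shared-alleles dissimilarity -> principal coordinates
#' (response `Y`) -> MEM basis on Euclidean inter-individual distances ->
#' permutation forward selection of positive-class (and optionally
#' negative-class) eigenvectors -> redundancy analysis of `Y` on the
#' selected vectors. The spatial genetic axes are the orthogonal axes of
#' the fitted values ordered by their eigenvalues; the proportion of
#' genetic variation explained by spatial patterns is the adjusted R2 of
#' the RDA (the raw R2 is reported alongside). Overall significance is by
#' permutation of the response rows.
#'
#' @param x a [genotype_table()].
#' @param xy optional `n x 2` coordinates (default `x$xy`).
#' @param alpha selection significance level (default 0.05). When both
#'   eigenvector classes are considered the class-level global gates run
#'   at `alpha/2` each.
#' @param n_perm permutations for selection and the overall test
#'   (default 1000).
#' @param use_negative `"auto"` (include negative class only when its
#'   global test passes), `TRUE`, or `FALSE`.
#' @param truncation passed to [mem_basis()].
#' @param D optional precomputed genetic distance matrix (default
#'   [dps_distance()]).
#' @return object of class `memgene_result`: `axes` (`n x a` spatial
#'   genetic axes), `proportions` (per-axis share of explained variation),
#'   `R2`, `adjR2`, `p`, `selected_pos`, `selected_neg`, `X` (selected
#'   eigenvectors), `basis`, `xy`, `n`.
#' @export
mgquick <- function(x, xy = NULL, alpha = 0.05, n_perm = 1000L,
                    use_negative = "auto", truncation = "auto", D = NULL) {
  stopifnot(inherits(x, "genotype_table"))
  if (is.null(xy)) xy <- x$xy
  xy <- as.matrix(xy)
  if (anyNA(xy)) stop("coordinates required for all individuals")
  if (is.null(D)) D <- dps_distance(x)
  Y <- pcoa(D)$coords
  basis <- mem_basis(euclidean_distance(xy), truncation = truncation)
  mg_fit(Y, basis, alpha = alpha, n_perm = n_perm,
         use_negative = use_negative, xy = xy)
}

#' MEM selection + RDA on a precomputed response and basis
#'
#' The engine behind [mgquick()] and the landscape/management-unit
#' analyses: forward-selects eigenvectors from `basis` and fits the RDA.
#' Exposed so that responses other than genetic principal coordinates can
#' be analysed and so simulations can target the selection machinery
#' directly.
#'
#' @inheritParams mgquick
#' @param Y response matrix, `n` rows.
#' @param basis a [mem_basis()].
#' @param xy optional coordinates stored on the result.
#' @return a `memgene_result` (see [mgquick()]).
#' @export
mg_fit <- function(Y, basis, alpha = 0.05, n_perm = 1000L,
                   use_negative = "auto", xy = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  both <- !identical(use_negative, FALSE)
  galpha <- if (both) alpha / 2 else alpha
  fs_pos <- forward_select(Y, basis, "positive", alpha = alpha,
                           n_perm = n_perm, global_alpha = galpha)
  fs_neg <- NULL
  if (both && any(basis$class == "negative"))
    fs_neg <- forward_select(Y, basis, "negative", alpha = alpha,
                             n_perm = n_perm, global_alpha = galpha)
  sel_pos <- fs_pos$selected
  sel_neg <- if (is.null(fs_neg)) integer(0) else fs_neg$selected
  sel <- c(sel_pos, sel_neg)
  if (!length(sel)) {
    out <- list(axes = matrix(0, n, 0), proportions = numeric(0),
                R2 = 0, adjR2 = 0, p = 1,
                selected_pos = integer(0), selected_neg = integer(0),
                X = matrix(0, n, 0), basis = basis, xy = xy, n = n,
                fs_pos = fs_pos, fs_neg = fs_neg)
    class(out) <- "memgene_result"
    return(out)
  }
  X <- basis$vectors[, sel, drop = FALSE]
  fit <- rda_fit(Y, X, n_perm = n_perm)
  out <- list(axes = fit$axes, proportions = fit$proportions,
              R2 = fit$R2, adjR2 = fit$adjR2, p = fit$p,
              selected_pos = sel_pos, selected_neg = sel_neg,
              X = X, basis = basis, xy = xy, n = n,
              fs_pos = fs_pos, fs_neg = fs_neg)
  class(out) <- "memgene_result"
  out
}

#' @export
print.memgene_result <- function(x, ...) {
  cat("memgene_result: n =", x$n, "\n")
  cat(sprintf("  spatial variation explained: adj R2 = %.3f (raw %.3f), p = %s\n",
              x$adjR2, x$R2, format.pval(x$p)))
  cat("  selected eigenvectors:", length(x$selected_pos), "positive,",
      length(x$selected_neg), "negative\n")
  if (length(x$proportions))
    cat("  per-axis proportions:",
        paste(sprintf("%.2f", utils::head(x$proportions, 5L)),
              collapse = ", "),
        if (length(x$proportions) > 5L) "...", "\n")
  invisible(x)
}
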