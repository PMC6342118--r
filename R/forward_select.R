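#' Permutation-based forward selection of MEM eigenvectors
#'
#' Selects spatial eigenvectors of one Moran's-I sign class to explain a
#' (multivariate) response. The procedure guards against the familywise
#' inflation of stepwise selection with two stopping rules on top of a
#' global gate:
#'
#' 1. *Global test*: the full class regression is tested first by
#'    permutation; a non-significant class returns an empty selection.
#' 2. *Max-statistic step test*: at each step the best remaining candidate
#'    (largest marginal fit on the residualized response; ties broken by
#'    larger `|eigenvalue|`, then lower index) is tested against the
#'    permutation distribution of the *maximum* marginal fit over all
#'    remaining candidates, so the "pick the best of many" selection bias
#'    is built into the null. Selection stops at the first candidate with
#'    `p > alpha`; once the true signal is exhausted this happens with
#'    probability `1 - alpha` per step.
#'
#' Because MEM eigenvectors are orthonormal, marginal contributions are
#' additive and the conditional test permutes the residualized response.
#' `adjR2_global` (the adjusted R2 of the full class regression) is
#' reported for reference.
#'
#' @param Y response matrix (`n` rows), e.g. principal coordinates of a
#'   genetic distance.
#' @param basis a [mem_basis()].
#' @param class `"positive"` or `"negative"` eigenvector class.
#' @param alpha candidate significance level (default 0.05).
#' @param n_perm permutations per test (default 1000).
#' @param global_alpha level for the global gate (defaults to `alpha`;
#'   callers testing both classes should split alpha between them).
#' @return list of class `forward_selection`: `selected` (column indices
#'   into `basis$vectors`, possibly empty), `p_global`, `adjR2_global`
#'   (the cap), `R2_cum`, `adjR2_cum`, `p_values` (per accepted candidate),
#'   `class`.
#' @export
forward_select <- function(Y, basis, class = c("positive", "negative"),
                           alpha = 0.05, n_perm = 1000L,
                           global_alpha = alpha) {
  class <- match.arg(class)
  stopifnot(inherits(basis, "mem_basis"))
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n != basis$n) stop("Y rows must match basis size")
  cand <- which(basis$class == class)
  empty <- structure(list(selected = integer(0), p_global = 1,
                          adjR2_global = 0, R2_cum = 0, adjR2_cum = 0,
                          p_values = numeric(0), class = class),
                     class = "forward_selection")
  if (!length(cand)) return(empty)
  B <- basis$vectors[, cand, drop = FALSE]
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  totSS <- sum(Yc^2)
  if (totSS == 0) stop("constant response")

  # marginal R2 per candidate; additive because columns are orthonormal
  proj <- crossprod(B, Yc)
  r2 <- rowSums(proj^2) / totSS
  R2_global <- sum(r2)
  adjR2_global <- adj_r2(R2_global, n, length(cand))

  cnt <- 0L
  for (b in seq_len(n_perm)) {
    R2p <- sum(crossprod(B, Yc[sample.int(n), , drop = FALSE])^2) / totSS
    if (R2p >= R2_global - 1e-12) cnt <- cnt + 1L
  }
  p_global <- (cnt + 1) / (n_perm + 1)
  if (p_global > global_alpha) { empty$p_global <- p_global; return(empty) }
  empty$p_global <- p_global

  # scan rank: decreasing |eigenvalue| within the class
  scan_rank <- order(-abs(basis$values[cand]), cand)
  rank_of <- integer(length(cand)); rank_of[scan_rank] <- seq_along(cand)

  selected <- integer(0); pvals <- numeric(0)
  R <- Yc                      # residual response
  remaining <- seq_along(cand)
  R2_cum <- 0
  while (length(remaining)) {
    Brem <- B[, remaining, drop = FALSE]
    rss <- sum(R^2)
    if (rss <= 0) break
    r2_step <- rowSums(crossprod(Brem, R)^2) / rss
    pick <- order(-r2_step, rank_of[remaining])[1]
    stat <- r2_step[pick]
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      Rp <- R[sample.int(n), , drop = FALSE]
      if (max(rowSums(crossprod(Brem, Rp)^2)) / rss >= stat - 1e-12)
        cnt <- cnt + 1L
    }
    p_j <- (cnt + 1) / (n_perm + 1)
    if (p_j > alpha) break
    j <- remaining[pick]
    selected <- c(selected, j)
    pvals <- c(pvals, p_j)
    R2_cum <- R2_cum + r2[j]
    R <- R - B[, j] %*% crossprod(B[, j], R)
    remaining <- remaining[-pick]
  }
  structure(list(selected = cand[selected], p_global = p_global,
                 adjR2_global = adjR2_global, R2_cum = R2_cum,
                 adjR2_cum = adj_r2(R2_cum, n, length(selected)),
                 p_values = pvals, class = class),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("forward_selection (", x$class, "): ", length(x$selected),
      " vectors, global p = ", format.pval(x$p_global),
      ", cumulative adj R2 = ", round(x$adjR2_cum, 4), "\n", sep = "")
  invisible(x)
}
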