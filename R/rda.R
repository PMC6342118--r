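#' Redundancy analysis of a multivariate response on explanatory variables
#'
#' Column-centers `Y` and `X`, fits each response column on `X` by least
#' squares, and eigen-analyses the fitted values (via SVD). `R2` is the
#' proportion of the total response sum of squares captured by the fitted
#' values; the adjusted value uses Ezekiel's formula
#' `1 - (1 - R2) (n - 1) / (n - m - 1)` with `m = rank(X)`. Significance is
#' assessed by permuting the rows of `Y`.
#'
#' @param Y numeric matrix (or vector) response, `n` rows.
#' @param X numeric matrix of explanatory variables, `n` rows; `NULL` or
#'   zero columns give the null model (`R2 = 0`).
#' @param n_perm permutations for the overall test (default 0 = none).
#' @return list of class `rda_fit`: `fitted`, `axes` (orthogonal site
#'   scores of the fitted values, columns ordered by their eigenvalues),
#'   `proportions` (per-axis share of fitted variance), `R2`, `adjR2`,
#'   `rank`, `p`.
#' @export
rda_fit <- function(Y, X, n_perm = 0L) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  totSS <- sum(Yc^2)
  if (totSS == 0) stop("constant response")
  if (is.null(X) || NCOL(X) == 0L) {
    return(structure(list(fitted = Yc * 0,
                          axes = matrix(0, n, 0), proportions = numeric(0),
                          R2 = 0, adjR2 = 0, rank = 0L, p = 1),
                     class = "rda_fit"))
  }
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and Y must have the same number of rows")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  m <- qrX$rank
  Q <- qr.Q(qrX)[, seq_len(m), drop = FALSE]
  fitted <- Q %*% crossprod(Q, Yc)
  R2 <- sum(fitted^2) / totSS
  sv <- svd(fitted)
  pos <- sv$d^2 > 1e-12 * max(sv$d^2, 1e-300)
  axes <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], sum(pos))
  props <- sv$d[pos]^2 / sum(sv$d[pos]^2)
  p <- NA_real_
  if (n_perm > 0L) {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      Yp <- Yc[sample.int(n), , drop = FALSE]
      # recenter not needed: permutation preserves column means (0)
      R2p <- sum(crossprod(Q, Yp)^2) / totSS
      if (R2p >= R2 - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  structure(list(fitted = fitted, axes = axes, proportions = props,
                 R2 = R2, adjR2 = adj_r2(R2, n, m), rank = m, p = p),
            class = "rda_fit")
}

# Ezekiel's adjusted R2; falls back to the raw R2 when the residual
# degrees of freedom vanish (saturated model)
adj_r2 <- function(R2, n, m) {
  if (m <= 0L) return(0)
  if (n - m - 1 <= 0) return(R2)
  1 - (1 - R2) * (n - 1) / (n - m - 1)
}
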