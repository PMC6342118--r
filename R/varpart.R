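# Two-block variation partitioning on adjusted R2 (Peres-Neto et al. 2006).
# Shared by the landscape (IBR vs IBD) and management-unit analyses; the
# caller decides how the unique/shared fractions are labelled.

#' Partition response variation between two explanatory blocks
#'
#' Computes adjusted-R2 fractions for explanatory blocks `X1` and `X2`:
#' `abc = adjR2(Y ~ X1 u X2)`, `ab = adjR2(Y ~ X1)`, `bc = adjR2(Y ~ X2)`,
#' unique fractions `a = abc - bc`, `c = abc - ab`, shared
#' `b = ab + bc - abc`, residual `d = 1 - abc`. The identities
#' `a + b + c = abc` and `abc + d = 1` hold exactly by construction. Small
#' negative adjusted fractions are possible and reported as computed.
#' P-values: `p_abc` permutes the response rows; the partial tests `p_a`
#' (`X1 | X2`) and `p_c` (`X2 | X1`) permute the residualized response.
#'
#' @param Y response matrix, `n` rows.
#' @param X1,X2 explanatory matrices (`NULL`/0 columns = empty block).
#' @param n_perm permutations (default 999; 0 skips tests).
#' @param labels character(2), block labels used in printing.
#' @return list of class `variation_partition`: `abc`, `a`, `b`, `c`, `d`,
#'   `p_abc`, `p_a`, `p_c`, `rank1`, `rank2`, `labels`.
#' @export
varpart2 <- function(Y, X1, X2, n_perm = 999L,
                     labels = c("X1", "X2")) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  e1 <- is.null(X1) || NCOL(X1) == 0L
  e2 <- is.null(X2) || NCOL(X2) == 0L
  fit1 <- rda_fit(Y, if (e1) NULL else X1)
  fit2 <- rda_fit(Y, if (e2) NULL else X2)
  X12 <- if (e1 && e2) NULL else
    cbind(if (!e1) as.matrix(X1), if (!e2) as.matrix(X2))
  fit12 <- rda_fit(Y, X12)
  abc <- fit12$adjR2; ab <- fit1$adjR2; bc <- fit2$adjR2
  a <- abc - bc; cc <- abc - ab; b <- ab + bc - abc
  d <- 1 - abc
  p_abc <- p_a <- p_c <- NA_real_
  if (n_perm > 0L && !(e1 && e2)) {
    p_abc <- perm_r2_test(Y, X12, n_perm)
    if (!e1) p_a <- partial_perm_test(Y, X1, if (e2) NULL else X2, n_perm)
    if (!e2) p_c <- partial_perm_test(Y, X2, if (e1) NULL else X1, n_perm)
  }
  structure(list(abc = abc, a = a, b = b, c = cc, d = d,
                 p_abc = p_abc, p_a = p_a, p_c = p_c,
                 rank1 = fit1$rank, rank2 = fit2$rank,
                 labels = labels, n = n),
            class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  cat("variation partition (", x$labels[1], " vs ", x$labels[2], "):\n",
      sep = "")
  cat(sprintf("  [abc] %.3f (p = %s)\n", x$abc, format.pval(x$p_abc)))
  cat(sprintf("  [a] %s-unique   %.3f (p = %s)\n", x$labels[1], x$a,
              format.pval(x$p_a)))
  cat(sprintf("  [c] %s-unique   %.3f (p = %s)\n", x$labels[2], x$c,
              format.pval(x$p_c)))
  cat(sprintf("  [b] confounded  %.3f\n  [d] residual    %.3f\n",
              x$b, x$d))
  invisible(x)
}

# permutation test of R2(Y ~ X), permuting rows of Y
perm_r2_test <- function(Y, X, n_perm) {
  if (is.null(X) || NCOL(X) == 0L) return(1)
  Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  totSS <- sum(Yc^2)
  n <- nrow(Yc)
  qrX <- qr(scale(as.matrix(X), center = TRUE, scale = FALSE))
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  R2 <- sum(crossprod(Q, Yc)^2) / totSS
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    if (sum(crossprod(Q, Yc[sample.int(n), , drop = FALSE])^2) / totSS >=
        R2 - 1e-12) cnt <- cnt + 1L
  }
  (cnt + 1) / (n_perm + 1)
}

# partial test of Xtest given Xcond: residualize response and Xtest on
# Xcond, permute the residualized response (residualized-response scheme)
partial_perm_test <- function(Y, Xtest, Xcond, n_perm) {
  Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  n <- nrow(Yc)
  if (!is.null(Xcond) && NCOL(Xcond) > 0L) {
    qrC <- qr(scale(as.matrix(Xcond), center = TRUE, scale = FALSE))
    Qc <- qr.Q(qrC)[, seq_len(qrC$rank), drop = FALSE]
    Yr <- Yc - Qc %*% crossprod(Qc, Yc)
    Xc <- scale(as.matrix(Xtest), center = TRUE, scale = FALSE)
    Xr <- Xc - Qc %*% crossprod(Qc, Xc)
  } else {
    Yr <- Yc
    Xr <- scale(as.matrix(Xtest), center = TRUE, scale = FALSE)
  }
  qrT <- qr(Xr)
  rk <- qrT$rank
  if (rk == 0L) return(1)
  Qt <- qr.Q(qrT)[, seq_len(rk), drop = FALSE]
  rss <- sum(Yr^2)
  if (rss == 0) return(1)
  stat <- sum(crossprod(Qt, Yr)^2) / rss
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    Yp <- Yr[sample.int(n), , drop = FALSE]
    if (sum(crossprod(Qt, Yp)^2) / sum(Yp^2) >= stat - 1e-12)
      cnt <- cnt + 1L
  }
  (cnt + 1) / (n_perm + 1)
}
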