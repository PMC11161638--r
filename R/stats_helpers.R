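# Shared regression machinery.
#
# .ols_test: single-response OLS returning the coefficient, two-sided t-test
# p-value and n for one focal column of the design. Used gene-by-gene.
#
# .ols_test_batch: many responses sharing one design matrix (power
# simulation): computes all coefficient p-values in one set of matrix
# products.
#
# .scan_fwl: many regressors (variants) sharing one response and covariate
# block; uses Frisch-Waugh-Lovell residualisation, exactly equivalent to the
# per-variant full OLS fit.

.ols_test <- function(y, x, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, x = x)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    return(list(beta = NA_real_, p = NA_real_, n = sum(keep),
                singular = TRUE))
  }
  fit <- qr.coef(qrX, y)
  res <- y - X %*% fit
  df <- length(y) - ncol(X)
  if (df <= 0) return(list(beta = unname(fit["x"]), p = NA_real_,
                           n = length(y), singular = FALSE))
  sigma2 <- sum(res^2) / df
  XtXi <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXi[2, 2])
  tval <- fit["x"] / se
  list(beta = unname(fit["x"]), p = unname(2 * pt(-abs(tval), df)),
       n = length(y), singular = FALSE)
}

.ols_test_batch <- function(X, Y, j) {
  qrX <- qr(X)
  stopifnot(qrX$rank == ncol(X))
  B <- qr.coef(qrX, Y)
  R <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(R^2) / df
  XtXi <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXi[j, j])
  tval <- B[j, ] / se
  list(beta = B[j, ], p = 2 * pt(-abs(tval), df))
}

# y: response; G: n x V dosage matrix (no missing); C: covariate matrix
# including intercept. Returns per-variant beta and p for the dosage term of
# the full model y ~ dosage + C.
.scan_fwl <- function(y, G, C) {
  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  RG <- qr.resid(qrC, G)
  gg <- colSums(RG^2)
  gy <- as.vector(crossprod(RG, ry))
  beta <- gy / gg
  df <- length(y) - qrC$rank - 1L
  rss <- sum(ry^2) - beta^2 * gg
  rss[rss < 0] <- 0
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gg)
  tval <- beta / se
  list(beta = beta, p = 2 * pt(-abs(tval), df), df = df)
}

# lineage factor -> covariate matrix with intercept; the smallest lineage is
# the dropped pivot
lineage_design <- function(lineage) {
  lineage <- droplevels(as.factor(lineage))
  if (nlevels(lineage) <= 1) return(matrix(1, length(lineage), 1,
                                           dimnames = list(NULL, "(Intercept)")))
  pivot <- names(which.min(table(lineage)))
  lineage <- stats::relevel(lineage, ref = pivot)
  stats::model.matrix(~lineage)
}

#' Squared-correlation linkage disequilibrium
#'
#' Composite LD between two variants: the squared Pearson correlation of
#' their diploid dosages over samples non-missing in both (no phasing).
#'
#' @param a,b Numeric dosage vectors in `{0, 1, 2}` (NA allowed).
#' @return r-squared in `[0, 1]`, or `NA` if fewer than 2 complete pairs or
#'   either vector is constant.
#' @export
ld_r2 <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)^2
}
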