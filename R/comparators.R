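#' Single-SNP association scan with optional polygenic background
#'
#' For each variant in turn, fits phenotype = covariates + variant by
#' weighted least squares, optionally after whitening with the covariance
#' `sigma2_a A + sigma2_e diag(1/w)` of a polygenic mixed model (variance
#' components either fixed from `h2_poly` or profiled by REML when weights
#' are uniform). Reports the Wald test per variant.
#'
#' @param pheno a [phenotype_table()]
#' @param W a `std_design` or numeric matrix of genotypes (any coding; the
#'   test is invariant to linear recoding)
#' @param A optional relationship matrix enabling the polygenic term
#' @param h2_poly fixed polygenic heritability used to set the variance
#'   components; `NULL` with `A` requests REML
#' @return data.frame (`gwas_result`) with columns `chrom`, `pos`, `id`,
#'   `beta`, `se`, `p`, `neg_log10_p`
#' @export
gwas_single_snp <- function(pheno, W, A = NULL, h2_poly = 0.3) {
  sd <- resolve_design(W)
  y <- pheno$y; X <- pheno$X; w <- pheno$weights
  n <- length(y)
  Wm <- sd$W
  if (!is.null(A)) {
    vy <- stats::var(y)
    if (is.null(h2_poly)) {
      if (stats::sd(pheno$weights) > 0)
        stop("REML for the polygenic term requires uniform weights; supply h2_poly")
      h2_poly <- reml_h2(y, X, A)
    }
    V <- h2_poly * vy * A + diag((1 - h2_poly) * vy / w)
    L <- t(chol(V))
    y <- drop(forwardsolve(L, y))
    X <- forwardsolve(L, X)
    Wm <- forwardsolve(L, Wm)
    w <- rep(1, n)
  }
  # weighted projection on the covariates
  XtDX <- crossprod(X, X * w)
  coefy <- solve(XtDX, crossprod(X, w * y))
  ytil <- y - drop(X %*% coefy)
  Wt <- Wm - X %*% solve(XtDX, crossprod(X, w * Wm))
  den <- colSums(Wt * (w * Wt))
  num <- colSums(Wt * (w * ytil))
  yy <- sum(w * ytil^2)
  df <- n - ncol(X) - 1
  bad <- den <= .Machine$double.eps * n
  if (any(bad)) warning(sum(bad), " variant(s) with singular system set to NA")
  beta <- ifelse(bad, NA_real_, num / den)
  rss <- pmax(yy - ifelse(bad, 0, num^2 / den), 0)
  s2 <- rss / df
  se <- ifelse(bad, NA_real_, sqrt(s2 / den))
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(chrom = sd$map$chrom, pos = sd$map$pos, id = sd$map$id,
                    beta = beta, se = se, p = p,
                    neg_log10_p = -log10(p))
  class(out) <- c("gwas_result", "data.frame")
  out
}

# profile REML for h2 on the eigendecomposition of A (uniform weights)
reml_h2 <- function(y, X, A) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-10)
  yr <- crossprod(eg$vectors, y)
  Xr <- crossprod(eg$vectors, X)
  n <- length(y); p <- ncol(X)
  nll <- function(h2) {
    d <- h2 * lam + (1 - h2)
    XtVX <- crossprod(Xr, Xr / d)
    b <- solve(XtVX, crossprod(Xr, yr / d))
    r <- yr - Xr %*% b
    ss <- sum(r^2 / d)
    s2 <- ss / (n - p)
    0.5 * (sum(log(d)) + (n - p) * log(s2) + determinant(XtVX)$modulus)
  }
  stats::optimize(nll, c(1e-4, 1 - 1e-4))$minimum
}

#' SNP-BLUP / GBLUP fit
#'
#' Linear mixed model in which every variant effect is drawn from one common
#' normal distribution `N(0, sigma2_g / m)`; equivalent to GBLUP with
#' genomic relationship matrix `G = W W' / m`. Solved in the dual (n x n)
#' form: `vhat = sigma2_v W' V^{-1} (y - X bhat)` with
#' `V = sigma2_v W W' + diag(sigma2_e / w)`.
#'
#' @param pheno a [phenotype_table()]
#' @param W training `std_design` (standardized genotypes)
#' @param h2 heritability fixing the variance components
#'   (`sigma2_g = h2 * var(y)`), or `NULL` for REML (uniform weights only)
#' @return object of class `gblup_fit`: list with `vhat`, `b`, `h2`,
#'   `sigma2_g`, `sigma2_e`, and the variant `map`
#' @export
gblup_fit <- function(pheno, W, h2 = 0.5) {
  sd <- resolve_design(W)
  y <- pheno$y; X <- pheno$X; w <- pheno$weights
  n <- length(y); m <- ncol(sd$W)
  if (is.null(h2)) {
    if (stats::sd(w) > 0) stop("REML requires uniform weights; supply h2")
    h2 <- reml_h2(y, X, tcrossprod(sd$W) / m)
  }
  vy <- stats::var(y)
  sigma2_g <- h2 * vy
  sigma2_e <- (1 - h2) * vy
  if (sigma2_e <= 0) sigma2_e <- 1e-8 * vy
  sigma2_v <- sigma2_g / m
  V <- sigma2_v * tcrossprod(sd$W) + diag(sigma2_e / w)
  Vi <- chol2inv(chol(V))
  XtViX <- crossprod(X, Vi %*% X)
  b <- drop(solve(XtViX, crossprod(X, Vi %*% y)))
  r <- y - drop(X %*% b)
  vhat <- drop(sigma2_v * crossprod(sd$W, Vi %*% r))
  structure(list(vhat = vhat, b = b, h2 = h2, sigma2_g = sigma2_g,
                 sigma2_e = sigma2_e, map = sd$map),
            class = "gblup_fit")
}

#' Predict genetic values from a GBLUP fit
#' @param object a `gblup_fit`
#' @param W_val validation `std_design` built with training centring/scale
#' @param ... unused
#' @return numeric vector of predicted genetic values
#' @export
predict.gblup_fit <- function(object, W_val, ...) {
  sd <- resolve_design(W_val)
  drop(sd$W %*% object$vhat)
}
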