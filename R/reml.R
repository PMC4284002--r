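# Spectral REML for the single-random-effect mixed model
#   y = X b + u + e,  u ~ N(0, sigma2_g K),  e ~ N(0, sigma2_e I).
# The restricted likelihood is profiled over the variance ratio
# delta = sigma2_e / sigma2_g after one eigendecomposition of the
# X-projected kinship, so refits (e.g. per perturbation replicate, or per
# training fold) cost only a 1-D optimization. Shared by the trait-BLUP,
# EMMAX-GWAS and ridge-prediction code.

#' Restricted-likelihood fit of the variance ratio
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (include the intercept column).
#' @param K Positive semi-definite covariance structure of the random
#'   effect (kinship, genomic relationship, or an incidence cross-product).
#' @param log_delta_range Search interval for `log(delta)`.
#' @param eig_K Optional pre-computed `eigen(K, symmetric = TRUE)` for
#'   reuse across calls with the same `K`.
#' @param eig_SKS Optional pre-computed projected eigendecomposition (as
#'   returned in the `proj` element) for reuse across responses sharing
#'   `X` and `K`.
#' @return A list with the REML estimates `delta`, `sigma2_g`, `sigma2_e`,
#'   the restricted log-likelihood `loglik`, and cached spectral parts
#'   (`eig_K`, `proj`) for downstream generalized least squares.
#' @keywords internal
reml_mixed <- function(y, X, K, log_delta_range = c(-10, 10),
                       eig_K = NULL, eig_SKS = NULL) {
  n <- length(y)
  X <- as.matrix(X)
  q <- qr(X)$rank
  if (n < q + 2) stop("too few observations for the fixed-effect design", call. = FALSE)

  if (is.null(eig_SKS)) {
    qrX <- qr(X)
    Q1 <- qr.Q(qrX)[, seq_len(q), drop = FALSE]
    # decompose S (K + I) S: contrast directions get eigenvalue xi + 1 >= 1
    # while the X-span gets 0, so the top n - q eigenvectors are exactly the
    # contrasts orthogonal to X (K's own null space cannot be told apart
    # from span(X) in S K S alone)
    K1 <- K + diag(n)
    KQ <- K1 %*% Q1
    SKS <- K1 - Q1 %*% t(KQ) - KQ %*% t(Q1) +
      Q1 %*% (crossprod(Q1, KQ) %*% t(Q1))
    e <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
    keep <- seq_len(n - q)
    xi <- pmax(e$values[keep] - 1, 0)
    U <- e$vectors[, keep, drop = FALSE]
    eig_SKS <- list(xi = xi, U = U, q = q)
  }
  xi <- eig_SKS$xi
  nq <- n - eig_SKS$q
  eta <- drop(crossprod(eig_SKS$U, y))
  if (max(xi) - min(xi) < 1e-10) {
    warning("kinship matrix carries no structure (proportional to identity); ",
            "the variance ratio is not identifiable", call. = FALSE)
  }

  neg_rll <- function(ld) {
    w <- xi + exp(ld)
    0.5 * (nq * log(sum(eta^2 / w)) + sum(log(w)))
  }
  # coarse grid to dodge local optima, then refine
  grid <- seq(log_delta_range[1], log_delta_range[2], length.out = 81)
  vals <- vapply(grid, neg_rll, 0)
  i0 <- which.min(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(neg_rll, c(lo, hi), tol = 1e-10)
  delta <- exp(opt$minimum)
  w <- xi + delta
  sigma2_g <- sum(eta^2 / w) / nq
  loglik <- 0.5 * (nq * log(nq / (2 * pi)) - nq -
                     nq * log(sum(eta^2 / w)) - sum(log(w)))
  list(delta = delta, sigma2_g = sigma2_g, sigma2_e = delta * sigma2_g,
       loglik = loglik, eig_K = eig_K, proj = eig_SKS)
}

# Generalized least squares given V propto (K + delta I), via eig_K.
# Returns the rotated/whitened response and design for downstream per-marker
# work, plus the GLS fixed-effect solution.
gls_rotate <- function(y, X, eig_K, delta) {
  w <- pmax(eig_K$values, 0) + delta
  Tm <- t(eig_K$vectors) / sqrt(w)   # whitening transform
  y_t <- drop(Tm %*% y)
  X_t <- Tm %*% X
  qrX <- qr(X_t)
  beta <- qr.coef(qrX, y_t)
  list(y_t = y_t, X_t = X_t, Tm = Tm, beta = beta, qrX = qrX, w = w)
}
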