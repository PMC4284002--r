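# Independent oracles and small fixture builders shared across tests.

# Hudson's two-population Fst estimator (ratio of averages), computed
# directly from subpopulation allele frequencies -- independent of the
# generator's internals.
hudson_fst <- function(dosage, pops) {
  stopifnot(length(unique(pops)) == 2)
  sp <- unique(pops)
  p1 <- colMeans(dosage[pops == sp[1], , drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(dosage[pops == sp[2], , drop = FALSE], na.rm = TRUE) / 2
  n1 <- 2 * colSums(!is.na(dosage[pops == sp[1], , drop = FALSE]))
  n2 <- 2 * colSums(!is.na(dosage[pops == sp[2], , drop = FALSE]))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- is.finite(num) & is.finite(den) & den > 0
  sum(num[ok]) / sum(den[ok])
}

# Dense-matrix GLS association oracle: full n x n solve per marker, no
# spectral shortcut (checks emmax_scan's whitened computation).
dense_gls_pvalues <- function(y, G, V, df_extra = 0) {
  n <- length(y)
  Vi <- solve(V)
  vapply(seq_len(ncol(G)), function(j) {
    Xj <- cbind(1, G[, j])
    XtVi <- crossprod(Xj, Vi)
    b <- solve(XtVi %*% Xj, XtVi %*% y)
    r <- y - Xj %*% b
    s2 <- drop(crossprod(r, Vi %*% r)) / (n - 2 - df_extra)
    se <- sqrt(diag(solve(XtVi %*% Xj))[2] * s2)
    stats::pf((b[2] / se)^2, 1, n - 2 - df_extra, lower.tail = FALSE)
  }, 0)
}

with_seed_rnorm <- function(seed, n, ...) {
  set.seed(seed)
  stats::rnorm(n, ...)
}

# A small genotype table built from an explicit dosage matrix.
toy_gt <- function(dosage, ...) {
  genotype_table(as.matrix(dosage), ...)
}

# Cached mid-sized structured panel reused by several test files.
shared_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pm <- population_model(n_individuals = 140, n_loci = 2000, fst = 0.05,
                             missing_rate = 0.02, seed = 31)
      cache <<- simulate_structured_genotypes(pm)
    }
    cache
  }
})
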