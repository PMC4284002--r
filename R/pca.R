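# Genotype PCA with Tracy-Widom axis significance, outlier detection,
# subpopulation assignment and trait-structure correlations.

#' Principal component analysis of genotypes
#'
#' Mean-imputed dosages are centered at twice the observed allele frequency
#' and scaled by `sqrt(p * (1 - p))` (the binomial normalization under
#' which the null eigenvalue spectrum follows Tracy-Widom theory); the
#' individual-by-individual covariance `M M' / m` is then
#' eigendecomposed. Each axis is assigned a Tracy-Widom p-value using the
#' moment estimator of the effective marker count applied to the eigenvalue
#' spectrum remaining after the preceding axes are removed.
#'
#' @param gt A [genotype_table()] (monomorphic loci are excluded).
#' @param max_axes Number of axes to return scores for.
#' @return An object of class `pca_result` with `eigenvalues` (all `n - 1`),
#'   `scores` (unit-norm eigenvectors, individuals x axes), `loadings`
#'   (loci x axes), `tw_pvalues`, `pct_variance`, and the individual ids.
#' @export
pca_genotypes <- function(gt, max_axes = 10) {
  n <- n_individuals(gt)
  if (n < 3) stop("need at least 3 individuals for PCA", call. = FALSE)
  X <- impute_mean(gt)
  p <- allele_freq(gt)
  keep <- p > 0 & p < 1 & apply(X, 2, stats::sd) > 0
  if (sum(keep) < 2) stop("fewer than 2 polymorphic loci", call. = FALSE)
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  m <- ncol(X)
  M <- sweep(sweep(X, 2, 2 * p), 2, sqrt(p * (1 - p)), "/")
  C <- tcrossprod(M) / m
  e <- eigen(C, symmetric = TRUE)
  n_ev <- n - 1                 # centering removes one dimension
  ev <- pmax(e$values[seq_len(n_ev)], 0)
  k <- min(max_axes, n_ev)
  scores <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(scores) <- gt$individual_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  loadings <- crossprod(M, scores)
  loadings <- sweep(loadings, 2, sqrt(colSums(loadings^2)), "/")
  rownames(loadings) <- gt$loci$locus_id[keep]

  structure(
    list(eigenvalues = ev,
         scores = scores,
         loadings = loadings,
         tw_pvalues = tw_axis_pvalues(ev, k),
         pct_variance = 100 * ev[seq_len(k)] / sum(ev),
         ids = gt$individual_ids,
         trace = sum(diag(C)),
         n_loci_used = m),
    class = "pca_result"
  )
}

# Patterson-style per-axis Tracy-Widom p-values: for axis j, restrict to the
# eigenvalues from rank j on, estimate the effective marker count by moment
# matching, standardize the leading eigenvalue, and refer it to TW(GOE).
tw_axis_pvalues <- function(ev, k) {
  n_ev <- length(ev)
  vapply(seq_len(k), function(j) {
    lam <- ev[j:n_ev]
    mprime <- length(lam) + 1          # samples remaining for this axis
    lsum <- sum(lam)
    if (lsum <= 0 || length(lam) < 2) return(NA_real_)
    n_eff <- ((mprime + 1) * lsum^2) /
      ((mprime - 1) * sum(lam^2) - lsum^2)
    if (!is.finite(n_eff) || n_eff <= 1) return(NA_real_)
    l_stat <- (mprime - 1) * lam[1] / lsum
    mu <- (sqrt(n_eff - 1) + sqrt(mprime))^2 / n_eff
    sig <- (sqrt(n_eff - 1) + sqrt(mprime)) / n_eff *
      (1 / sqrt(n_eff - 1) + 1 / sqrt(mprime))^(1 / 3)
    tw1_pvalue((l_stat - mu) / sig)
  }, 0)
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("<pca_result> %d individuals, %d loci, %d axes\n",
              length(x$ids), x$n_loci_used, k))
  show <- min(k, 5)
  for (j in seq_len(show)) {
    cat(sprintf("  PC%d: %.2f%% of variance, TW p = %.3g\n", j,
                x$pct_variance[j], x$tw_pvalues[j]))
  }
  invisible(x)
}

#' Tidy a `pca_result`
#'
#' @param x A [pca_genotypes()] result.
#' @param ... Unused.
#' @return A tibble of per-individual scores (`id`, `PC1`, ...); `glance()`
#'   returns per-axis eigenvalues, variance shares and TW p-values.
#' @export
tidy.pca_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(id = x$ids),
                   tibble::as_tibble(x$scores))
}

#' @rdname tidy.pca_result
#' @export
glance.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  tibble::tibble(axis = seq_len(k),
                 eigenvalue = x$eigenvalues[seq_len(k)],
                 pct_variance = x$pct_variance,
                 tw_pvalue = x$tw_pvalues)
}

#' Iterative PCA outlier detection
#'
#' Flags individuals lying more than `sd_threshold` standard deviations
#' from the mean along any of the examined axes, removes them, recomputes
#' the PCA, and repeats until no new outliers appear or `max_iter` rounds
#' have run (the defaults mirror the usual smartpca settings: 6 SD, top 10
#' axes, 5 iterations).
#'
#' @param gt A [genotype_table()].
#' @param sd_threshold Flagging threshold in per-axis SD units.
#' @param n_axes Number of leading axes examined.
#' @param max_iter Maximum removal rounds.
#' @param axes_rule `"top_n"` examines the first `n_axes` axes regardless of
#'   significance; `"significant"` restricts them to axes with Tracy-Widom
#'   p-value below `tw_alpha`.
#' @param tw_alpha Significance gate used when `axes_rule = "significant"`.
#' @return Character vector of outlier individual ids (possibly empty).
#' @export
detect_outliers <- function(gt, sd_threshold = 6, n_axes = 10, max_iter = 5,
                            axes_rule = c("top_n", "significant"),
                            tw_alpha = 1e-4) {
  if (n_axes < 1) stop("invalid parameter: n_axes must be >= 1", call. = FALSE)
  if (sd_threshold <= 0) stop("invalid parameter: sd_threshold must be positive", call. = FALSE)
  axes_rule <- match.arg(axes_rule)
  current <- gt
  outliers <- character(0)
  for (iter in seq_len(max_iter)) {
    pca <- pca_genotypes(current, max_axes = n_axes)
    axes <- seq_len(ncol(pca$scores))
    if (axes_rule == "significant") {
      axes <- axes[!is.na(pca$tw_pvalues[axes]) & pca$tw_pvalues[axes] < tw_alpha]
      if (length(axes) == 0) break
    }
    S <- pca$scores[, axes, drop = FALSE]
    z <- abs(scale(S))
    flagged <- rownames(S)[apply(z, 1, max) > sd_threshold]
    if (length(flagged) == 0) break
    outliers <- c(outliers, flagged)
    keep <- setdiff(current$individual_ids, flagged)
    if (length(keep) < 3) break
    current <- current[keep, ]
  }
  outliers
}

#' Assign individuals to subpopulations from PCA scores
#'
#' Partitions individuals into `k` groups by Ward hierarchical clustering
#' of the scores on the significant axes (Tracy-Widom p below `tw_alpha`;
#' the first axis is always used as a fallback). Clusters are labelled
#' `pop1..popk` in order of their mean PC1 score, so the output is fully
#' deterministic.
#'
#' @param pca A [pca_genotypes()] result.
#' @param k Number of groups (`1 <= k <= n`).
#' @param tw_alpha Axis-significance gate.
#' @return Character vector of labels, named by individual id.
#' @export
assign_subpops <- function(pca, k, tw_alpha = 1e-4) {
  n <- length(pca$ids)
  if (k > n) stop("k exceeds the number of individuals", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k == 1) return(stats::setNames(rep("pop1", n), pca$ids))
  axes <- which(!is.na(pca$tw_pvalues) & pca$tw_pvalues < tw_alpha)
  if (length(axes) == 0) axes <- 1L
  S <- pca$scores[, axes, drop = FALSE]
  hc <- stats::hclust(stats::dist(S), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  ord <- rank(tapply(pca$scores[, 1], cl, mean), ties.method = "first")
  labels <- paste0("pop", ord[cl])
  stats::setNames(labels, pca$ids)
}

#' Correlate a trait with structure axes
#'
#' Pearson correlation (with two-sided t-test p-values) between per-genotype
#' trait BLUPs and the scores of the requested principal component axes.
#'
#' @param blups A [estimate_blups()] result (or `(genotype_id, blup)` data
#'   frame / named vector).
#' @param pca A [pca_genotypes()] result.
#' @param axes Integer vector of axes.
#' @return A tibble with `axis`, `r`, `p_value`, `n`.
#' @export
correlate_trait_with_axes <- function(blups, pca, axes = c(1, 2)) {
  b <- blup_vector(blups)
  shared <- intersect(names(b), pca$ids)
  if (length(shared) < 3) stop("fewer than 3 shared genotype ids", call. = FALSE)
  S <- pca$scores[match(shared, pca$ids), , drop = FALSE]
  purrr::map_dfr(axes, function(j) {
    ct <- stats::cor.test(b[shared], S[, j])
    tibble::tibble(axis = j, r = unname(ct$estimate),
                   p_value = ct$p.value, n = length(shared))
  })
}
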