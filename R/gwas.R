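# Mixed-linear-model association: EMMAX-style single-locus scans with a
# kinship matrix and optional PC covariates, a naive least-squares
# comparison scan, multiple-testing control, and multi-locus
# forward-backward model selection.

align_response <- function(y, gt = NULL, K = NULL, X = NULL) {
  y <- blup_vector(y)
  ids <- names(y)
  if (!is.null(gt)) {
    missing_ids <- setdiff(ids, gt$individual_ids)
    if (length(missing_ids)) {
      stop("ids present in the response but absent from the genotypes: ",
           paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
    }
    ids <- ids[ids %in% gt$individual_ids]
  }
  if (!is.null(K)) ids <- ids[ids %in% K$ids]
  if (!is.null(X) && !is.null(rownames(X))) ids <- ids[ids %in% rownames(X)]
  list(y = y[ids], ids = ids)
}

#' Fit the null mixed model for association scans
#'
#' Estimates the variance components of `y = X b + u + e` with
#' `u ~ N(0, sigma2_g K)` by spectral REML, and caches the whitening
#' transform so every marker can then be tested by generalized least
#' squares at fixed variance components (the EMMAX approximation).
#'
#' @param y Trait BLUPs: a [estimate_blups()] result, a `(genotype_id,
#'   blup)` data frame, or a named numeric vector.
#' @param K A `kinship_matrix` (from [ibs_kinship()] or [grm_vanraden()]).
#' @param covariates Optional numeric matrix of covariates (e.g. PC scores),
#'   rows named by individual id; an intercept is always added.
#' @return An object of class `mlm_null` with variance components
#'   (`sigma2_g`, `sigma2_e`, `delta`), the restricted log-likelihood, and
#'   the spectral cache used by [emmax_scan()].
#' @export
fit_null_mlm <- function(y, K, covariates = NULL) {
  stopifnot(inherits(K, "kinship_matrix"))
  al <- align_response(y, K = K, X = covariates)
  if (length(al$ids) < 3) stop("fewer than 3 individuals shared between response and kinship", call. = FALSE)
  Km <- K$values[al$ids, al$ids]
  ek <- eigen(Km, symmetric = TRUE)
  if (min(ek$values) < -1e-6 * max(abs(ek$values))) {
    stop("kinship matrix is not positive semi-definite", call. = FALSE)
  }
  X <- matrix(1, nrow = length(al$ids), ncol = 1,
              dimnames = list(al$ids, "(Intercept)"))
  cov_names <- character(0)
  if (!is.null(covariates)) {
    Xc <- as.matrix(covariates)
    if (is.null(rownames(Xc))) {
      if (nrow(Xc) != length(al$ids)) stop("covariate rows do not match the response", call. = FALSE)
      rownames(Xc) <- al$ids
    }
    Xc <- Xc[al$ids, , drop = FALSE]
    cov_names <- colnames(Xc) %||% paste0("cov", seq_len(ncol(Xc)))
    X <- cbind(X, Xc)
  }
  fit <- reml_mixed(al$y, X, Km, eig_K = ek)
  rot <- gls_rotate(al$y, X, ek, fit$delta)
  structure(
    list(ids = al$ids, y = al$y, X = X, covariates = cov_names,
         delta = fit$delta, sigma2_g = fit$sigma2_g,
         sigma2_e = fit$sigma2_e, loglik = fit$loglik,
         eig_K = ek, rot = rot, kinship_method = K$method),
    class = "mlm_null"
  )
}

#' @export
print.mlm_null <- function(x, ...) {
  cat(sprintf("<mlm_null> n = %d, covariates: %s\n", length(x$ids),
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "(intercept only)"))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, delta = %.4g, logREML = %.2f\n",
              x$sigma2_g, x$sigma2_e, x$delta, x$loglik))
  invisible(x)
}

# Core per-marker scan on an already whitened system. y_t, X_t are the
# rotated response/design; G_t the rotated marker matrix. Returns beta, se,
# p (F-test with n - q - 1 df by default, or chi-square Wald).
marker_tests <- function(y_t, X_t, G_t, test = c("f", "chisq")) {
  test <- match.arg(test)
  n <- length(y_t)
  qrX <- qr(X_t)
  q <- qrX$rank
  y_r <- qr.resid(qrX, y_t)
  G_r <- qr.resid(qrX, G_t)
  ss_g <- colSums(G_r^2)
  testable <- ss_g > 1e-12 * n
  beta <- se <- p <- rep(NA_real_, ncol(G_t))
  gy <- colSums(G_r * y_r)
  b <- gy[testable] / ss_g[testable]
  rss <- sum(y_r^2) - b^2 * ss_g[testable]
  rss <- pmax(rss, 0)
  df <- n - q - 1
  s2 <- rss / df
  se_b <- sqrt(s2 / ss_g[testable])
  beta[testable] <- b
  se[testable] <- se_b
  stat <- (b / se_b)^2
  p[testable] <- if (test == "f") {
    stats::pf(stat, 1, df, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, 1, lower.tail = FALSE)
  }
  list(beta = beta, se = se, p = pmax(p, 1e-300), testable = testable, df = df)
}

lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1, lower.tail = FALSE)
}

new_gwas_result <- function(results, method, delta = NA_real_,
                            covariates = character(0), n = NA_integer_,
                            test = "f") {
  structure(
    list(results = results, method = method, delta = delta,
         covariates = covariates, n = n, test = test,
         lambda_gc = lambda_gc(results$p_value)),
    class = "gwas_result"
  )
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("<gwas_result> %s scan, %d markers, n = %d\n", x$method,
              nrow(x$results), x$n))
  cat(sprintf("  lambda_GC = %.3f; min p = %.3g\n", x$lambda_gc,
              suppressWarnings(min(x$results$p_value, na.rm = TRUE))))
  invisible(x)
}

#' Tidy / summarize a GWAS result
#'
#' @param x A [emmax_scan()] or [naive_scan()] result.
#' @param ... Unused.
#' @return `tidy()`: the per-marker tibble (`locus_id`, `chrom`, `pos`,
#'   `maf`, `beta`, `se`, `p_value`, `n`). `glance()`: one row of model-level
#'   metadata including the genomic inflation factor `lambda_gc`.
#' @export
tidy.gwas_result <- function(x, ...) x$results

#' @rdname tidy.gwas_result
#' @export
glance.gwas_result <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n, n_markers = nrow(x$results),
                 n_tested = sum(!is.na(x$results$p_value)),
                 delta = x$delta, lambda_gc = x$lambda_gc, test = x$test,
                 covariates = paste(x$covariates, collapse = ","))
}

#' EMMAX single-locus association scan
#'
#' Tests every marker by generalized least squares with the covariance
#' fixed at the null-model REML fit (kinship plus optional PC covariates).
#' Markers with (near-)zero dosage variance after mean imputation are
#' flagged untestable (`NA` p-value). The default significance test is an
#' F-test on `n - q - 1` residual degrees of freedom; a chi-square Wald
#' test is available via `test = "chisq"`.
#'
#' @param null A [fit_null_mlm()] object.
#' @param gt A [genotype_table()] covering the null model's individuals.
#' @param test `"f"` or `"chisq"`.
#' @return A `gwas_result`; see [tidy.gwas_result()].
#' @export
emmax_scan <- function(null, gt, test = c("f", "chisq")) {
  stopifnot(inherits(null, "mlm_null"))
  test <- match.arg(test)
  missing_ids <- setdiff(null$ids, gt$individual_ids)
  if (length(missing_ids)) {
    stop("individuals in the null model are absent from the genotypes: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  sub <- gt[null$ids, ]
  G <- impute_mean(sub)
  G_t <- null$rot$Tm %*% G
  mt <- marker_tests(null$rot$y_t, null$rot$X_t, G_t, test = test)
  maf <- locus_stats(sub)$maf
  res <- tibble::tibble(
    locus_id = sub$loci$locus_id, chrom = sub$loci$chrom, pos = sub$loci$pos,
    maf = maf, beta = mt$beta, se = mt$se, p_value = mt$p,
    n = colSums(!is.na(sub$dosage))
  )
  new_gwas_result(res, "emmax", delta = null$delta,
                  covariates = null$covariates, n = length(null$ids),
                  test = test)
}

#' Naive single-locus regression scan
#'
#' Ordinary least-squares regression of the trait BLUP on each marker (plus
#' optional covariates), with no correction for relatedness or structure.
#' Serves as the comparison scan whose inflation quantifies confounding.
#'
#' @param y Trait BLUPs (as in [fit_null_mlm()]).
#' @param gt A [genotype_table()].
#' @param covariates Optional covariate matrix, rows named by id.
#' @param test `"f"` or `"chisq"`.
#' @return A `gwas_result`.
#' @export
naive_scan <- function(y, gt, covariates = NULL, test = c("f", "chisq")) {
  test <- match.arg(test)
  al <- align_response(y, gt = gt, X = covariates)
  sub <- gt[al$ids, ]
  G <- impute_mean(sub)
  X <- cbind(`(Intercept)` = rep(1, length(al$ids)))
  cov_names <- character(0)
  if (!is.null(covariates)) {
    Xc <- as.matrix(covariates)[al$ids, , drop = FALSE]
    cov_names <- colnames(Xc) %||% paste0("cov", seq_len(ncol(Xc)))
    X <- cbind(X, Xc)
  }
  mt <- marker_tests(al$y, X, G, test = test)
  res <- tibble::tibble(
    locus_id = sub$loci$locus_id, chrom = sub$loci$chrom, pos = sub$loci$pos,
    maf = locus_stats(sub)$maf, beta = mt$beta, se = mt$se, p_value = mt$p,
    n = colSums(!is.na(sub$dosage))
  )
  new_gwas_result(res, "naive", covariates = cov_names,
                  n = length(al$ids), test = test)
}

#' Multiple-testing control
#'
#' @param pvals Vector of p-values in `(0, 1]`.
#' @param method `"bonferroni"` returns the genome-wide per-test threshold
#'   `alpha / m`; `"bh"` returns Benjamini-Hochberg step-up adjusted
#'   p-values (monotone, never below the raw p); `"storey"` additionally
#'   rescales them by an estimate of the true-null fraction `pi0` (fixed
#'   `lambda = 0.5`).
#' @param alpha Significance level used by `"bonferroni"`.
#' @return A scalar threshold (`"bonferroni"`) or a vector of q-values.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "bh", "storey"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (length(pvals) == 0) stop("empty p-value vector", call. = FALSE)
  ok <- !is.na(pvals)
  if (any(pvals[ok] <= 0 | pvals[ok] > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (method == "bonferroni") return(alpha / sum(ok))
  q <- rep(NA_real_, length(pvals))
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(pvals[ok] > 0.5) / 0.5)
    pi0 <- max(pi0, 1 / sum(ok))
    q[ok] <- pmin(1, q[ok] * pi0)
  }
  q
}

# Wald t-tests for each fitted coefficient of the GLS fit of y on X under
# covariance (K + delta I); used to judge cofactors inside MLMM models.
gls_coef_tests <- function(y, X, eig_K, delta) {
  rot <- gls_rotate(y, X, eig_K, delta)
  n <- length(y); p <- ncol(X)
  fit <- stats::lm.fit(rot$X_t, rot$y_t)
  rss <- sum(fit$residuals^2)
  df <- n - p
  XtX_inv <- chol2inv(chol(crossprod(rot$X_t)))
  se <- sqrt(diag(XtX_inv) * rss / df)
  tval <- fit$coefficients / se
  pv <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = fit$coefficients, se = se, p = pv, df = df)
}

#' Multi-locus mixed-model forward-backward selection
#'
#' Starting from the null mixed model, forward steps add the most
#' significant marker as a fixed cofactor and refit the variance components
#' under the extended model; after `max_steps` forward steps (or when no
#' testable marker remains), backward steps remove the least significant
#' cofactor one at a time. Among all models on the path, the selected model
#' is the largest one whose cofactors all pass the Bonferroni threshold
#' `alpha / m` (the "multiple Bonferroni" criterion).
#'
#' @param y Trait BLUPs (as in [fit_null_mlm()]).
#' @param K A `kinship_matrix`.
#' @param gt A [genotype_table()].
#' @param covariates Optional covariate matrix (e.g. the first two PCs),
#'   rows named by id.
#' @param max_steps Maximum number of forward steps.
#' @param alpha Genome-wide significance level for the Bonferroni
#'   criterion.
#' @return An object of class `mlmm_path`: `steps` (tibble of the forward /
#'   backward trajectory), `models` (list of cofactor sets with their
#'   cofactor p-values), `selected` (locus ids of the chosen model) and
#'   `threshold`.
#' @export
mlmm_select <- function(y, K, gt, covariates = NULL, max_steps = 9,
                        alpha = 0.05) {
  if (max_steps < 1) stop("max_steps must be >= 1", call. = FALSE)
  al <- align_response(y, gt = gt, K = K, X = covariates)
  sub <- gt[al$ids, ]
  Km <- K$values[al$ids, al$ids]
  ek <- eigen(Km, symmetric = TRUE)
  G <- impute_mean(sub)
  m <- ncol(G)
  threshold <- alpha / m
  X0 <- cbind(`(Intercept)` = rep(1, length(al$ids)))
  if (!is.null(covariates)) {
    Xc <- as.matrix(covariates)[al$ids, , drop = FALSE]
    X0 <- cbind(X0, Xc)
  }
  q0 <- ncol(X0)

  cof_p <- function(cof) {
    X <- cbind(X0, G[, cof, drop = FALSE])
    fit <- reml_mixed(al$y, X, Km, eig_K = ek)
    ct <- gls_coef_tests(al$y, X, ek, fit$delta)
    stats::setNames(ct$p[-seq_len(q0)], cof)
  }

  steps <- list()
  models <- list(list(cofactors = character(0), p = numeric(0)))
  cof <- character(0)
  for (s in seq_len(max_steps)) {
    X <- cbind(X0, G[, cof, drop = FALSE])
    fit <- reml_mixed(al$y, X, Km, eig_K = ek)
    rot <- gls_rotate(al$y, X, ek, fit$delta)
    cand <- setdiff(colnames(G), cof)
    mt <- marker_tests(rot$y_t, rot$X_t, rot$Tm %*% G[, cand, drop = FALSE])
    if (all(is.na(mt$p))) break
    best <- which.min(mt$p)
    cof <- c(cof, cand[best])
    pv <- cof_p(cof)
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(steps) + 1, action = "forward", locus_id = cand[best],
      p_value = mt$p[best], n_cofactors = length(cof))
    models[[length(models) + 1]] <- list(cofactors = cof, p = pv)
  }
  back <- cof
  while (length(back) > 1) {
    pv <- cof_p(back)
    drop_id <- names(pv)[which.max(pv)]
    back <- setdiff(back, drop_id)
    pvb <- cof_p(back)
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(steps) + 1, action = "backward", locus_id = drop_id,
      p_value = max(pv), n_cofactors = length(back))
    models[[length(models) + 1]] <- list(cofactors = back, p = pvb)
  }
  sizes <- vapply(models, function(mo) length(mo$cofactors), 0L)
  ok <- vapply(models, function(mo) {
    length(mo$p) == 0 || max(mo$p) <= threshold
  }, TRUE)
  selected <- models[[which(sizes == max(sizes[ok]) & ok)[1]]]$cofactors
  structure(
    list(steps = if (length(steps)) dplyr::bind_rows(steps) else
           tibble::tibble(step = integer(), action = character(),
                          locus_id = character(), p_value = double(),
                          n_cofactors = integer()),
         models = models, selected = selected, threshold = threshold,
         n_markers = m, max_steps = max_steps),
    class = "mlmm_path"
  )
}

#' @export
print.mlmm_path <- function(x, ...) {
  cat(sprintf("<mlmm_path> %d markers, threshold %.3g\n", x$n_markers,
              x$threshold))
  cat(sprintf("  path of %d models; selected model has %d cofactor(s)%s\n",
              length(x$models), length(x$selected),
              if (length(x$selected))
                paste0(": ", paste(x$selected, collapse = ", ")) else ""))
  invisible(x)
}
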