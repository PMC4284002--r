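# Data-perturbation power simulation: constant additive effects (-a, 0, a)
# are added to trait BLUPs at a randomly chosen SNV, the perturbed trait is
# rescanned with the mixed model, and empirical power plus the winner's-curse
# inflation of naive PVE estimates are tabulated across a grid of expected
# PVE values.

#' Expected proportion of variance explained by a standardized additive
#' effect
#'
#' For a biallelic SNV in Hardy-Weinberg proportions with allele frequency
#' `p` and an additive effect of `k` phenotypic standard deviations per
#' allele copy, the marker's additive variance is `2 p (1 - p) k^2` (in
#' units of the pre-perturbation trait variance), so the expected PVE after
#' adding the effect is
#' `2 p (1 - p) k^2 / (1 + 2 p (1 - p) k^2)`.
#' The function is strictly increasing in `k` and symmetric in
#' `p <-> 1 - p`.
#'
#' @param p Allele frequency in `(0, 1)`.
#' @param k Standardized additive effect (effect `a` divided by the SD of
#'   the trait BLUPs), `k >= 0`.
#' @return Expected PVE in `[0, 1)`.
#' @export
expected_pve <- function(p, k) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  if (any(k < 0)) stop("k must be non-negative", call. = FALSE)
  v <- 2 * p * (1 - p) * k^2
  v / (1 + v)
}

#' Standardized effect size for a target expected PVE
#'
#' Closed-form inverse of [expected_pve()] in `k`.
#'
#' @param p Allele frequency in `(0, 1)`.
#' @param target_pve Target expected PVE in `[0, 1)`.
#' @return `k >= 0` with `expected_pve(p, k) == target_pve`.
#' @export
solve_k_for_pve <- function(p, target_pve) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  if (any(target_pve < 0 | target_pve >= 1)) {
    stop("target_pve must lie in [0, 1)", call. = FALSE)
  }
  sqrt(target_pve / (1 - target_pve) / (2 * p * (1 - p)))
}

#' Power configuration for the perturbation simulation
#'
#' @param alpha Per-marker significance level (default `1e-5`, the usual
#'   suggestive genome-wide threshold).
#' @param target_pve_grid Expected-PVE grid (default 0.01 to 0.20 by 0.01).
#' @param n_reps Simulation replicates per grid point (1000 in the full
#'   protocol; scale down for quick runs).
#' @param min_maf Minimum MAF of the perturbed SNV (avoids degenerate
#'   monomorphic picks).
#' @param seed Integer seed.
#' @return A list of class `power_config`.
#' @export
power_config <- function(alpha = 1e-5,
                         target_pve_grid = seq(0.01, 0.20, by = 0.01),
                         n_reps = 1000, min_maf = 0.05, seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (any(target_pve_grid < 0 | target_pve_grid >= 1)) {
    stop("target_pve_grid values must be in [0, 1)", call. = FALSE)
  }
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, target_pve_grid = target_pve_grid,
                 n_reps = as.integer(n_reps), min_maf = min_maf,
                 seed = as.integer(seed)),
            class = "power_config")
}

#' Perturbation-based GWAS power and naive-PVE inflation
#'
#' For each expected-PVE grid point and each replicate: a SNV is drawn at
#' random, the standardized effect `k` solving [expected_pve()] for that
#' SNV's allele frequency is converted to a trait-unit effect
#' `a = k * sd(BLUPs)`, constant effects `(-a, 0, a)` are added to the
#' BLUPs of individuals carrying 0, 1 and 2 copies of the alternate allele,
#' the mixed model is refitted (variance components re-optimized on the
#' cached spectral decomposition) and the perturbed SNV is tested exactly as
#' in [emmax_scan()]. Power is the fraction of replicates reaching `alpha`;
#' for those hits the naive PVE is recorded as the `R^2` of the simple
#' linear regression of the perturbed BLUPs on the SNV dosage.
#'
#' @param blups Trait BLUPs (as in [fit_null_mlm()]).
#' @param gt A [genotype_table()].
#' @param K A `kinship_matrix`.
#' @param covariates Optional covariate matrix (PC scores), rows named by
#'   id.
#' @param config A [power_config()].
#' @return An object of class `power_curve`: a tibble with one row per grid
#'   point (`expected_pve`, `n_reps`, `power`, `n_significant`,
#'   `mean_naive_pve`, `inflation`), plus the configuration.
#' @export
perturb_and_scan <- function(blups, gt, K, covariates = NULL,
                             config = power_config()) {
  stopifnot(inherits(config, "power_config"))
  al <- align_response(blups, gt = gt, K = K, X = covariates)
  sub <- gt[al$ids, ]
  Km <- K$values[al$ids, al$ids]
  ek <- eigen(Km, symmetric = TRUE)
  X <- cbind(`(Intercept)` = rep(1, length(al$ids)))
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(covariates)[al$ids, , drop = FALSE])
  }
  proj <- NULL
  sd_blup <- stats::sd(al$y)    # fixed at the unperturbed BLUP scale
  G <- impute_mean(sub)
  maf <- locus_stats(sub)$maf
  eligible <- which(maf >= config$min_maf)
  if (!length(eligible)) stop("no SNV passes the min_maf condition", call. = FALSE)
  p_alt <- allele_freq(sub)

  with_seed(config$seed, {
    rows <- purrr::map_dfr(config$target_pve_grid, function(pve) {
      hits <- logical(config$n_reps)
      naive <- rep(NA_real_, config$n_reps)
      for (r in seq_len(config$n_reps)) {
        j <- sample(eligible, 1)
        p <- p_alt[j]
        k <- solve_k_for_pve(p, pve)
        a <- k * sd_blup
        shift <- a * (sub$dosage[, j] - 1)
        shift[is.na(shift)] <- 0      # missing calls receive no effect
        y_p <- al$y + shift
        fit <- reml_mixed(y_p, X, Km, eig_K = ek, eig_SKS = proj)
        if (is.null(proj)) proj <<- fit$proj
        rot <- gls_rotate(y_p, X, ek, fit$delta)
        mt <- marker_tests(rot$y_t, rot$X_t,
                           rot$Tm %*% G[, j, drop = FALSE])
        pval <- mt$p[1]
        if (!is.na(pval) && pval <= config$alpha) {
          hits[r] <- TRUE
          obs <- !is.na(sub$dosage[, j])
          naive[r] <- stats::cor(y_p[obs], sub$dosage[obs, j])^2
        }
      }
      tibble::tibble(
        expected_pve = pve, n_reps = config$n_reps,
        power = mean(hits), n_significant = sum(hits),
        mean_naive_pve = if (any(hits)) mean(naive[hits]) else NA_real_,
        inflation = if (any(hits) && pve > 0) mean(naive[hits]) / pve
                    else NA_real_
      )
    })
    structure(list(curve = rows, config = config, n = length(al$ids)),
              class = "power_curve")
  })
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("<power_curve> n = %d, alpha = %g, %d reps per point\n",
              x$n, x$config$alpha, x$config$n_reps))
  print(x$curve, n = 5)
  invisible(x)
}

#' @rdname tidy.gwas_result
#' @export
tidy.power_curve <- function(x, ...) x$curve
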