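# Trait BLUPs, variance components and broad-sense heritability from
# replicated field-trial observations, plus phenotypic and genetic
# correlations between traits.

#' Estimate trait BLUPs and broad-sense heritability
#'
#' Fits `value = mean + block (fixed) + genotype (random) + error` by REML
#' (1-D profile likelihood over the variance ratio on the spectral scale)
#' and returns best linear unbiased predictors of the genotype effects,
#' the variance components, and clone-mean broad-sense heritability
#' `H2 = sigma2_G / (sigma2_G + sigma2_E / n_reps)` with `n_reps` the
#' harmonic-mean replicate count per genotype.
#'
#' @param observations A data frame with columns `genotype_id`, `block`,
#'   `value` (one row per plot). A `trait` column, if present, must contain
#'   a single trait (use [dplyr::filter()] or split beforehand).
#' @param trait Optional trait name recorded in the result.
#' @return An object of class `trait_blups`; see [tidy.trait_blups()] and
#'   [glance.trait_blups()].
#' @export
estimate_blups <- function(observations, trait = NULL) {
  obs <- tibble::as_tibble(observations)
  stopifnot(all(c("genotype_id", "block", "value") %in% names(obs)))
  if ("trait" %in% names(obs)) {
    tr <- unique(obs$trait)
    if (length(tr) > 1) stop("observations contain more than one trait", call. = FALSE)
    trait <- trait %||% tr
  }
  obs <- obs[!is.na(obs$value), ]
  geno <- factor(obs$genotype_id)
  block <- factor(obs$block)
  if (nlevels(geno) < 2) stop("need at least 2 genotypes", call. = FALSE)
  reps <- table(geno)
  if (nlevels(block) < 2 && max(reps) < 2) {
    stop("variance components are inestimable: a single block with one ",
         "replicate per genotype provides no within-genotype information",
         call. = FALSE)
  }
  y <- obs$value
  X <- stats::model.matrix(~block)
  Z <- stats::model.matrix(~ 0 + geno)
  K <- tcrossprod(Z)

  fit <- reml_mixed(y, X, K)
  eig_K <- eigen(K, symmetric = TRUE)
  rot <- gls_rotate(y, X, eig_K, fit$delta)
  resid <- y - drop(X %*% rot$beta)
  # u_hat = Z' (ZZ' + delta I)^{-1} (y - X beta)
  Vinv_r <- eig_K$vectors %*% (crossprod(eig_K$vectors, resid) /
                                 (pmax(eig_K$values, 0) + fit$delta))
  u <- drop(crossprod(Z, Vinv_r))
  names(u) <- levels(geno)

  n_reps <- 1 / mean(1 / as.numeric(reps))   # harmonic mean
  h2 <- fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e / n_reps)
  structure(
    list(trait = trait %||% "trait",
         blups = tibble::tibble(genotype_id = levels(geno), blup = unname(u)),
         sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
         h2 = h2, n_reps = n_reps,
         block_effects = rot$beta, loglik = fit$loglik,
         n_genotypes = nlevels(geno), n_obs = length(y)),
    class = "trait_blups"
  )
}

#' @export
print.trait_blups <- function(x, ...) {
  cat(sprintf("<trait_blups> %s: %d genotypes, %d observations\n",
              x$trait, x$n_genotypes, x$n_obs))
  cat(sprintf("  sigma2_G = %.4g, sigma2_E = %.4g, H2 = %.3f (n_reps = %.2f)\n",
              x$sigma2_g, x$sigma2_e, x$h2, x$n_reps))
  invisible(x)
}

#' Tidy a `trait_blups` object
#'
#' @param x A [estimate_blups()] result.
#' @param ... Unused.
#' @return `tidy()`: tibble of per-genotype BLUPs. `glance()`: one-row
#'   tibble of variance components and heritability.
#' @export
tidy.trait_blups <- function(x, ...) x$blups

#' @rdname tidy.trait_blups
#' @export
glance.trait_blups <- function(x, ...) {
  tibble::tibble(trait = x$trait, sigma2_g = x$sigma2_g,
                 sigma2_e = x$sigma2_e, h2 = x$h2, n_reps = x$n_reps,
                 n_genotypes = x$n_genotypes, n_obs = x$n_obs,
                 loglik = x$loglik)
}

blup_vector <- function(blups) {
  if (inherits(blups, "trait_blups")) {
    stats::setNames(blups$blups$blup, blups$blups$genotype_id)
  } else if (is.data.frame(blups)) {
    stats::setNames(blups$blup, blups$genotype_id)
  } else if (is.numeric(blups) && !is.null(names(blups))) {
    blups
  } else {
    stop("expected a trait_blups object, a (genotype_id, blup) data frame, ",
         "or a named numeric vector", call. = FALSE)
  }
}

#' Phenotypic correlation between two traits
#'
#' Pearson correlation of per-genotype BLUPs over shared genotypes.
#'
#' @param blups_x,blups_y [estimate_blups()] results (or `(genotype_id,
#'   blup)` data frames / named vectors).
#' @return Pearson `r` (`NA` if either trait has zero variance over the
#'   shared genotypes).
#' @export
phenotypic_correlation <- function(blups_x, blups_y) {
  x <- blup_vector(blups_x); y <- blup_vector(blups_y)
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3) stop("fewer than 3 shared genotypes", call. = FALSE)
  x <- x[shared]; y <- y[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Genetic correlation from heritabilities
#'
#' For traits measured in different trials, the genetic correlation is
#' approximated from the phenotypic correlation of their BLUPs and the two
#' broad-sense heritabilities: `r_G = r_p / sqrt(h2_x * h2_y)`. Values
#' outside `[-1, 1]` are clipped and flagged via the `"clipped"` attribute.
#'
#' @param r_p Phenotypic (BLUP) correlation.
#' @param h2_x,h2_y Broad-sense heritabilities in `(0, 1]`.
#' @return `r_G`, clipped into `[-1, 1]`.
#' @export
genetic_correlation_h2 <- function(r_p, h2_x, h2_y) {
  if (h2_x <= 0 || h2_y <= 0) stop("heritabilities must be positive", call. = FALSE)
  r <- r_p / sqrt(h2_x * h2_y)
  clipped <- abs(r) > 1
  r <- max(-1, min(1, r))
  attr(r, "clipped") <- clipped
  r
}

#' Genetic correlation from genetic covariance
#'
#' For two traits measured on the same genotypes in the same block design,
#' estimates the genetic covariance by method of moments: block effects are
#' removed per trait, and the covariance of genotype means is corrected by
#' the within-genotype residual cross-covariance divided by the
#' harmonic-mean replicate count. `r_G = cov_G / sqrt(sigma2_Gx *
#' sigma2_Gy)`.
#'
#' @param observations_x,observations_y Data frames with `genotype_id`,
#'   `block`, `value` covering the same genotypes and blocks.
#' @return `r_G` (clipped into `[-1, 1]`, flagged via `"clipped"`), or `NA`
#'   with a `"reason"` attribute when either genetic variance estimate is
#'   non-positive.
#' @export
genetic_correlation_cov <- function(observations_x, observations_y) {
  prep <- function(obs) {
    obs <- tibble::as_tibble(obs)[, c("genotype_id", "block", "value")]
    obs <- obs[!is.na(obs$value), ]
    fit <- stats::lm(value ~ factor(block), data = obs)
    obs$adj <- mean(obs$value) + stats::resid(fit)
    obs
  }
  ox <- prep(observations_x); oy <- prep(observations_y)
  key <- function(o) paste(o$genotype_id, o$block)
  shared <- intersect(key(ox), key(oy))
  ox <- ox[match(shared, key(ox)), ]; oy <- oy[match(shared, key(oy)), ]
  g <- ox$genotype_id
  mx <- tapply(ox$adj, g, mean); my <- tapply(oy$adj, g, mean)
  ni <- tapply(ox$adj, g, length)
  dx <- ox$adj - mx[g]; dy <- oy$adj - my[g]
  df_within <- sum(ni - 1)
  if (df_within < 1) {
    out <- NA_real_
    attr(out, "reason") <- "no within-genotype replication"
    return(out)
  }
  cov_e <- sum(dx * dy) / df_within
  var_ex <- sum(dx^2) / df_within
  var_ey <- sum(dy^2) / df_within
  nh <- 1 / mean(1 / ni)
  cov_g <- stats::cov(mx, my) - cov_e / nh
  var_gx <- stats::var(mx) - var_ex / nh
  var_gy <- stats::var(my) - var_ey / nh
  if (var_gx <= 0 || var_gy <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "non-positive genetic variance estimate"
    return(out)
  }
  r <- cov_g / sqrt(var_gx * var_gy)
  clipped <- abs(r) > 1
  r <- max(-1, min(1, r))
  attr(r, "clipped") <- clipped
  r
}
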