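structured_trait <- function(gt, h2 = 0.6, shift = 0, seed = 1) {
  sim <- simulate_trait(gt, trait_model(h2 = h2, n_qtl = 60,
                                        subpop_shift = shift, seed = seed))
  estimate_blups(sim$observations)
}

test_that("null-model REML matches a fine grid search over log delta", {
  pm <- population_model(n_individuals = 50, n_loci = 800, fst = 0.05,
                         missing_rate = 0, seed = 71)
  gt <- simulate_structured_genotypes(pm)
  K <- ibs_kinship(gt)
  b <- structured_trait(gt, seed = 72)
  null <- fit_null_mlm(b, K)
  # independent oracle: dense evaluation of the restricted likelihood on a
  # 1e-3 grid in log delta
  y <- stats::setNames(b$blups$blup, b$blups$genotype_id)[null$ids]
  Km <- K$values[null$ids, null$ids]
  n <- length(y)
  X <- matrix(1, n, 1)
  qrX <- qr(X)
  Q1 <- qr.Q(qrX)
  K1 <- Km + diag(n)
  KQ <- K1 %*% Q1
  SKS <- K1 - Q1 %*% t(KQ) - KQ %*% t(Q1) +
    Q1 %*% (crossprod(Q1, KQ) %*% t(Q1))
  e <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
  xi <- pmax(e$values[seq_len(n - 1)] - 1, 0)
  eta <- drop(crossprod(e$vectors[, seq_len(n - 1)], y))
  grid <- seq(-10, 10, by = 1e-3)
  nll <- vapply(grid, function(ld) {
    w <- xi + exp(ld)
    0.5 * ((n - 1) * log(sum(eta^2 / w)) + sum(log(w)))
  }, 0)
  expect_lt(abs(log(null$delta) - grid[which.min(nll)]), 1e-3 + 1e-9)
})

test_that("marker-heritability recovery and the pure-noise null behave", {
  pm <- population_model(n_individuals = 300, n_loci = 2000, fst = 0.05,
                         missing_rate = 0, seed = 73)
  gt <- simulate_structured_genotypes(pm)
  K <- grm_vanraden(gt)
  X <- impute_mean(gt)
  frac <- vapply(1:10, function(s) {
    set.seed(400 + s)
    qtl <- sample(2000, 200)
    g <- drop(scale(X[, qtl] %*% stats::rnorm(200)))
    y <- stats::setNames(sqrt(0.5) * g + stats::rnorm(300, 0, sqrt(0.5)),
                         gt$individual_ids)
    f <- fit_null_mlm(y, K)
    f$sigma2_g / (f$sigma2_g + f$sigma2_e)
  }, 0)
  expect_lt(abs(mean(frac) - 0.5), 0.15)

  noise_frac <- vapply(1:10, function(s) {
    y <- stats::setNames(with_seed_rnorm(500 + s, 300), gt$individual_ids)
    f <- fit_null_mlm(y, K)
    f$sigma2_g / (f$sigma2_g + f$sigma2_e)
  }, 0)
  expect_gte(mean(noise_frac < 0.15), 0.9)
})

test_that("emmax_scan equals a dense per-marker GLS oracle", {
  pm <- population_model(n_individuals = 50, n_loci = 200, fst = 0.05,
                         missing_rate = 0.02, seed = 74)
  gt <- simulate_structured_genotypes(pm)
  K <- ibs_kinship(gt)
  b <- structured_trait(gt, seed = 75)
  null <- fit_null_mlm(b, K)
  scan <- tidy(emmax_scan(null, gt))
  y <- stats::setNames(b$blups$blup, b$blups$genotype_id)[null$ids]
  V <- null$sigma2_g * K$values[null$ids, null$ids] +
    null$sigma2_e * diag(length(y))
  ok <- which(!is.na(scan$p_value))
  p_oracle <- dense_gls_pvalues(y, impute_mean(gt[null$ids, ])[, ok], V)
  expect_lt(max(abs(log10(scan$p_value[ok]) - log10(p_oracle))), 1e-6)
})

test_that("forcing an identity kinship reduces the mixed model to OLS", {
  pm <- population_model(n_individuals = 50, n_loci = 500, fst = 0.03,
                         missing_rate = 0, seed = 76)
  gt <- simulate_structured_genotypes(pm)
  y <- stats::setNames(with_seed_rnorm(77, 50), gt$individual_ids)
  Kid <- structure(list(ids = gt$individual_ids,
                        values = matrix(diag(50), 50, 50,
                                        dimnames = list(gt$individual_ids,
                                                        gt$individual_ids)),
                        method = "IBS"),
                   class = "kinship_matrix")
  expect_warning(null <- fit_null_mlm(y, Kid), "identifiable")
  p_mlm <- tidy(emmax_scan(null, gt))$p_value
  p_ols <- tidy(naive_scan(y, gt))$p_value
  ok <- !is.na(p_mlm)
  expect_lt(max(abs(log10(p_mlm[ok]) - log10(p_ols[ok]))), 0.05)
})

test_that("a planted additive marker is detected with high power", {
  pm <- population_model(n_individuals = 300, n_loci = 500, fst = 0.02,
                         missing_rate = 0, seed = 78)
  gt <- simulate_structured_genotypes(pm)
  hits <- vapply(1:10, function(s) {
    set.seed(600 + s)
    j <- sample(which(locus_stats(gt)$maf > 0.2), 1)
    g <- drop(scale(impute_mean(gt)[, j]))
    y <- stats::setNames(sqrt(0.2) * g + stats::rnorm(300, 0, sqrt(0.8)),
                         gt$individual_ids)
    tidy(naive_scan(y, gt))$p_value[j] < 1e-5
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("monomorphic markers are flagged, not tested", {
  dos <- cbind(m1 = c(0, 1, 2, 1, 0, 1, 2, 0, 1, 1),
               m2 = rep(0, 10))
  gt <- toy_gt(dos)
  y <- stats::setNames(with_seed_rnorm(79, 10), gt$individual_ids)
  res <- tidy(naive_scan(y, gt))
  expect_false(is.na(res$p_value[1]))
  expect_true(is.na(res$p_value[2]))
})

test_that("permuted phenotypes give calibrated p-values and lambda_GC", {
  gt <- shared_panel()
  K <- ibs_kinship(gt)
  b <- structured_trait(gt, shift = 1.5, seed = 80)
  y <- stats::setNames(b$blups$blup, b$blups$genotype_id)
  set.seed(81)
  yp <- stats::setNames(sample(unname(y)), names(y))
  null <- fit_null_mlm(yp, K)
  scan <- emmax_scan(null, gt)
  p <- tidy(scan)$p_value
  expect_gt(mean(p < 0.05, na.rm = TRUE), 0.03)
  expect_lt(mean(p < 0.05, na.rm = TRUE), 0.07)
  expect_gt(scan$lambda_gc, 0.85)
  expect_lt(scan$lambda_gc, 1.15)
})

test_that("multiple-testing control follows the printed thresholds and BH", {
  expect_equal(signif(adjust_pvalues(rep(0.5, 53174), "bonferroni"), 2),
               9.4e-7)
  expect_equal(signif(adjust_pvalues(rep(0.5, 121771), "bonferroni"), 2),
               4.1e-7)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  set.seed(82)
  p <- stats::runif(500)
  q <- adjust_pvalues(p, "bh")
  expect_true(all(q >= p))
  expect_true(all(adjust_pvalues(p, "storey") <= q + 1e-12))
  expect_error(adjust_pvalues(numeric(0)), "empty")
  expect_error(adjust_pvalues(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("MLMM selects planted cofactors under the Bonferroni criterion", {
  pm <- population_model(n_individuals = 300, n_loci = 2000, fst = 0.02,
                         ld_block_size = 5, missing_rate = 0, seed = 21)
  gt <- simulate_structured_genotypes(pm)
  K <- ibs_kinship(gt)
  X <- impute_mean(gt)
  recovered <- vapply(1:5, function(s) {
    set.seed(700 + s)
    qtl <- sample(seq(3, 1998, by = 5), 2)  # distinct LD blocks
    g <- scale(X[, qtl])
    y <- stats::setNames(
      drop(g %*% rep(sqrt(0.15), 2)) + stats::rnorm(300, 0, sqrt(0.7)),
      gt$individual_ids)
    ml <- mlmm_select(y, K, gt, max_steps = 4)
    truth <- gt$loci$locus_id[qtl]
    blocks_hit <- vapply(truth, function(t) {
      any(vapply(ml$selected, function(sel)
        sel == t || ld_r2(gt, sel, t) > 0.8, TRUE))
    }, TRUE)
    sum(blocks_hit)
  }, 0)
  expect_gte(mean(recovered >= 2), 0.7)

  # pure noise: nothing passes the threshold at step one
  y0 <- stats::setNames(with_seed_rnorm(83, 300), gt$individual_ids)
  ml0 <- mlmm_select(y0, K, gt, max_steps = 2)
  expect_length(ml0$selected, 0)
})

test_that("a QTL pair in complete LD yields exactly one selected cofactor", {
  pm <- population_model(n_individuals = 200, n_loci = 300, ld_strength = 0,
                         fst = 0.02, missing_rate = 0, seed = 84)
  gt <- simulate_structured_genotypes(pm)
  gt$dosage[, 101] <- gt$dosage[, 100]   # perfect proxy
  set.seed(85)
  g <- drop(scale(gt$dosage[, 100]))
  y <- stats::setNames(sqrt(0.4) * g + stats::rnorm(200, 0, sqrt(0.6)),
                       gt$individual_ids)
  ml <- mlmm_select(y, ibs_kinship(gt), gt, max_steps = 3)
  pair <- gt$loci$locus_id[c(100, 101)]
  expect_equal(sum(ml$selected %in% pair), 1)
})
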