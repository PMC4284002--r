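test_that("IBS kinship matches hand computations", {
  g <- toy_gt(rbind(i1 = c(0, 1, 2), i2 = c(2, 1, 0), i3 = c(0, 1, 2),
                    i4 = c(0, 0, 0), i5 = c(2, 2, 2)))
  K <- ibs_kinship(g)
  expect_equal(unname(K$values["i1", "i3"]), 1)        # duplicates
  expect_equal(unname(K$values["i4", "i5"]), 0)        # opposite homozygotes
  expect_equal(unname(K$values["i1", "i2"]), 1 / 3)
  expect_true(all(diag(K$values) == 1))
  expect_lt(max(abs(K$values - t(K$values))), 1e-10)
  expect_true(all(K$values >= 0 & K$values <= 1))

  # a pair with no jointly observed loci is an error naming the pair
  g2 <- toy_gt(rbind(a = c(0, NA), b = c(NA, 1), c = c(1, 1)))
  expect_error(ibs_kinship(g2), "a.*b|b.*a")
})

test_that("VanRaden GRM has the expected scaling", {
  # single locus, p = 0.5, dosages (0, 2): K_12 = (-1)(+1)/(2 * 0.25) = -2
  g <- toy_gt(cbind(a = c(0, 2)))
  K <- grm_vanraden(g)
  expect_equal(unname(K$values[1, 2]), -2)

  pm <- population_model(n_individuals = 200, n_loci = 5000, fst = 0,
                         n_subpops = 1, missing_rate = 0, seed = 61)
  gt <- simulate_structured_genotypes(pm)
  G <- grm_vanraden(gt)
  expect_lt(abs(mean(diag(G$values)) - 1), 0.05)

  expect_error(grm_vanraden(toy_gt(cbind(a = c(0, 0), b = c(2, 2)))),
               "polymorphic")
})

test_that("subpopulation mates are more related than across-subpop pairs", {
  gt <- shared_panel()
  G <- grm_vanraden(gt)
  same <- outer(gt$subpop, gt$subpop, "==")
  off <- upper.tri(G$values)
  expect_gt(mean(G$values[off & same]), mean(G$values[off & !same]))
})

test_that("IBS and GRM orderings agree on HWE data", {
  pm <- population_model(n_individuals = 80, n_loci = 3000, fst = 0.05,
                         missing_rate = 0, seed = 62)
  gt <- simulate_structured_genotypes(pm)
  ki <- ibs_kinship(gt)$values
  kg <- grm_vanraden(gt)$values
  off <- upper.tri(ki)
  expect_gt(stats::cor(ki[off], kg[off], method = "spearman"), 0.9)
})

test_that("Tracy-Widom tail probabilities match published quantiles", {
  expect_equal(tw1_pvalue(0.9793), 0.05, tolerance = 1e-3)
  expect_equal(tw1_pvalue(2.0234), 0.01, tolerance = 1e-3)
  expect_equal(tw1_pvalue(3.2724), 0.001, tolerance = 1e-2)
  expect_equal(tw1_pvalue(-10), 1)
  expect_true(all(diff(tw1_pvalue(seq(-5, 5, by = 0.5))) < 0))
})

test_that("PCA separates subpopulations and satisfies spectral identities", {
  pm <- population_model(n_individuals = 200, n_loci = 10000, fst = 0.10,
                         missing_rate = 0, seed = 63)
  gt <- simulate_structured_genotypes(pm)
  pca <- pca_genotypes(gt, max_axes = 5)
  expect_lt(pca$tw_pvalues[1], 1e-4)
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  expect_true(all(pca$eigenvalues >= 0))
  expect_lte(sum(pca$pct_variance), 100)
  expect_lt(abs(sum(pca$eigenvalues) - pca$trace) / pca$trace, 1e-8)
  # PC1 classifies subpopulation membership
  side <- pca$scores[, 1] > stats::median(pca$scores[, 1])
  agree <- mean(side == (gt$subpop == "pop1"))
  expect_gte(max(agree, 1 - agree), 0.95)
})

test_that("duplicating every individual preserves top-axis ordering", {
  pm <- population_model(n_individuals = 40, n_loci = 800, fst = 0.08,
                         missing_rate = 0, seed = 64)
  gt <- simulate_structured_genotypes(pm)
  dbl <- genotype_table(rbind(gt$dosage, gt$dosage),
                        individual_ids = c(gt$individual_ids,
                                           paste0(gt$individual_ids, "_b")),
                        loci = gt$loci)
  p1 <- pca_genotypes(gt, max_axes = 2)
  p2 <- pca_genotypes(dbl, max_axes = 2)
  o1 <- order(p1$scores[, 1])
  o2 <- order(p2$scores[seq_len(40), 1])
  if (stats::cor(p1$scores[, 1], p2$scores[seq_len(40), 1]) < 0) o2 <- rev(o2)
  expect_identical(o1, o2)
})

test_that("outlier detection flags planted aberrant individuals only", {
  pm <- population_model(n_individuals = 80, n_loci = 1500, fst = 0.03,
                         missing_rate = 0, seed = 65)
  gt <- simulate_structured_genotypes(pm)
  expect_length(detect_outliers(gt), 0)

  # plant one individual carrying the rare homozygote at 30% of loci
  planted <- gt
  rare <- ifelse(allele_freq(gt) > 0.5, 0, 2)
  idx <- seq(1, 1500, by = 3)
  planted$dosage[7, idx] <- rare[idx]
  expect_true("ind007" %in% detect_outliers(planted))

  # a duplicated individual is ordinary, not an outlier
  dup <- gt
  dup$dosage[3, ] <- dup$dosage[4, ]
  expect_false("ind003" %in% detect_outliers(dup))
  expect_error(detect_outliers(gt, n_axes = 0), "n_axes")
})

test_that("subpopulation assignment recovers the generating labels", {
  pm <- population_model(n_individuals = 120, n_loci = 4000, fst = 0.10,
                         missing_rate = 0, seed = 66)
  gt <- simulate_structured_genotypes(pm)
  pca <- pca_genotypes(gt, max_axes = 5)
  lab <- assign_subpops(pca, 2)
  agree <- max(mean(lab == gt$subpop), mean(lab != gt$subpop))
  expect_gte(agree, 0.95)

  expect_equal(unique(unname(assign_subpops(pca, 1))), "pop1")
  expect_error(assign_subpops(pca, 500), "exceeds")

  # permutation equivariance
  perm <- sample(120)
  gtp <- gt[perm, ]
  labp <- assign_subpops(pca_genotypes(gtp, max_axes = 5), 2)
  expect_identical(unname(labp[gt$individual_ids]),
                   unname(lab[gt$individual_ids]))
})

test_that("trait-axis correlations behave at both extremes", {
  gt <- shared_panel()
  pca <- pca_genotypes(gt, max_axes = 3)
  fake <- stats::setNames(pca$scores[, 1], pca$ids)
  out <- correlate_trait_with_axes(fake, pca, axes = 1:2)
  expect_equal(out$r[1], 1)
  expect_lt(out$p_value[1], 1e-10)

  # structure-independent traits rarely exceed the null band |r| > 0.17
  hits <- vapply(1:30, function(s) {
    y <- stats::setNames(with_seed_rnorm(s, length(pca$ids)), pca$ids)
    abs(correlate_trait_with_axes(y, pca, axes = 1)$r) < 0.17
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
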