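test_that("ridge BLUP matches OLS in the no-shrinkage single-marker limit", {
  pm <- population_model(n_individuals = 40, n_loci = 1, fst = 0,
                         n_subpops = 1, missing_rate = 0, seed = 91)
  gt <- simulate_structured_genotypes(pm)
  g <- impute_mean(gt)[, 1]
  y <- stats::setNames(0.8 * g + with_seed_rnorm(92, 40, sd = 0.3),
                       gt$individual_ids)
  fit <- fit_ridge_blup(y, gt, lambda = 1e-8)
  ols <- unname(stats::coef(stats::lm(y ~ g))[2])
  expect_equal(unname(fit$effects[1]), ols, tolerance = 1e-6)
})

test_that("marker-effect predictions equal the GBLUP formulation", {
  pm <- population_model(n_individuals = 100, n_loci = 1000, fst = 0.03,
                         missing_rate = 0.02, seed = 93)
  gt <- simulate_structured_genotypes(pm)
  sim <- simulate_trait(gt, trait_model(h2 = 0.7, n_qtl = 30, seed = 94))
  y <- stats::setNames(sim$genotypic_values$value +
                         with_seed_rnorm(95, 100, sd = 0.3),
                       gt$individual_ids)
  fit <- fit_ridge_blup(y, gt)
  pred_marker <- predict(fit, gt)
  X <- impute_mean(gt)
  Z <- sweep(X, 2, colMeans(X))
  K <- tcrossprod(Z)
  mu <- fit$intercept
  pred_gblup <- mu + drop(K %*% solve(K + fit$lambda * diag(100), y - mu))
  expect_lt(max(abs(pred_marker - pred_gblup)), 1e-8)
})

test_that("input validation catches degenerate prediction problems", {
  pm <- population_model(n_individuals = 30, n_loci = 50, seed = 96)
  gt <- simulate_structured_genotypes(pm)
  y <- stats::setNames(rep(1, 30), gt$individual_ids)
  expect_error(fit_ridge_blup(y, gt), "zero variance")
  y2 <- stats::setNames(with_seed_rnorm(97, 5), gt$individual_ids[1:5])
  expect_error(fit_ridge_blup(y2, gt), "at least 10")
  y3 <- stats::setNames(with_seed_rnorm(98, 30), gt$individual_ids)
  expect_error(cross_validate(y3, gt, folds = 1), "fold count")
  expect_error(cross_validate(y3, gt, folds = 31), "fold count")
  expect_error(accuracy(0.5, 0), "h2")
})

test_that("accuracy identity reproduces the published example cells", {
  expect_equal(round(accuracy(0.76, 0.89), 2), 0.81)
  expect_equal(round(accuracy(0.67, 0.65), 2), 0.83)
  expect_equal(accuracy(0.42, 1), 0.42)
})

test_that("a marker-determined trait is recovered almost perfectly", {
  pm <- population_model(n_individuals = 300, n_loci = 100, fst = 0.02,
                         missing_rate = 0, seed = 41)
  gt <- simulate_structured_genotypes(pm)
  X <- impute_mean(gt)
  set.seed(42)
  qtl <- sample(100, 5)
  y <- stats::setNames(drop(scale(X[, qtl] %*% stats::rnorm(5))),
                       gt$individual_ids)
  cv <- cross_validate(y, gt, folds = 10, repeats = 3, h2 = 1, seed = 43)
  expect_gt(glance(cv)$mean_r, 0.9)
})

test_that("permuted responses have no predictive ability", {
  pm <- population_model(n_individuals = 120, n_loci = 800, fst = 0.03,
                         missing_rate = 0, seed = 44)
  gt <- simulate_structured_genotypes(pm)
  sim <- simulate_trait(gt, trait_model(h2 = 0.6, n_qtl = 40, seed = 45))
  set.seed(46)
  y <- stats::setNames(sample(sim$genotypic_values$value),
                       gt$individual_ids)
  cv <- cross_validate(y, gt, folds = 5, repeats = 6, h2 = 0.6, seed = 47)
  expect_lt(abs(glance(cv)$mean_r), 2 / sqrt(120 / 5) / sqrt(6) * 3 + 0.1)
})

test_that("predictive ability is invariant to affine trait rescaling", {
  pm <- population_model(n_individuals = 100, n_loci = 500, fst = 0.03,
                         missing_rate = 0, seed = 48)
  gt <- simulate_structured_genotypes(pm)
  sim <- simulate_trait(gt, trait_model(h2 = 0.7, n_qtl = 40, seed = 49))
  y <- stats::setNames(sim$genotypic_values$value, gt$individual_ids)
  cv1 <- cross_validate(y, gt, folds = 5, repeats = 3, h2 = 0.7, seed = 50)
  cv2 <- cross_validate(3 * y + 7, gt, folds = 5, repeats = 3, h2 = 0.7,
                        seed = 50)
  expect_equal(tidy(cv1)$r, tidy(cv2)$r, tolerance = 1e-6)
  # model and response rescale together, so the calibration slope of
  # observed on predicted is unchanged; the raw regression of the rescaled
  # observations on the *original* predictions would scale by 3
  expect_equal(tidy(cv2)$b1, tidy(cv1)$b1, tolerance = 1e-6)
  expect_equal(tidy(cv2)$b0, 3 * tidy(cv1)$b0 + 7 * (1 - tidy(cv1)$b1),
               tolerance = 1e-5)
})

test_that("calibration slopes approach (0, 1) at larger sample sizes", {
  pm <- population_model(n_individuals = 500, n_loci = 1000, fst = 0.03,
                         missing_rate = 0, seed = 51)
  gt <- simulate_structured_genotypes(pm)
  sim <- simulate_trait(gt, trait_model(h2 = 0.6, n_qtl = 100, seed = 52))
  b <- estimate_blups(sim$observations)
  cv <- cross_validate(b, gt, folds = 5, repeats = 3, seed = 53)
  s <- glance(cv)
  expect_lt(abs(s$mean_b0), 0.1 * stats::sd(b$blups$blup))
  expect_lt(abs(s$mean_b1 - 1), 0.15)
})

test_that("marker selection uses training information correctly", {
  pm <- population_model(n_individuals = 150, n_loci = 500, fst = 0.03,
                         missing_rate = 0, seed = 54)
  gt <- simulate_structured_genotypes(pm)
  y <- stats::setNames(with_seed_rnorm(55, 150), gt$individual_ids)
  expect_setequal(select_markers(gt, y, "random", 500), gt$loci$locus_id)
  expect_warning(sel <- select_markers(gt, y, "random", 600), "exceeds")
  expect_length(select_markers(gt, y, "random", 50, seed = 1), 50)
  expect_identical(select_markers(gt, y, "random", 50, seed = 1),
                   select_markers(gt, y, "random", 50, seed = 1))

  # a 10-QTL trait: informed selection recovers true loci or tight proxies
  X <- impute_mean(gt)
  hits <- vapply(1:5, function(s) {
    set.seed(800 + s)
    qtl <- sample(500, 10)
    yq <- stats::setNames(
      drop(scale(X[, qtl] %*% stats::rnorm(10))) * sqrt(0.7) +
        stats::rnorm(150, 0, sqrt(0.3)),
      gt$individual_ids)
    sel <- select_markers(gt, yq, "gwas_p", 100)
    truth <- gt$loci$locus_id[qtl]
    sum(vapply(truth, function(t) {
      any(vapply(sel, function(m) m == t || ld_r2(gt, m, t) > 0.8, TRUE))
    }, TRUE))
  }, 0)
  expect_gte(mean(hits >= 5), 0.8)
})

test_that("across-subpopulation validation is bracketed by its baseline", {
  gt <- shared_panel()
  sim <- simulate_trait(gt, trait_model(h2 = 0.6, n_qtl = 80,
                                        subpop_shift = 1, seed = 56))
  b <- estimate_blups(sim$observations)
  res <- cross_validate_subpops(b, gt, train_label = "pop1",
                                test_label = "pop2", n_baseline = 15,
                                seed = 57)
  expect_equal(nrow(res$baseline), 15)
  expect_true(is.finite(res$across$r))
  expect_error(cross_validate_subpops(b, gt, train_label = "nope",
                                      test_label = "pop2"), "unknown label")

  # a training set of one individual is rejected
  labs <- stats::setNames(c("solo", rep("rest", 139)), gt$individual_ids)
  expect_error(cross_validate_subpops(b, gt, labels = labs,
                                      train_label = "solo",
                                      test_label = "rest"),
               "too small")
})
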