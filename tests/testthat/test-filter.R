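# The five-locus toy table used for profile evaluation: L1 clean biallelic
# near-HWE; L2 only two minor-allele copies (single rare homozygote, so
# Fis = 1); L3 30% missing; L4 triallelic; L5 Fis = 1 with six minor copies.
toy_filter_table <- function() {
  dosage <- cbind(
    L1 = c(0, 1, 1, 0, 1, 2, 1, 0, 1, 2),
    L2 = c(2, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    L3 = c(0, 1, NA, NA, NA, 1, 0, 1, 0, 2),
    L4 = c(0, 1, 1, 0, 0, 1, 0, 0, 1, 0),
    L5 = c(2, 2, 2, 0, 0, 0, 0, 0, 0, 0)
  )
  loci <- tibble::tibble(locus_id = colnames(dosage), chrom = "1",
                         pos = 1:5 * 100L, ref = "A", alt = "T",
                         n_alleles = c(2L, 2L, 2L, 3L, 2L))
  genotype_table(dosage, loci = loci)
}

test_that("locus_stats reproduces hand-computed MAF, Ho, He and Fis", {
  s <- locus_stats(toy_gt(cbind(a = c(0, 1, 1, 2))))
  expect_equal(s$p, 0.5)
  expect_equal(s$ho, 0.5)
  expect_equal(s$he, 0.5)
  expect_equal(s$fis, 0)

  s2 <- locus_stats(toy_gt(cbind(a = c(0, 2, 0, 2))))
  expect_equal(s2$ho, 0)
  expect_equal(s2$he, 0.5)
  expect_equal(s2$fis, 1)

  s3 <- locus_stats(toy_gt(cbind(a = c(1, 1, 1, 1))))
  expect_equal(s3$ho, 1)
  expect_equal(s3$fis, -1)

  # monomorphic: He = 0 -> Fis undefined
  s4 <- locus_stats(toy_gt(cbind(a = c(0, 0, 0))))
  expect_true(is.na(s4$fis))
  expect_equal(s4$maf, 0)
})

test_that("filter profiles reproduce the hand-evaluated survivor sets", {
  gt <- toy_filter_table()
  liberal <- filter_profile("custom", min_minor_allele_copies = 3,
                            max_missing_pct = 20, required_n_alleles = 2)
  res <- apply_filter_profile(gt, liberal)
  expect_setequal(res$genotypes$loci$locus_id, c("L1", "L5"))
  expect_equal(sum(!res$report$pass), 3)
  expect_equal(res$report$fail_criterion[res$report$locus_id == "L2"],
               "minor_copies")
  expect_equal(res$report$fail_criterion[res$report$locus_id == "L3"],
               "missing")
  expect_equal(res$report$fail_criterion[res$report$locus_id == "L4"],
               "n_alleles")

  stringent <- filter_profile("custom", max_missing_pct = 10,
                              max_abs_fis = 0.25, required_n_alleles = 2)
  res2 <- apply_filter_profile(gt, stringent)
  expect_setequal(res2$genotypes$loci$locus_id, "L1")
  expect_equal(res2$report$fail_criterion[res2$report$locus_id == "L5"], "fis")

  # an empty profile keeps every biallelic locus
  open <- filter_profile("custom", required_n_alleles = 2)
  res3 <- apply_filter_profile(gt[, 1:3], open)
  expect_equal(n_loci(res3$genotypes), 3L)
})

test_that("profiles are idempotent and tightening is monotone", {
  pm <- population_model(n_individuals = 60, n_loci = 500, fst = 0.03,
                         missing_rate = 0.1, seed = 15)
  gt <- simulate_read_support(simulate_structured_genotypes(pm),
                              mean_depth = 8, error_rate = 0.02, seed = 16)
  prof <- filter_profile("liberal")
  once <- apply_filter_profile(gt, prof)
  twice <- apply_filter_profile(once$genotypes, prof)
  expect_equal(n_loci(twice$genotypes), n_loci(once$genotypes))
  expect_equal(twice$n_calls_masked, 0L)

  survivors <- function(p) sum(apply_filter_profile(gt, p)$report$pass)
  base <- filter_profile("custom", max_missing_pct = 20,
                         min_minor_allele_copies = 3)
  for (tighter in list(
    filter_profile("custom", max_missing_pct = 10, min_minor_allele_copies = 3),
    filter_profile("custom", max_missing_pct = 20, min_minor_allele_copies = 6),
    filter_profile("custom", max_missing_pct = 20, min_minor_allele_copies = 3,
                   max_abs_fis = 0.25))) {
    expect_lte(survivors(tighter), survivors(base))
  }
})

test_that("het read-balance masking happens before locus statistics", {
  dosage <- cbind(L1 = c(1, 1, 0, 2, 0, 1, 1, 1, 1, 1))
  ad_alt <- cbind(L1 = c(1, 5, 0, 10, 0, 5, 6, 4, 5, 5))
  depth <- cbind(L1 = c(30, 10, 9, 10, 8, 10, 11, 9, 10, 10))
  gt <- genotype_table(dosage, depth = depth, ad_ref = depth - ad_alt,
                       ad_alt = ad_alt)
  prof <- filter_profile("custom", min_het_read_fraction = 0.05,
                         max_missing_pct = 15)
  res <- apply_filter_profile(gt, prof)
  # first call is 1/30 = 0.033 < 0.05 -> masked; missingness becomes 10%
  expect_equal(res$n_calls_masked, 1L)
  expect_true(is.na(res$genotypes$dosage[1, 1]))
  expect_equal(res$report$missing_pct, 10)
  expect_true(res$report$pass)

  # configuration referencing absent annotations is rejected up front
  bare <- toy_gt(cbind(a = c(0, 1, 2)))
  expect_error(apply_filter_profile(bare, filter_profile("stringent")),
               "requires")
})

test_that("ld_r2 is the squared genotypic correlation", {
  g <- toy_gt(cbind(a = c(0, 1, 2, 0), b = c(0, 1, 2, 0),
                    c = c(2, 1, 0, 2), d = c(0, 1, 0, 2),
                    e = c(1, 1, 1, 1)))
  expect_equal(ld_r2(g, "a", "b"), 1)
  expect_equal(ld_r2(g, "a", "c"), 1)     # complement: r = -1, r^2 = 1
  expect_equal(ld_r2(g, "a", "d"),
               stats::cor(c(0, 1, 2, 0), c(0, 1, 0, 2))^2)
  expect_true(is.na(ld_r2(g, "a", "e")))  # zero variance -> undefined flag
})

test_that("ld_prune keeps one of a duplicated pair and respects the window", {
  dos <- cbind(L1 = c(0, 1, 2, 0, 1, 2, 0, 0),
               L2 = c(0, 1, 2, 0, 1, 2, 0, 0),
               L3 = c(2, 0, 1, 1, 0, 2, 1, 0))
  gt <- toy_gt(dos)
  kept <- ld_prune(gt, window = 3, step = 1, r2_threshold = 0.2)
  expect_setequal(kept, c("L1", "L3"))    # duplicate dropped (tie -> larger index)

  # mutually unlinked loci are untouched
  pm <- population_model(n_individuals = 200, n_loci = 60, ld_strength = 0,
                         fst = 0, n_subpops = 1, missing_rate = 0, seed = 42)
  g2 <- simulate_structured_genotypes(pm)
  expect_equal(ld_prune(g2, window = 20, step = 5, r2_threshold = 0.5),
               g2$loci$locus_id)

  expect_error(ld_prune(gt, window = 1), "window")
})

test_that("pruned sets satisfy the pairwise constraint (brute-force oracle)", {
  pm <- population_model(n_individuals = 150, n_loci = 200,
                         ld_block_size = 8, ld_strength = 0.9,
                         fst = 0.03, missing_rate = 0.02, seed = 55)
  gt <- simulate_structured_genotypes(pm)
  window <- 50; thr <- 0.2
  kept <- ld_prune(gt, window = window, step = 5, r2_threshold = thr)
  expect_lt(length(kept), n_loci(gt))
  idx <- match(kept, gt$loci$locus_id)
  expect_equal(idx, sort(idx))
  # exhaustive scan over the same sliding windows: no retained pair inside
  # any window exceeds the threshold
  worst <- 0
  for (ws in seq(1, n_loci(gt), by = 5)) {
    inside <- idx[idx >= ws & idx <= ws + window - 1]
    if (length(inside) < 2) next
    pairs <- utils::combn(inside, 2)
    r2 <- apply(pairs, 2, function(pr) ld_r2(gt, pr[1], pr[2]))
    worst <- max(worst, r2, na.rm = TRUE)
  }
  expect_lte(worst, thr)
})
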