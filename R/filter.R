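# SNV quality filtering: per-locus statistics, named filter profiles
# ("stringent" / "liberal"), heterozygote read-balance masking, pairwise LD
# and windowed LD pruning.

#' Per-locus genotype statistics
#'
#' Computes, from observed calls only: alternate-allele frequency `p`, minor
#' allele frequency, observed heterozygosity `Ho` (fraction of heterozygous
#' calls), expected heterozygosity `He = 2p(1-p)`, the Hardy-Weinberg
#' departure statistic `Fis = 1 - Ho/He` (`NA` when `He = 0`), missing-call
#' percentage, mean read depth over non-missing calls, and the copy count of
#' the minor allele.
#'
#' @param gt A [genotype_table()].
#' @param loci Optional locus ids or indices to restrict to.
#' @return A tibble with one row per locus.
#' @export
locus_stats <- function(gt, loci = NULL) {
  X <- gt$dosage
  if (!is.null(loci)) {
    j <- if (is.character(loci)) match(loci, gt$loci$locus_id) else loci
    if (anyNA(j)) stop("unknown locus id", call. = FALSE)
    X <- X[, j, drop = FALSE]
    meta <- gt$loci[j, , drop = FALSE]
    depth <- if (is.null(gt$depth)) NULL else gt$depth[, j, drop = FALSE]
  } else {
    meta <- gt$loci
    depth <- gt$depth
  }
  n <- nrow(X)
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0)) {
    stop("all calls missing at locus ",
         paste(meta$locus_id[n_obs == 0], collapse = ", "), call. = FALSE)
  }
  alt_copies <- colSums(X, na.rm = TRUE)
  p <- alt_copies / (2 * n_obs)
  maf <- pmin(p, 1 - p)
  ho <- colSums(X == 1, na.rm = TRUE) / n_obs
  he <- 2 * p * (1 - p)
  fis <- ifelse(he > 0, 1 - ho / he, NA_real_)
  minor_copies <- pmin(alt_copies, 2 * n_obs - alt_copies)
  mean_depth <- if (is.null(depth)) rep(NA_real_, ncol(X)) else {
    d <- depth
    d[is.na(X)] <- NA
    colMeans(d, na.rm = TRUE)
  }
  tibble::tibble(
    locus_id = meta$locus_id,
    n_obs = unname(n_obs), p = unname(p), maf = unname(maf),
    ho = unname(ho), he = unname(he), fis = unname(fis),
    missing_pct = unname(100 * (n - n_obs) / n),
    mean_depth = unname(mean_depth),
    minor_allele_copies = unname(minor_copies),
    n_alleles = meta$n_alleles,
    qual = if ("qual" %in% names(meta)) meta$qual else NA_real_
  )
}

#' SNV filter profiles
#'
#' A named set of filtering criteria. Two built-in profiles mirror common
#' RAD-Seq practice for outbred panels:
#' \describe{
#'   \item{stringent}{site quality `Q >= 15`, per-call depth `>= 14`,
#'     missingness `<= 10`\%, `|Fis| <= 0.25`, heterozygote minor-read
#'     fraction `>= 0.05`, exactly 2 alleles. No MAF restriction.}
#'   \item{liberal}{per-call depth `>= 3`, mean depth `>= 6`, missingness
#'     `<= 20`\%, minor-allele copies `>= 3`, exactly 2 alleles.}
#' }
#' Calls failing `min_depth`, and heterozygous calls whose minor-read
#' fraction falls below `min_het_read_fraction`, are set missing before the
#' per-locus statistics are recomputed and the locus-level thresholds
#' applied.
#'
#' @param name `"stringent"`, `"liberal"` or `"custom"`.
#' @param min_qual Minimum Phred-like site quality `Q`.
#' @param min_depth Minimum reads per call (failing calls set missing).
#' @param min_ave_depth Minimum mean depth across non-missing calls.
#' @param max_missing_pct Maximum percentage of missing calls, `[0, 100]`.
#' @param min_minor_allele_copies Minimum copies of the minor allele.
#' @param max_abs_fis Maximum `|1 - Ho/He|`.
#' @param min_het_read_fraction Minimum minor-read fraction at heterozygous
#'   calls.
#' @param required_n_alleles Required number of alleles at the site
#'   (2 keeps clean biallelic SNVs).
#' @param het_read_action `"mask_call"` (default: offending heterozygous
#'   calls become missing) or `"drop_locus"`.
#' @return A list of class `filter_profile`. Unset criteria (`NULL`) are not
#'   applied.
#' @export
filter_profile <- function(name = "custom", min_qual = NULL, min_depth = NULL,
                           min_ave_depth = NULL, max_missing_pct = 100,
                           min_minor_allele_copies = NULL, max_abs_fis = NULL,
                           min_het_read_fraction = NULL,
                           required_n_alleles = 2,
                           het_read_action = c("mask_call", "drop_locus")) {
  het_read_action <- match.arg(het_read_action)
  if (name == "stringent") {
    p <- filter_profile("custom", min_qual = 15, min_depth = 14,
                        max_missing_pct = 10, max_abs_fis = 0.25,
                        min_het_read_fraction = 0.05,
                        required_n_alleles = 2,
                        het_read_action = het_read_action)
    p$name <- "stringent"
    return(p)
  }
  if (name == "liberal") {
    p <- filter_profile("custom", min_depth = 3, min_ave_depth = 6,
                        max_missing_pct = 20, min_minor_allele_copies = 3,
                        required_n_alleles = 2)
    p$name <- "liberal"
    return(p)
  }
  num_ok <- function(x) is.null(x) || (is.numeric(x) && x >= 0)
  if (!all(vapply(list(min_qual, min_depth, min_ave_depth,
                       min_minor_allele_copies, max_abs_fis,
                       min_het_read_fraction), num_ok, TRUE))) {
    stop("filter thresholds must be non-negative", call. = FALSE)
  }
  if (max_missing_pct < 0 || max_missing_pct > 100) {
    stop("max_missing_pct must be in [0, 100]", call. = FALSE)
  }
  structure(list(name = name, min_qual = min_qual, min_depth = min_depth,
                 min_ave_depth = min_ave_depth,
                 max_missing_pct = max_missing_pct,
                 min_minor_allele_copies = min_minor_allele_copies,
                 max_abs_fis = max_abs_fis,
                 min_het_read_fraction = min_het_read_fraction,
                 required_n_alleles = required_n_alleles,
                 het_read_action = het_read_action),
            class = "filter_profile")
}

#' Apply a filter profile to a genotype table
#'
#' Per-call criteria (`min_depth`, `min_het_read_fraction`) are applied
#' first by masking offending calls as missing; missingness, MAF and the
#' other per-locus statistics are then recomputed and every configured
#' locus-level criterion applied. A locus is kept iff it satisfies all of
#' them. The report names the first failed criterion of every removed locus
#' (checked in the order: n_alleles, qual, ave_depth, missing, minor_copies,
#' fis).
#'
#' @param gt A [genotype_table()].
#' @param profile A [filter_profile()].
#' @return A list with `genotypes` (the filtered [genotype_table()], masked
#'   calls applied), `report` (tibble: `locus_id`, `pass`, `fail_criterion`
#'   and the recomputed statistics), and `n_calls_masked`.
#' @export
apply_filter_profile <- function(gt, profile) {
  stopifnot(inherits(gt, "genotype_table"), inherits(profile, "filter_profile"))
  needs <- function(field, crit) {
    if (is.null(gt[[field]])) {
      stop("filter profile configuration error: criterion '", crit,
           "' requires the '", field, "' annotation, which is absent",
           call. = FALSE)
    }
  }
  if (!is.null(profile$min_depth)) needs("depth", "min_depth")
  if (!is.null(profile$min_het_read_fraction)) needs("ad_ref", "min_het_read_fraction")
  if (!is.null(profile$min_ave_depth)) needs("depth", "min_ave_depth")
  if (!is.null(profile$min_qual) && !"qual" %in% names(gt$loci)) {
    stop("filter profile configuration error: criterion 'min_qual' requires ",
         "per-locus 'qual' metadata, which is absent", call. = FALSE)
  }

  work <- gt
  n_masked <- 0L
  drop_het_locus <- rep(FALSE, ncol(gt$dosage))
  if (!is.null(profile$min_depth)) {
    mask <- !is.na(work$dosage) & !is.na(work$depth) &
      work$depth < profile$min_depth
    n_masked <- n_masked + sum(mask)
    work$dosage[mask] <- NA
  }
  if (!is.null(profile$min_het_read_fraction)) {
    mrf <- minor_read_fraction(work)
    bad <- !is.na(work$dosage) & work$dosage == 1 &
      (!is.na(mrf) & mrf < profile$min_het_read_fraction)
    if (profile$het_read_action == "mask_call") {
      n_masked <- n_masked + sum(bad)
      work$dosage[bad] <- NA
    } else {
      drop_het_locus <- colSums(bad) > 0
    }
  }
  for (nm in c("depth", "ad_ref", "ad_alt", "gq")) {
    if (!is.null(work[[nm]])) work[[nm]][is.na(work$dosage)] <- NA
  }

  all_missing <- colSums(!is.na(work$dosage)) == 0
  stats <- locus_stats(work[, !all_missing])
  fail <- rep(NA_character_, ncol(work$dosage))
  fail[all_missing] <- "missing"
  idx <- which(!all_missing)
  check <- function(bad, crit) {
    hit <- idx[bad & is.na(fail[idx])]
    fail[hit] <<- crit
  }
  check(stats$n_alleles != profile$required_n_alleles, "n_alleles")
  if (!is.null(profile$min_qual)) {
    check(is.na(stats$qual) | stats$qual < profile$min_qual, "qual")
  }
  if (!is.null(profile$min_ave_depth)) {
    check(stats$mean_depth < profile$min_ave_depth, "ave_depth")
  }
  check(stats$missing_pct > profile$max_missing_pct, "missing")
  if (!is.null(profile$min_minor_allele_copies)) {
    check(stats$minor_allele_copies < profile$min_minor_allele_copies,
          "minor_copies")
  }
  if (!is.null(profile$max_abs_fis)) {
    check(!is.na(stats$fis) & abs(stats$fis) > profile$max_abs_fis, "fis")
  }
  check(drop_het_locus[idx], "het_reads")

  pass <- is.na(fail)
  report <- tibble::tibble(locus_id = gt$loci$locus_id, pass = pass,
                           fail_criterion = fail)
  report <- dplyr::left_join(report, stats, by = "locus_id")
  list(genotypes = work[, pass], report = report,
       n_calls_masked = n_masked)
}

#' Pairwise linkage disequilibrium
#'
#' LD between two loci as the squared Pearson correlation of their dosage
#' vectors (genotypic correlation) over jointly observed individuals.
#'
#' @param gt A [genotype_table()].
#' @param locus_a,locus_b Locus ids or indices.
#' @return `r^2` in `[0, 1]`, or `NA` if either locus has zero variance over
#'   the jointly observed individuals.
#' @export
ld_r2 <- function(gt, locus_a, locus_b) {
  j <- c(if (is.character(locus_a)) match(locus_a, gt$loci$locus_id) else locus_a,
         if (is.character(locus_b)) match(locus_b, gt$loci$locus_id) else locus_b)
  if (anyNA(j)) stop("unknown locus id", call. = FALSE)
  a <- gt$dosage[, j[1]]
  b <- gt$dosage[, j[2]]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("fewer than 2 jointly observed individuals", call. = FALSE)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])^2
}

#' Windowed LD pruning
#'
#' Greedy sliding-window pruning in the style of PLINK's
#' `--indep-pairwise`: within each window of `window` consecutive loci,
#' while any retained pair has `r^2` above `r2_threshold`, the member of the
#' worst (highest-`r^2`) pair with the lower MAF is dropped (ties drop the
#' locus with the larger index); the window then slides by `step` loci.
#' Windows are taken within chromosomes, loci ordered by position.
#'
#' @param gt A [genotype_table()] with loci sorted by (chrom, pos).
#' @param window Window size in loci (>= 2).
#' @param step Slide in loci.
#' @param r2_threshold Pairwise `r^2` ceiling.
#' @return Character vector of retained locus ids, in input order. No
#'   retained pair within any window exceeds the threshold.
#' @export
ld_prune <- function(gt, window = 50, step = 5, r2_threshold = 0.2) {
  if (window < 2) stop("invalid parameter: window must be >= 2", call. = FALSE)
  if (step < 1) stop("invalid parameter: step must be >= 1", call. = FALSE)
  ord <- order(gt$loci$chrom, gt$loci$pos)
  if (!identical(ord, seq_len(nrow(gt$loci)))) {
    stop("loci must be sorted by (chrom, pos) before pruning", call. = FALSE)
  }
  X <- gt$dosage
  maf <- locus_stats(gt)$maf
  retained <- rep(TRUE, ncol(X))
  for (chr in unique(gt$loci$chrom)) {
    cidx <- which(gt$loci$chrom == chr)
    mc <- length(cidx)
    starts <- seq(1, mc, by = step)
    for (ws in starts) {
      widx <- cidx[ws:min(ws + window - 1, mc)]
      widx <- widx[retained[widx]]
      if (length(widx) < 2) next
      r2 <- suppressWarnings(
        stats::cor(X[, widx, drop = FALSE],
                   use = "pairwise.complete.obs")^2)
      r2[is.na(r2)] <- 0
      diag(r2) <- 0
      while (max(r2) > r2_threshold) {
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        i1 <- widx[worst[1]]; i2 <- widx[worst[2]]
        drop_local <- if (maf[i1] < maf[i2]) worst[1]
          else if (maf[i2] < maf[i1]) worst[2]
          else max(worst)
        retained[widx[drop_local]] <- FALSE
        r2[drop_local, ] <- 0
        r2[, drop_local] <- 0
      }
      if (ws + window - 1 >= mc) break
    }
  }
  gt$loci$locus_id[retained]
}
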