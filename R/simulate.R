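# Synthetic population generator: Balding-Nichols subpopulation allele
# frequencies, block-wise LD through shared latent gamete uniforms,
# Poisson/binomial read support, and replicated block-design phenotypes.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Population model for genotype simulation
#'
#' Parameters of the synthetic population the generator emulates: an outbred
#' population of `n_individuals` split into `n_subpops` weakly differentiated
#' subpopulations (Balding-Nichols differentiation `fst`), genotyped at
#' `n_loci` biallelic SNVs whose ancestral allele frequencies are drawn
#' uniformly from `ancestral_maf_range`. Loci are organised in blocks of
#' `ld_block_size` consecutive markers that share a latent gamete signal,
#' producing positive local linkage disequilibrium; `ld_strength` in [0,1]
#' controls how often a locus copies the block signal (the squared value is
#' roughly the dosage correlation between equal-frequency loci in a block).
#'
#' @param n_individuals,n_loci,n_subpops Dimensions of the simulated panel.
#' @param fst Wright's fixation index among subpopulations, in `[0, 1)`.
#' @param ancestral_maf_range Length-2 interval in `(0, 0.5]` for ancestral
#'   minor-allele frequencies.
#' @param ld_block_size Number of consecutive loci per LD block (>= 1).
#' @param ld_strength Probability that a locus reads the block-level latent
#'   gamete uniform instead of an independent one.
#' @param missing_rate Fraction of calls masked as missing, in `[0, 1)`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A validated list of class `population_model`.
#' @export
population_model <- function(n_individuals = 138, n_loci = 10000,
                             n_subpops = 2, fst = 0.05,
                             ancestral_maf_range = c(0.05, 0.5),
                             ld_block_size = 10, ld_strength = 0.8,
                             missing_rate = 0.05, seed = 1) {
  if (n_individuals < 1 || n_loci < 1 || n_subpops < 1) {
    stop("invalid population model: dimensions must be positive", call. = FALSE)
  }
  if (fst < 0 || fst >= 1) stop("invalid population model: fst must be in [0, 1)", call. = FALSE)
  if (length(ancestral_maf_range) != 2 ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      diff(ancestral_maf_range) < 0) {
    stop("invalid population model: ancestral_maf_range must lie in (0, 0.5]", call. = FALSE)
  }
  if (ld_block_size < 1) stop("invalid population model: ld_block_size must be >= 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("invalid population model: missing_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_loci = as.integer(n_loci),
                 n_subpops = as.integer(n_subpops), fst = fst,
                 ancestral_maf_range = ancestral_maf_range,
                 ld_block_size = as.integer(ld_block_size),
                 ld_strength = ld_strength,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "population_model")
}

#' Simulate genotypes for a structured population
#'
#' Draws per-subpopulation allele frequencies from the Balding-Nichols beta
#' distribution around an ancestral frequency (variance `fst * p * (1-p)`),
#' then genotypes each individual as two independent gametes. Within an LD
#' block both gametes of an individual reuse a shared latent uniform with
#' probability `ld_strength`, which induces positive dosage correlation among
#' neighbouring loci while leaving each locus in Hardy-Weinberg proportions
#' within its subpopulation. Calls are masked at `missing_rate`.
#'
#' @param model A [population_model()].
#' @return A [genotype_table()] with per-individual `subpop` labels
#'   (`"pop1"`, `"pop2"`, ...).
#' @export
simulate_structured_genotypes <- function(model) {
  stopifnot(inherits(model, "population_model"))
  with_seed(model$seed, {
    n <- model$n_individuals
    m <- model$n_loci
    k <- model$n_subpops
    subpop <- paste0("pop", rep_len(seq_len(k), n))
    subpop <- sort(subpop)

    p_anc <- stats::runif(m, model$ancestral_maf_range[1],
                          model$ancestral_maf_range[2])
    fst <- model$fst
    pfreq <- matrix(0, nrow = k, ncol = m)  # subpop x locus alt-allele freq
    for (s in seq_len(k)) {
      if (fst == 0) {
        pfreq[s, ] <- p_anc
      } else {
        shape_scale <- (1 - fst) / fst
        pfreq[s, ] <- stats::rbeta(m, p_anc * shape_scale,
                                   (1 - p_anc) * shape_scale)
      }
    }

    block <- (seq_len(m) - 1) %/% model$ld_block_size + 1
    n_blocks <- max(block)
    dosage <- matrix(0, nrow = n, ncol = m)
    s_idx <- match(subpop, paste0("pop", seq_len(k)))
    for (g in 1:2) {
      u_block <- matrix(stats::runif(n * n_blocks), nrow = n)  # shared signal
      u_loc <- matrix(stats::runif(n * m), nrow = n)
      use_block <- matrix(stats::runif(n * m) < model$ld_strength, nrow = n)
      u <- ifelse(use_block, u_block[, block, drop = FALSE], u_loc)
      p_il <- pfreq[s_idx, , drop = FALSE]
      dosage <- dosage + (u < p_il)
    }
    if (model$missing_rate > 0) {
      dosage[matrix(stats::runif(n * m) < model$missing_rate, nrow = n)] <- NA
    }

    loci <- tibble::tibble(
      locus_id = sprintf("snv%06d", seq_len(m)),
      chrom = "1", pos = seq_len(m) * 100L,
      ref = "A", alt = "T", n_alleles = 2L
    )
    genotype_table(dosage,
                   individual_ids = sprintf("ind%03d", seq_len(n)),
                   loci = loci, subpop = subpop)
  })
}

#' Annotate simulated genotypes with read support
#'
#' Adds the per-call fields consumed by the depth and heterozygote
#' read-balance filters: total depth (Poisson around `mean_depth`),
#' reference/alternate read counts (allele balance 0.5 at heterozygotes;
#' `error_rate` leakage toward the absent allele at homozygotes), a
#' Phred-scaled genotype quality from binomial genotype likelihoods, and a
#' per-locus Phred-like site quality.
#'
#' @param gt A [genotype_table()].
#' @param mean_depth Mean sequencing depth per call (> 0).
#' @param error_rate Per-read probability of reporting the absent allele at a
#'   homozygous call, in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return The input table with `depth`, `ad_ref`, `ad_alt`, `gq` matrices
#'   and a `qual` column in the locus metadata.
#' @export
simulate_read_support <- function(gt, mean_depth = 14, error_rate = 0.01,
                                  seed = 1) {
  stopifnot(inherits(gt, "genotype_table"))
  if (mean_depth <= 0) stop("mean_depth must be positive", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("invalid parameter: error_rate must be in [0, 0.5)", call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(gt$dosage); m <- ncol(gt$dosage)
    obs <- !is.na(gt$dosage)
    depth <- matrix(NA_real_, n, m)
    depth[obs] <- stats::rpois(sum(obs), mean_depth)
    alt_p <- matrix(NA_real_, n, m)
    alt_p[obs] <- c(error_rate, 0.5, 1 - error_rate)[gt$dosage[obs] + 1]
    ad_alt <- matrix(NA_real_, n, m)
    ad_alt[obs] <- stats::rbinom(sum(obs), depth[obs], alt_p[obs])
    ad_ref <- depth - ad_alt

    # Phred-scaled quality: gap between best and second-best binomial
    # genotype log-likelihoods at a nominal 1% sequencing error rate
    e <- 0.01
    gq <- matrix(NA_real_, n, m)
    r <- ad_ref[obs]; a <- ad_alt[obs]
    ll <- cbind(r * log(1 - e) + a * log(e),
                (r + a) * log(0.5),
                r * log(e) + a * log(1 - e))
    top2 <- apply(ll, 1, function(x) diff(sort(x, decreasing = TRUE)[2:1]))
    gq[obs] <- pmin(99, round(10 * top2 / log(10)))

    out <- gt
    out$depth <- depth; out$ad_ref <- ad_ref; out$ad_alt <- ad_alt
    dimnames(out$depth) <- dimnames(out$ad_ref) <- dimnames(out$ad_alt) <-
      dimnames(gt$dosage)
    out$gq <- gq; dimnames(out$gq) <- dimnames(gt$dosage)
    mean_dp <- colMeans(depth, na.rm = TRUE)
    mean_dp[is.nan(mean_dp)] <- 0
    out$loci$qual <- pmin(99, round(pmax(
      1, 3 * mean_dp + stats::rnorm(m, 0, 8))))
    out
  })
}

#' Trait model for phenotype simulation
#'
#' @param h2 Target broad-sense heritability on a clone-mean basis, `[0, 1]`.
#' @param n_qtl Number of causal loci with additive effects.
#' @param qtl_effect_sd Standard deviation of raw additive effects (the
#'   genotypic values are rescaled afterwards, so this only shapes the
#'   relative effect-size distribution).
#' @param subpop_shift Mean shift (in genotypic-SD units) added to the last
#'   subpopulation, confounding the trait with population structure.
#' @param n_blocks Number of complete blocks (one replicate of every
#'   genotype per block).
#' @param block_effect_sd SD of the fixed block effects.
#' @param seed Integer seed.
#' @return A validated list of class `trait_model`.
#' @export
trait_model <- function(h2 = 0.6, n_qtl = 50, qtl_effect_sd = 1,
                        subpop_shift = 0, n_blocks = 4,
                        block_effect_sd = 0.5, seed = 1) {
  if (h2 < 0 || h2 > 1) stop("invalid trait model: h2 must be in [0, 1]", call. = FALSE)
  if (n_blocks < 1) stop("invalid trait model: n_blocks must be >= 1", call. = FALSE)
  if (n_qtl < 0) stop("invalid trait model: n_qtl must be >= 0", call. = FALSE)
  structure(list(h2 = h2, n_qtl = as.integer(n_qtl),
                 qtl_effect_sd = qtl_effect_sd, subpop_shift = subpop_shift,
                 n_blocks = as.integer(n_blocks),
                 block_effect_sd = block_effect_sd, seed = as.integer(seed)),
            class = "trait_model")
}

#' Simulate a replicated field-trial trait
#'
#' Genotypic values are a sum of `n_qtl` additive marker effects plus an
#' optional subpopulation mean shift, rescaled so their realized variance is
#' exactly `h2`; the residual variance is set to `n_blocks * (1 - h2)` so
#' the clone-mean (broad-sense) heritability equals `h2` by construction.
#' Observations follow a randomized complete block design,
#' `y_ij = g_i + block_j + e_ij`, with one replicate of every genotype in
#' each of `n_blocks` blocks.
#'
#' @param gt A [genotype_table()].
#' @param model A [trait_model()].
#' @return A list with `observations` (tibble: `genotype_id`, `block`,
#'   `value`), `genotypic_values` (tibble: `genotype_id`, `value`), `qtl`
#'   (tibble: `locus_id`, `effect`), and the realized `sigma2_e` and target
#'   `h2`.
#' @export
simulate_trait <- function(gt, model) {
  stopifnot(inherits(gt, "genotype_table"), inherits(model, "trait_model"))
  if (model$n_qtl > n_loci(gt)) {
    stop("invalid trait model: n_qtl exceeds the number of loci", call. = FALSE)
  }
  with_seed(model$seed, {
    n <- n_individuals(gt)
    X <- impute_mean(gt)
    poly <- which(apply(X, 2, stats::sd) > 0)
    qtl_idx <- if (model$n_qtl > 0) {
      sort(sample(poly, min(model$n_qtl, length(poly))))
    } else integer(0)
    effects <- stats::rnorm(length(qtl_idx), 0, model$qtl_effect_sd)
    g <- if (length(qtl_idx)) drop(X[, qtl_idx, drop = FALSE] %*% effects) else
      rep(0, n)
    if (model$subpop_shift != 0 && !is.null(gt$subpop)) {
      sdg <- stats::sd(g)
      if (sdg > 0) g <- g / sdg
      g <- g + model$subpop_shift * (gt$subpop == max(gt$subpop))
    }
    # rescale so var(g) is exactly h2 (clone-mean phenotypic variance 1)
    sdg <- stats::sd(g)
    g <- if (model$h2 == 0 || sdg == 0) rep(0, n) else
      (g - mean(g)) / sdg * sqrt(model$h2)
    sigma2_e <- model$n_blocks * (1 - model$h2)

    block_eff <- stats::rnorm(model$n_blocks, 0, model$block_effect_sd)
    obs <- tidyr::expand_grid(
      genotype_id = gt$individual_ids,
      block = paste0("block", seq_len(model$n_blocks))
    )
    gi <- g[match(obs$genotype_id, gt$individual_ids)]
    bj <- block_eff[match(obs$block, paste0("block", seq_len(model$n_blocks)))]
    obs$value <- gi + bj + stats::rnorm(nrow(obs), 0, sqrt(sigma2_e))

    list(observations = obs,
         genotypic_values = tibble::tibble(genotype_id = gt$individual_ids,
                                           value = g),
         qtl = tibble::tibble(locus_id = gt$loci$locus_id[qtl_idx],
                              effect = effects),
         sigma2_e = sigma2_e, h2 = model$h2)
  })
}
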