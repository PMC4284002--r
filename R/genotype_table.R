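#' Genotype table
#'
#' The central container for SNV genotype data: an individuals-by-loci
#' allele-dosage matrix (`0`, `1`, `2` copies of the alternate allele, `NA`
#' for missing calls) plus per-locus metadata and, optionally, per-call read
#' support (total depth, per-allele depths, genotype quality).
#'
#' @param dosage Numeric matrix, individuals in rows, loci in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param individual_ids Character vector of unique individual identifiers;
#'   defaults to the dosage rownames or `ind1..indN`.
#' @param loci A data frame with one row per locus: columns `locus_id`,
#'   `chrom`, `pos`, `ref`, `alt`; optional `qual` (Phred-like SNV quality)
#'   and `n_alleles` (number of alleles observed at the site, 2 for a clean
#'   biallelic SNV). Missing columns are filled with defaults.
#' @param depth,gq Optional numeric matrices (same shape as `dosage`) of
#'   per-call total read depth and Phred-like genotype quality.
#' @param ad_ref,ad_alt Optional numeric matrices of per-call reference and
#'   alternate allele read counts.
#' @param subpop Optional character vector of per-individual subpopulation
#'   labels.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(dosage, individual_ids = NULL, loci = NULL,
                           depth = NULL, ad_ref = NULL, ad_alt = NULL,
                           gq = NULL, subpop = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (n < 1) {
    stop("dosage matrix must have at least one individual", call. = FALSE)
  }
  bad <- !(is.na(dosage) | dosage %in% c(0, 1, 2))
  if (any(bad)) {
    stop("dosage entries must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(dosage) %||% sprintf("ind%03d", seq_len(n))
  }
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != n) stop("individual_ids length mismatch", call. = FALSE)
  if (anyDuplicated(individual_ids)) stop("duplicated individual ids", call. = FALSE)

  if (is.null(loci)) {
    loci <- tibble::tibble(
      locus_id = colnames(dosage) %||% sprintf("snv%05d", seq_len(m)),
      chrom = "1", pos = seq_len(m),
      ref = "A", alt = "T"
    )
  }
  loci <- tibble::as_tibble(loci)
  if (nrow(loci) != m) stop("loci metadata row count must equal ncol(dosage)", call. = FALSE)
  if (!"locus_id" %in% names(loci)) {
    loci$locus_id <- colnames(dosage) %||% sprintf("snv%05d", seq_len(m))
  }
  if (!"chrom" %in% names(loci)) loci$chrom <- "1"
  if (!"pos" %in% names(loci)) loci$pos <- seq_len(m)
  if (!"ref" %in% names(loci)) loci$ref <- "A"
  if (!"alt" %in% names(loci)) loci$alt <- "T"
  if (!"n_alleles" %in% names(loci)) loci$n_alleles <- 2L
  if (any(loci$pos <= 0)) stop("locus positions must be strictly positive", call. = FALSE)
  if (anyDuplicated(loci$locus_id)) stop("duplicated locus ids", call. = FALSE)

  dimnames(dosage) <- list(individual_ids, loci$locus_id)
  for (nm in c("depth", "ad_ref", "ad_alt", "gq")) {
    mat <- get(nm)
    if (!is.null(mat)) {
      mat <- as.matrix(mat)
      if (!all(dim(mat) == c(n, m))) stop(nm, " matrix shape mismatch", call. = FALSE)
      dimnames(mat) <- dimnames(dosage)
      assign(nm, mat)
    }
  }
  if (!is.null(subpop) && length(subpop) != n) {
    stop("subpop length mismatch", call. = FALSE)
  }

  structure(
    list(dosage = dosage, individual_ids = individual_ids, loci = loci,
         depth = depth, ad_ref = ad_ref, ad_alt = ad_alt, gq = gq,
         subpop = subpop),
    class = "genotype_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d loci\n",
              nrow(x$dosage), ncol(x$dosage)))
  miss <- mean(is.na(x$dosage)) * 100
  cat(sprintf("  missing calls: %.2f%%", miss))
  if (!is.null(x$depth)) cat("; read depth present")
  if (!is.null(x$subpop)) {
    cat(sprintf("; subpops: %s", paste(names(table(x$subpop)), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosage)

#' Number of individuals / loci in a genotype table
#' @param gt A [genotype_table()].
#' @return Integer count.
#' @export
n_individuals <- function(gt) nrow(gt$dosage)

#' @rdname n_individuals
#' @export
n_loci <- function(gt) ncol(gt$dosage)

#' Subset a genotype table
#'
#' @param x A [genotype_table()].
#' @param i Individual index (integer, logical or id character vector).
#' @param j Locus index (integer, logical or id character vector).
#' @param ... Unused.
#' @return A `genotype_table` restricted to the selected rows/columns.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$individual_ids)
  if (is.character(j)) j <- match(j, x$loci$locus_id)
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  sub <- function(mat) if (is.null(mat)) NULL else mat[i, j, drop = FALSE]
  genotype_table(
    dosage = x$dosage[i, j, drop = FALSE],
    individual_ids = x$individual_ids[i],
    loci = x$loci[j, , drop = FALSE],
    depth = sub(x$depth), ad_ref = sub(x$ad_ref), ad_alt = sub(x$ad_alt),
    gq = sub(x$gq),
    subpop = if (is.null(x$subpop)) NULL else x$subpop[i]
  )
}

#' Mean-impute missing dosages
#'
#' Replaces each missing call by the mean dosage of the observed calls at
#' that locus, the standard preparation for kinship, PCA and whole-genome
#' regression on incomplete genotype matrices. Observed calls are unchanged.
#'
#' @param gt A [genotype_table()].
#' @return A dense numeric matrix (individuals x loci) with no missing
#'   values.
#' @export
impute_mean <- function(gt) {
  X <- gt$dosage
  miss <- is.na(X)
  if (!any(miss)) return(X)
  n_obs <- colSums(!miss)
  if (any(n_obs == 0)) {
    stop("all calls missing at locus ",
         paste(gt$loci$locus_id[n_obs == 0], collapse = ", "), call. = FALSE)
  }
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}

#' Per-call minor-read fraction
#'
#' For tables carrying per-allele read counts, the fraction of reads
#' supporting the less frequent allele of each call. Used by the
#' heterozygote read-balance filter.
#'
#' @param gt A [genotype_table()] with `ad_ref`/`ad_alt` matrices.
#' @return Matrix of minor-read fractions (`NA` where depth is zero or read
#'   counts are absent).
#' @export
minor_read_fraction <- function(gt) {
  if (is.null(gt$ad_ref) || is.null(gt$ad_alt)) {
    stop("genotype table carries no per-allele read counts", call. = FALSE)
  }
  tot <- gt$ad_ref + gt$ad_alt
  out <- pmin(gt$ad_ref, gt$ad_alt) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Alternate-allele frequencies from observed calls
#' @param gt A [genotype_table()].
#' @return Numeric vector, one frequency per locus.
#' @export
allele_freq <- function(gt) {
  colMeans(gt$dosage, na.rm = TRUE) / 2
}

#' Write / read a dosage matrix as TSV
#'
#' Plain-text interchange format: rows are individuals, the header names the
#' loci, missing calls are written as `NA`.
#'
#' @param gt A [genotype_table()].
#' @param path File path.
#' @return `write_dosage_tsv` returns `path` invisibly; `read_dosage_tsv`
#'   returns a [genotype_table()] (with default locus metadata).
#' @export
write_dosage_tsv <- function(gt, path) {
  df <- data.frame(individual_id = gt$individual_ids, gt$dosage,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  genotype_table(mat, individual_ids = ids)
}
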