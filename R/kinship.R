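# Relatedness matrices: identity-by-state allele sharing and the VanRaden
# genomic relationship matrix.

new_kinship <- function(values, ids, method) {
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, method = method),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %s, %d individuals\n", x$method,
              length(x$ids)))
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("  off-diagonal range [%.3f, %.3f], mean diagonal %.3f\n",
              min(off), max(off), mean(diag(x$values))))
  invisible(x)
}

#' Identity-by-state kinship matrix
#'
#' Average allele sharing between every pair of individuals:
#' `K_ij = mean over jointly observed loci of (2 - |g_i - g_j|) / 2`,
#' i.e. 1 for identical genotypes and 0 for opposite homozygotes at every
#' locus. The diagonal is exactly 1. This is the kinship the EMMAX-style
#' association scan uses by default.
#'
#' @param gt A [genotype_table()].
#' @return A `kinship_matrix` (method `"IBS"`).
#' @export
ibs_kinship <- function(gt) {
  X <- gt$dosage
  n <- nrow(X)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  O <- !is.na(X)
  I0 <- (X == 0) & O; I1 <- (X == 1) & O; I2 <- (X == 2) & O
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <-
    storage.mode(O) <- "double"
  C <- tcrossprod(O)                       # jointly observed locus counts
  if (any(C == 0)) {
    bad <- which(C == 0, arr.ind = TRUE)[1, ]
    stop("individuals ", gt$individual_ids[bad[1]], " and ",
         gt$individual_ids[bad[2]], " share no observed loci", call. = FALSE)
  }
  absdiff <- 2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0)) +
    tcrossprod(I1, I0 + I2) + tcrossprod(I0 + I2, I1)
  K <- 1 - absdiff / (2 * C)
  new_kinship((K + t(K)) / 2, gt$individual_ids, "IBS")
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p * (1 - p)))` with `Z` the mean-imputed dosage
#' matrix centered at twice the observed alternate-allele frequency of each
#' locus. Under Hardy-Weinberg equilibrium the diagonal averages ~1.
#'
#' @param gt A [genotype_table()].
#' @return A `kinship_matrix` (method `"GRM"`).
#' @export
grm_vanraden <- function(gt) {
  X <- impute_mean(gt)
  p <- allele_freq(gt)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci: cannot scale the GRM", call. = FALSE)
  Z <- sweep(X[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(Z) / denom
  new_kinship((K + t(K)) / 2, gt$individual_ids, "GRM")
}

#' Write / read a kinship matrix as square TSV
#'
#' @param k A `kinship_matrix`.
#' @param path File path.
#' @return `write_kinship_tsv` returns `path` invisibly; `read_kinship_tsv`
#'   returns a `kinship_matrix` (method read from the first header
#'   comment, defaulting to `"IBS"`).
#' @export
write_kinship_tsv <- function(k, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method=", k$method), con)
  df <- data.frame(id = k$ids, k$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  first <- readLines(path, n = 1)
  method <- if (grepl("^# method=", first)) sub("^# method=", "", first) else "IBS"
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  ids <- as.character(df[[1]])
  new_kinship(as.matrix(df[, -1, drop = FALSE]), ids, method)
}
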