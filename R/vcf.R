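#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (via the vcfR package) into a [genotype_table()].
#' Biallelic genotypes are converted to alternate-allele dosage 0/1/2;
#' `./.` calls become missing. Multi-allelic records are preserved with
#' `n_alleles > 2` in the locus metadata (their dosages are set missing) so
#' they can be removed later by the allele-count filter. Per-call `DP`,
#' `AD` and `GQ` fields are captured when present.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return A [genotype_table()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  m <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicated sample id in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(samples)

  alt <- fix[, "ALT"]
  n_alleles <- 1L + ifelse(is.na(alt) | alt == ".", 0L,
                           1L + nchar(gsub("[^,]", "", alt)))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])

  gt_str <- vcfR::extract.gt(v, element = "GT")
  # dosage: count of '1' alleles; any allele index >1 or missing -> NA
  to_dosage <- function(g) {
    g <- sub(":.*", "", g)
    out <- rep(NA_real_, length(g))
    clean <- !is.na(g)
    gg <- gsub("\\|", "/", g[clean])
    d <- rep(NA_real_, length(gg))
    d[gg %in% c("0/0", "0")] <- 0
    d[gg %in% c("0/1", "1/0")] <- 1
    d[gg %in% c("1/1", "1")] <- 2
    out[clean] <- d
    out
  }
  dosage <- apply(gt_str, 2, to_dosage)
  if (m == 1) dosage <- matrix(dosage, nrow = 1)
  dosage <- t(dosage)  # vcfR is loci x samples; we want samples x loci

  grab_num <- function(el) {
    if (!any(grepl(el, v@gt[, 1]))) return(NULL)
    t(suppressWarnings(vcfR::extract.gt(v, element = el, as.numeric = TRUE)))
  }
  depth <- grab_num("DP")
  gq <- grab_num("GQ")
  ad_ref <- ad_alt <- NULL
  if (any(grepl("AD", v@gt[, 1]))) {
    ad <- vcfR::extract.gt(v, element = "AD")
    ad_ref <- t(suppressWarnings(matrix(as.numeric(sub(",.*", "", ad)),
                                        nrow = nrow(ad))))
    ad_alt <- t(suppressWarnings(matrix(
      as.numeric(vapply(strsplit(ad, ","), function(x)
        if (length(x) >= 2) x[2] else NA_character_, "")),
      nrow = nrow(ad))))
  }

  loci <- tibble::tibble(
    locus_id = as.character(ids),
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(alt),
    qual = qual,
    n_alleles = as.integer(n_alleles)
  )
  genotype_table(dosage, individual_ids = samples, loci = loci,
                 depth = depth, ad_ref = ad_ref, ad_alt = ad_alt, gq = gq)
}

#' Write a genotype table to a VCF file
#'
#' Serializes dosages (and read support, when present) to VCF 4.2 with
#' `GT[:DP:AD:GQ]` FORMAT fields. Missing calls are written as `./.`.
#' `read_vcf(write_vcf(x))` reproduces the dosage matrix, individual ids
#' and locus coordinates exactly.
#'
#' @param gt A [genotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  has_dp <- !is.null(gt$depth)
  has_ad <- !is.null(gt$ad_ref) && !is.null(gt$ad_alt)
  has_gq <- !is.null(gt$gq)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=grasspred",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (has_dp) hdr <- c(hdr, '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (has_ad) hdr <- c(hdr, '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  if (has_gq) hdr <- c(hdr, '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gt$individual_ids),
                      collapse = "\t"))
  writeLines(hdr, con)
  m <- ncol(gt$dosage)
  if (m == 0) return(invisible(path))

  gt_codes <- matrix("./.", nrow = nrow(gt$dosage), ncol = m)
  gt_codes[!is.na(gt$dosage) & gt$dosage == 0] <- "0/0"
  gt_codes[!is.na(gt$dosage) & gt$dosage == 1] <- "0/1"
  gt_codes[!is.na(gt$dosage) & gt$dosage == 2] <- "1/1"
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_ad) "AD", if (has_gq) "GQ"),
               collapse = ":")
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE, scientific = FALSE))
  calls <- gt_codes
  if (has_dp) calls <- matrix(paste(calls, fmt_num(gt$depth), sep = ":"),
                              nrow = nrow(calls))
  if (has_ad) calls <- matrix(paste0(calls, ":", fmt_num(gt$ad_ref), ",",
                                     fmt_num(gt$ad_alt)), nrow = nrow(calls))
  if (has_gq) calls <- matrix(paste(calls, fmt_num(gt$gq), sep = ":"),
                              nrow = nrow(calls))
  qual <- if ("qual" %in% names(gt$loci)) fmt_num(gt$loci$qual) else rep(".", m)
  lines <- vapply(seq_len(m), function(j) {
    paste(c(gt$loci$chrom[j], gt$loci$pos[j], gt$loci$locus_id[j],
            gt$loci$ref[j], gt$loci$alt[j], qual[j], "PASS", ".",
            fmt, calls[, j]), collapse = "\t")
  }, "")
  writeLines(lines, con)
  invisible(path)
}
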