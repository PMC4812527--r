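## GenotypeTable: biallelic SNP dosages (count of alternative alleles,
## 0/1/2/NA) with a flag for CpG-destroying variants. A variant is
## CpG-destroying when it removes a CpG dinucleotide on either strand,
## e.g. a C>A substitution whose reference right flank is G, or a G>T whose
## left flank is C.

#' Construct a GenotypeTable
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `cpg_destroying` (logical).
#' @param dosage integer matrix snps x samples with values 0, 1, 2 or `NA`.
#' @return object of class `GenotypeTable`.
#' @export
GenotypeTable <- function(snps, dosage) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(snps)) stop("dosage rows != number of SNPs")
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id")
  rownames(dosage) <- snps$snp_id
  structure(list(snps = as.data.frame(snps), dosage = dosage),
            class = "GenotypeTable")
}

#' @method print GenotypeTable
#' @export
print.GenotypeTable <- function(x, ...) {
  cat("GenotypeTable:", nrow(x$snps), "SNPs x", ncol(x$dosage),
      "samples;", sum(x$snps$cpg_destroying), "CpG-destroying\n")
  invisible(x)
}

#' Is a biallelic substitution CpG-destroying?
#'
#' Given reference allele, alternative allele and the reference bases
#' immediately left and right of the site, decide whether the variant
#' removes a CpG dinucleotide on either strand: a reference C followed by G
#' mutated away from C, or a reference G preceded by C mutated away from G.
#'
#' @param ref,alt single reference/alternative bases.
#' @param left,right flanking reference bases (may be `NA`).
#' @return logical (NA flanks give `FALSE` for the corresponding strand).
#' @export
is_cpg_destroying <- function(ref, alt, left = NA, right = NA) {
  ref <- toupper(ref); alt <- toupper(alt)
  left <- toupper(left); right <- toupper(right)
  plus <- !is.na(right) & ref == "C" & right == "G" & alt != "C"
  minus <- !is.na(left) & ref == "G" & left == "C" & alt != "G"
  plus | minus
}

#' Read genotypes from a VCF or a plain site table
#'
#' VCF input (via \pkg{vcfR}) uses only site fields and the GT genotype;
#' dosage is the alt-allele count. Multiallelic sites are skipped with a
#' warning reporting the count. CpG-destroying status is computed from
#' ref/alt plus flanking bases when the INFO field carries `LF=`/`RF=`
#' (left/right reference flank) tags; otherwise it is `NA` unless supplied.
#' Table input is tab-separated with header columns `snp_id`, `chrom`,
#' `pos` (1-based, converted), `ref`, `alt`, `cpg_destroying`
#' (TRUE/FALSE), then one dosage column per sample. The explicit flag column
#' is required for tables: flanking context is never guessed.
#'
#' @param path file path (`.vcf` or table).
#' @return GenotypeTable.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_genotypes_vcf(path)
  else read_genotypes_table(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    warning(sum(multi), " multiallelic site(s) skipped")
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(a != "0")
  })
  info <- if (is.null(fix$INFO)) rep(NA_character_, nrow(fix)) else fix$INFO
  lf <- sub(".*LF=([ACGTN]).*", "\\1", info)
  lf[!grepl("LF=", info)] <- NA
  rf <- sub(".*RF=([ACGTN]).*", "\\1", info)
  rf[!grepl("RF=", info)] <- NA
  cpg <- ifelse(is.na(lf) & is.na(rf), NA,
                is_cpg_destroying(fix$REF, fix$ALT, lf, rf))
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0("snp", which(is.na(ids) | ids == "."))
  snps <- data.frame(snp_id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS) - 1L,
                     ref = fix$REF, alt = fix$ALT,
                     cpg_destroying = as.logical(cpg),
                     stringsAsFactors = FALSE)
  storage.mode(dos) <- "integer"
  GenotypeTable(snps, dos)
}

read_genotypes_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt", "cpg_destroying")
  if (!all(need %in% names(x)))
    stop("genotype table needs columns ", paste(need, collapse = ", "))
  samp <- setdiff(names(x), need)
  if (!length(samp)) stop("genotype table has no sample columns")
  dos <- as.matrix(x[, samp, drop = FALSE])
  storage.mode(dos) <- "integer"
  snps <- x[, need]
  snps$pos <- as.integer(snps$pos) - 1L
  snps$cpg_destroying <- as.logical(snps$cpg_destroying)
  GenotypeTable(snps, dos)
}

#' Write a GenotypeTable as a site table
#' @param gt GenotypeTable.
#' @param path output path (1-based positions on disk).
#' @export
write_genotypes <- function(gt, path) {
  d <- gt$snps[, c("snp_id", "chrom", "pos", "ref", "alt",
                   "cpg_destroying")]
  d$pos <- d$pos + 1L
  d <- cbind(d, as.data.frame(gt$dosage))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a normalized expression matrix
#'
#' Tab-separated, first column `gene_id`, remaining header columns are
#' sample ids; values are normalized (batch-corrected) expression.
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(x$gene_id)) stop("duplicate gene ids")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  if (!all(is.finite(m))) stop("non-finite expression values")
  m
}

#' @rdname read_expression
#' @param expr genes x samples matrix with gene rownames.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
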