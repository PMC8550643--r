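# Plain-text genotype interchange: whitespace-delimited dosage matrix with
# a SNP-id header row, plus a minimal GT-only VCF writer for interop.

#' Write / read a genotype dataset as whitespace-delimited text
#'
#' The file has a header row of SNP identifiers and one row of 0/1/2
#' dosages per individual. Haplotypes are not round-tripped.
#'
#' @param data A [genotype_dataset()].
#' @param path Output file path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns a [genotype_dataset()].
#' @export
write_genotypes <- function(data, path) {
  stopifnot(inherits(data, "genotype_dataset"))
  out <- as.data.frame(data$dosages)
  names(out) <- data$snp_ids
  write.table(out, path, quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_genotypes
#' @param population Population label to attach on read.
#' @export
read_genotypes <- function(path, population = "pop") {
  tab <- read.table(path, header = TRUE, check.names = FALSE)
  genotype_dataset(as.matrix(tab), snp_ids = names(tab),
                   population = population)
}

#' Export genotypes as a minimal VCF
#'
#' Writes a GT-only VCFv4.2 file on a single synthetic contig, with SNP
#' index as position and placeholder A/G alleles (dosage counts the A
#' allele). Intended for interoperability checks, not as a primary format.
#'
#' @param data A [genotype_dataset()].
#' @param path Output path (plain text; use a `.vcf` extension).
#' @param contig Contig name written in the header and records.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(data, path, contig = "1") {
  stopifnot(inherits(data, "genotype_dataset"))
  n <- nrow(data$dosages)
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", contig),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  samples <- sprintf("ind%d", seq_len(n))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  m <- ncol(data$dosages)
  for (j in seq_len(m)) {
    # ALT allele (A) is the dosage-counted allele
    gt <- gt_codes[data$dosages[, j] + 1L]
    writeLines(paste(c(contig, j, data$snp_ids[j], "G", "A", ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
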