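#' Write diploid genotypes as a minimal VCF
#'
#' Emits an uncompressed VCF 4.2 with GT, DP and GQ per sample. Missing
#' genotypes are written as `./.`. Positions are 1-based per the VCF
#' convention.
#'
#' @param dosage site x sample integer matrix of alt-allele dosages
#'   (0/1/2, NA = missing).
#' @param chrom chromosome label (recycled per site).
#' @param pos 1-based positions.
#' @param id site identifiers.
#' @param ref,alt reference and alternate bases.
#' @param path output file path.
#' @param qual per-site QUAL values (default missing, written as `.`).
#' @param dp,gq optional site x sample depth and genotype-quality matrices.
#' @param sample_names column names for the genotype columns.
#' @return the path, invisibly.
#' @export
write_genotype_vcf <- function(dosage, chrom, pos, id, ref, alt, path,
                               qual = NULL, dp = NULL, gq = NULL,
                               sample_names = colnames(dosage)) {
  abort_if(!is.matrix(dosage), "dosage must be a site x sample matrix")
  ns <- ncol(dosage)
  nsite <- nrow(dosage)
  if (is.null(sample_names)) sample_names <- sprintf("S%03d", seq_len(ns))
  chrom <- rep_len(chrom, nsite)
  qual_chr <- if (is.null(qual)) rep(".", nsite) else format(qual, trim = TRUE)
  gt_of <- function(d) c(`0` = "0/0", `1` = "0/1", `2` = "1/1")[as.character(d)]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=apoeadmix",
    sprintf("##contig=<ID=%s>", unique(chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  body <- vapply(seq_len(nsite), function(i) {
    cells <- vapply(seq_len(ns), function(j) {
      d <- dosage[i, j]
      gt <- if (is.na(d)) "./." else gt_of(d)
      dpv <- if (is.null(dp)) "." else
        if (is.na(dp[i, j])) "." else as.character(dp[i, j])
      gqv <- if (is.null(gq)) "." else
        if (is.na(gq[i, j])) "." else as.character(round(gq[i, j]))
      paste(gt, dpv, gqv, sep = ":")
    }, character(1))
    paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], qual_chr[i], "PASS", ".",
            "GT:DP:GQ", cells), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read diploid genotypes from a VCF into a dosage matrix
#'
#' @param path VCF file path.
#' @return list with `dosage` (site x sample alt dosage matrix, NA for
#'   missing), `fix` (the fixed VCF columns as a data.frame) and
#'   `samples`.
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  })
  dosage <- matrix(as.integer(dosage), nrow = nrow(gt),
                   dimnames = dimnames(gt))
  list(dosage = dosage, fix = as.data.frame(vcfR::getFIX(v)),
       samples = colnames(gt))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
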