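#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCFv4.2 file with one biallelic SNP per column of the genotype
#' matrix and GT-only sample columns. Positions are supplied 0-based and
#' written 1-based per the standard. Panel tag SNPs can be flagged in INFO.
#'
#' @param genotypes integer matrix (samples x sites) with entries 0/1/2/NA
#' @param positions 0-based site positions
#' @param contig contig name
#' @param path output path
#' @param tag logical vector (or NULL): sites to flag with INFO \code{TAG}
#' @return invisibly, \code{path}
#' @export
write_vcf <- function(genotypes, positions, contig, path, tag = NULL) {
  stopifnot(ncol(genotypes) == length(positions))
  samples <- rownames(genotypes)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- apply(genotypes, 2L, function(col) {
    out <- gt_code[as.character(col)]
    out[is.na(out)] <- "./."
    out
  })  # samples x sites
  info <- if (is.null(tag)) rep(".", length(positions)) else
    ifelse(tag, "TAG", ".")
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contig),
    "##INFO=<ID=TAG,Number=0,Type=Flag,Description=\"Inversion tag SNP\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(contig, positions + 1L, ".", "A", "G", ".", "PASS", info, "GT",
          apply(body, 2L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into a 0/1/2 genotype matrix
#'
#' Diploid GT fields are converted to alternate-allele counts; missing or
#' half-missing calls become NA. Multiallelic records are dropped with a
#' warning.
#'
#' @param vcf_path VCF file (plain or bgzipped)
#' @return list with \code{genotypes} (integer matrix, samples x sites),
#'   \code{contig}, \code{positions} (1-based), \code{ids} (site ids)
#' @export
vcf_genotype_matrix <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  counts <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  counts[clean %in% c("0/0")] <- 0L
  counts[clean %in% c("0/1", "1/0")] <- 1L
  counts[clean %in% c("1/1")] <- 2L
  list(
    genotypes = t(counts),
    contig = fix[, "CHROM"],
    positions = as.integer(fix[, "POS"]),
    ids = paste0(fix[, "CHROM"], ":", fix[, "POS"])
  )
}

#' Load tag-panel genotypes from a VCF
#'
#' Builds the (samples x panel SNPs) genotype matrix the inversion genotyper
#' consumes: one column per panel SNP, coded so that 2 always means two
#' H2-tagging alleles. Panel SNPs absent from the VCF become missing
#' columns; sites whose panel polarity is \code{ref_tags_H2} are flipped
#' (g -> 2 - g).
#'
#' @param vcf_path VCF file
#' @param panel tag-SNP panel data.frame (see \code{\link{read_tag_panel}})
#' @return integer matrix (samples x panel SNPs) with entries 0/1/2/NA
#' @export
load_genotypes <- function(vcf_path, panel) {
  v <- vcf_genotype_matrix(vcf_path)
  key_vcf <- paste0(v$contig, ":", v$positions)
  key_panel <- paste0(panel$contig, ":", panel$pos)
  idx <- match(key_panel, key_vcf)
  if (all(is.na(idx))) stop("no panel SNP found in the VCF")
  n <- nrow(v$genotypes)
  out <- matrix(NA_integer_, nrow = n, ncol = nrow(panel),
                dimnames = list(rownames(v$genotypes), key_panel))
  found <- !is.na(idx)
  out[, found] <- v$genotypes[, idx[found], drop = FALSE]
  flip <- panel$polarity == "ref_tags_H2"
  if (any(flip)) out[, flip] <- 2L - out[, flip, drop = FALSE]
  out
}
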