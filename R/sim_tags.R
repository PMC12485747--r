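#' Simulate tag-SNP genotypes for a cohort
#'
#' Tag SNPs are biallelic markers in perfect linkage with the inversion
#' state: the alternate allele tags H2. With zero error an individual's
#' genotype at every panel SNP equals its count of H2 haplotypes; each
#' haplotype's tag allele flips independently with probability
#' \code{tag_error_rate}, emulating genotyping error and imperfect tagging.
#'
#' @param truth a \code{\link{draw_cohort}} result
#' @param config the \code{\link{sim_config}} used to draw it
#' @return list with \code{genotypes} (integer matrix, samples x SNPs, values
#'   0/1/2), \code{panel} (data.frame: contig, pos (1-based), tag_allele,
#'   polarity), and \code{positions} (0-based site positions)
#' @export
simulate_tag_genotypes <- function(truth, config) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  m <- config$n_tag_snps
  loc <- config$locus
  pos0 <- sort(sample.int(loc$end - loc$start, m)) + loc$start - 1L

  is_h2 <- cbind(parse_haplotype(truth$individuals$hap1)$inversion == "H2",
                 parse_haplotype(truth$individuals$hap2)$inversion == "H2")
  g <- matrix(0L, nrow = n, ncol = m,
              dimnames = list(truth$individuals$sample_id,
                              paste0("tag", seq_len(m))))
  for (h in 1:2) {
    allele <- matrix(rep(is_h2[, h], m), nrow = n)
    if (config$tag_error_rate > 0) {
      flip <- matrix(stats::runif(n * m) < config$tag_error_rate, nrow = n)
      allele <- xor(allele, flip)
    }
    g <- g + allele
  }
  panel <- data.frame(
    contig = loc$contig,
    pos = pos0 + 1L,
    tag_allele = "ALT",
    polarity = "alt_tags_H2",
    stringsAsFactors = FALSE
  )
  list(genotypes = g, panel = panel, positions = pos0)
}

#' Write a tag-SNP panel TSV
#'
#' @param panel data.frame with columns contig, pos, tag_allele, polarity
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_tag_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tag-SNP panel TSV
#'
#' @param path TSV with columns contig, pos (1-based), tag_allele, polarity
#'   (\code{alt_tags_H2} or \code{ref_tags_H2})
#' @return validated panel data.frame
#' @export
read_tag_panel <- function(path) {
  panel <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("contig", "pos", "tag_allele", "polarity")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(panel[, c("contig", "pos")])) {
    stop("panel positions must be unique")
  }
  if (nrow(panel) == 0L) stop("panel is empty")
  if (!all(panel$polarity %in% c("alt_tags_H2", "ref_tags_H2"))) {
    stop("polarity must be alt_tags_H2 or ref_tags_H2")
  }
  panel
}
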