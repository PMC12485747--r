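#' Simulate inversion-interior SNP genotypes with divergent haplotype pools
#'
#' Because recombination between inversion orientations is suppressed, SNPs
#' inside the inversion fall into two divergent pools: every site has an
#' H1-pool and an H2-pool allele frequency differing by
#' \code{haplotype_divergence}. Per-window PCA of such a matrix separates
#' H1/H1, H1/H2 and H2/H2 individuals. Implanted recombination tracts make
#' the carrying haplotype draw its alleles from the donor pool inside the
#' tract, emulating double crossovers / long gene-conversion events.
#'
#' Each tract is implanted on exactly one haplotype: the first of the
#' individual's two haplotypes whose orientation differs from the donor
#' state (a tract matching both haplotypes' state would be invisible).
#'
#' @param truth a \code{\link{draw_cohort}} result
#' @param config the \code{\link{sim_config}} used
#' @return list with \code{genotypes} (integer matrix, samples x sites,
#'   0/1/2), \code{positions} (0-based), \code{contig}, and the per-site pool
#'   frequencies \code{p_h1}, \code{p_h2}
#' @export
simulate_inversion_snps <- function(truth, config) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(config$seed + 3L)
  reg <- config$inversion_interior
  width <- reg$end - reg$start
  m <- max(2L, round(config$snp_density * width / 1000))
  pos0 <- sort(sample.int(width - 1L, m)) + reg$start
  d <- config$haplotype_divergence

  base <- stats::runif(m, 0, 1 - d)
  hi_is_h2 <- stats::runif(m) < 0.5
  p_h1 <- ifelse(hi_is_h2, base, base + d)
  p_h2 <- ifelse(hi_is_h2, base + d, base)

  ind <- truth$individuals
  n <- nrow(ind)
  states <- cbind(parse_haplotype(ind$hap1)$inversion,
                  parse_haplotype(ind$hap2)$inversion)
  g <- matrix(0L, nrow = n, ncol = m,
              dimnames = list(ind$sample_id, paste0("snp", seq_len(m))))
  for (h in 1:2) {
    # per individual x site pool frequency for this haplotype
    f <- matrix(p_h1, nrow = n, ncol = m, byrow = TRUE)
    is_h2 <- states[, h] == "H2"
    f[is_h2, ] <- matrix(p_h2, nrow = sum(is_h2), ncol = m, byrow = TRUE)
    for (tr in truth$tracts) {
      i <- tr$individual
      carrier <- which(states[i, ] != tr$donor)[1]
      if (is.na(carrier) || carrier != h) next
      in_tract <- pos0 >= tr$start & pos0 < tr$end
      donor_p <- if (tr$donor == "H2") p_h2 else p_h1
      f[i, in_tract] <- donor_p[in_tract]
    }
    g <- g + (matrix(stats::runif(n * m), nrow = n) < f)
  }
  list(genotypes = g, positions = pos0, contig = reg$contig,
       p_h1 = p_h1, p_h2 = p_h2)
}
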