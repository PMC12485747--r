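#' Default sector definitions for the 17q21.31 locus (GRCh38)
#'
#' Genomic intervals (0-based half-open) over which duplicon copy numbers are
#' read: the unique regions of the alpha and beta KANSL1 duplicons, the two
#' NSF reference copies, and a large copy-number-invariant control region
#' used for depth normalization.
#'
#' @return data.frame with columns name, contig, start, end
#' @export
sector_defs <- function() {
  data.frame(
    name   = c("alpha", "beta", "nsf_1", "nsf_2", "control"),
    contig = "chr17",
    start  = c(46143000L, 46095000L, 46336376L, 46564311L, 42800000L),
    end    = c(46238000L, 46123000L, 46489410L, 46707123L, 46000000L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the simulator: cohort size and structural-haplotype
#' frequencies, the tag-SNP panel, sequencing depth, the inversion-interior
#' SNP model (two divergent haplotype pools), implanted recombination tracts,
#' and an optional temporal frequency trajectory for time-stamped samples.
#' Defaults emulate the study conditions: present-day European frequencies of
#' the four simplified categories, a 1271-SNP tag panel, 30x coverage, and
#' strongly divergent H1/H2 SNP pools inside the inversion.
#'
#' All coordinates are 0-based half-open internally; VCF output is written
#' 1-based per the standard.
#'
#' @param n_individuals cohort size
#' @param haplotype_freqs named numeric vector of structural-haplotype
#'   frequencies (must sum to 1 within 1e-9)
#' @param n_tag_snps number of inversion tag SNPs on the simulated panel
#' @param tag_error_rate per-site, per-haplotype probability that a tag
#'   allele is discordant with the inversion state
#' @param mean_coverage expected reads per base for a diploid (CN 2) region
#' @param locus list(contig, start, end): the region over which depth is
#'   simulated; must contain all sectors
#' @param inversion_interior list(contig, start, end): the non-duplicated
#'   inversion interior over which SNPs are simulated
#' @param snp_density SNPs per kb inside \code{inversion_interior}
#' @param haplotype_divergence per-site allele-frequency difference between
#'   the H1 and H2 haplotype pools, in (0, 1]
#' @param nsf_extra_copies integer vector (recycled over individuals) of
#'   extra diploid NSF copies beyond the reference baseline of 4
#' @param recomb_tracts list of tracts, each
#'   list(individual =, start =, end =, donor = "H1"|"H2"): within the tract
#'   the carrying haplotype's alleles come from the donor pool
#' @param trajectory NULL, or list(t_range = c(young, old) years BP,
#'   freq_present, freq_past = named frequency vectors over the simplified
#'   categories). Sample ages are uniform on t_range and haplotypes are drawn
#'   from the multinomial-logit interpolation between the two endpoints.
#' @param seed integer seed; a fixed seed makes all outputs byte-identical
#' @return object of class \code{sim_config}
#' @export
sim_config <- function(n_individuals = 200L,
                       haplotype_freqs = default_haplotype_freqs(),
                       n_tag_snps = 1271L,
                       tag_error_rate = 0.01,
                       mean_coverage = 30,
                       locus = list(contig = "chr17",
                                    start = 42800000L, end = 46921902L),
                       inversion_interior = list(contig = "chr17",
                                                 start = 45600000L,
                                                 end = 46100000L),
                       snp_density = 3,
                       haplotype_divergence = 0.8,
                       nsf_extra_copies = 0L,
                       recomb_tracts = list(),
                       trajectory = NULL,
                       seed = 1L) {
  if (abs(sum(haplotype_freqs) - 1) > 1e-9) {
    stop("haplotype_freqs must sum to 1 (got ", sum(haplotype_freqs), ")")
  }
  if (any(haplotype_freqs < 0)) stop("haplotype_freqs must be nonnegative")
  parse_haplotype(names(haplotype_freqs))  # validates labels
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  if (n_tag_snps < 1L) stop("n_tag_snps must be >= 1")
  if (tag_error_rate < 0 || tag_error_rate > 1) stop("tag_error_rate in [0,1]")
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  if (haplotype_divergence < 0 || haplotype_divergence > 1) {
    stop("haplotype_divergence must lie in [0, 1]")
  }
  for (tr in recomb_tracts) {
    if (tr$start >= tr$end) stop("tract interval empty")
    if (tr$start < inversion_interior$start || tr$end > inversion_interior$end) {
      stop("recombination tract outside the inversion interior")
    }
    if (tr$individual < 1L || tr$individual > n_individuals) {
      stop("tract individual index out of range")
    }
    if (!tr$donor %in% c("H1", "H2")) stop("tract donor must be H1 or H2")
  }
  if (!is.null(trajectory)) {
    stopifnot(length(trajectory$t_range) == 2L,
              trajectory$t_range[1] < trajectory$t_range[2])
    for (f in list(trajectory$freq_present, trajectory$freq_past)) {
      if (abs(sum(f) - 1) > 1e-9) stop("trajectory frequencies must sum to 1")
    }
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    haplotype_freqs = haplotype_freqs,
    n_tag_snps = as.integer(n_tag_snps),
    tag_error_rate = tag_error_rate,
    mean_coverage = mean_coverage,
    locus = locus,
    inversion_interior = inversion_interior,
    snp_density = snp_density,
    haplotype_divergence = haplotype_divergence,
    nsf_extra_copies = as.integer(nsf_extra_copies),
    recomb_tracts = recomb_tracts,
    trajectory = trajectory,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default structural-haplotype frequencies
#'
#' Present-day European frequencies of the four simplified architectures
#' (direct unduplicated, direct duplicated, inverted unduplicated, inverted
#' duplicated), consistent with the modern endpoint of the fitted temporal
#' trajectory.
#'
#' @return named numeric vector summing to 1
#' @export
default_haplotype_freqs <- function() {
  stats::setNames(c(0.47, 0.29, 0.03, 0.21),
                  c(format_haplotype("H1", 1), format_haplotype("H1", 2),
                    format_haplotype("H2", 1), format_haplotype("H2", 2)))
}

#' Default temporal trajectory of the simplified categories
#'
#' Endpoint frequencies over the past 12 ky: the direct unduplicated
#' haplotype falls from 90% to 47% while both duplication-carrying classes
#' rise (1% to 29% direct, 7% to 21% inverted), so the pooled
#' duplication-carrying frequency climbs from 8% to 50%.
#'
#' @return list(t_range, freq_present, freq_past) suitable for
#'   \code{\link{sim_config}}
#' @export
default_trajectory <- function() {
  cats <- haplotype_categories()
  list(
    t_range = c(0, 12000),
    freq_present = stats::setNames(c(0.47, 0.29, 0.03, 0.21), cats),
    freq_past    = stats::setNames(c(0.90, 0.01, 0.02, 0.07), cats)
  )
}

#' Read a simulator configuration from YAML
#'
#' The YAML file mirrors \code{\link{sim_config}} field for field; absent
#' fields take the defaults.
#'
#' @param path YAML file path
#' @return \code{sim_config} object
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$haplotype_freqs)) {
    raw$haplotype_freqs <- unlist(raw$haplotype_freqs)
  }
  do.call(sim_config, raw)
}
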