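#!/usr/bin/env Rscript
# Simulate the study cohort: 300 diploid individuals drawn from present-day
# European structural-haplotype frequencies, with a 500-SNP inversion tag
# panel (1% tagging error), Poisson read depth at 30x over the full locus,
# and SNPs across the non-duplicated inversion interior. Writes the standard
# input formats the pipeline consumes (VCF, tag-panel TSV, metadata TSV) and
# the ground truth used by later steps to score recovery. Bulky per-sample
# depth goes to scratch/ as an R object; summary tables go to results/.

suppressMessages(library(structhap))
dir.create("results", showWarnings = FALSE)
dir.create("scratch/cohort", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_individuals = 300L, n_tag_snps = 500L,
                  tag_error_rate = 0.01, mean_coverage = 30, seed = 1234L)
saveRDS(cfg, "scratch/cohort/config.rds")

truth <- draw_cohort(cfg)
write_cohort_truth(truth, "results")

tags <- simulate_tag_genotypes(truth, cfg)
write_tag_panel(tags$panel, "results/tag_panel.tsv")

snps <- simulate_inversion_snps(truth, cfg)

# one VCF carrying the tag panel (INFO flag TAG) plus the interior SNPs
geno <- cbind(tags$genotypes, snps$genotypes)
pos <- c(tags$positions, snps$positions)
is_tag <- c(rep(TRUE, ncol(tags$genotypes)), rep(FALSE, ncol(snps$genotypes)))
ord <- order(pos)
write_vcf(geno[, ord], pos[ord], cfg$locus$contig,
          "scratch/cohort/cohort.vcf", tag = is_tag[ord])

depth <- simulate_depth(truth, sector_defs(), cfg)
saveRDS(depth, "scratch/cohort/depth.rds")
write_bedgraph(depth_bedgraph(depth, 1L), "scratch/cohort/S0001.bedgraph")

message("cohort: ", nrow(truth$individuals), " individuals, ",
        ncol(geno), " variant sites (", sum(is_tag), " tag SNPs)")
message("haplotype counts:")
print(table(c(truth$individuals$hap1, truth$individuals$hap2)))
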