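#!/usr/bin/env Rscript
# Inversion genotyping: load the tag-panel genotypes from the cohort VCF and
# assign H1/H1, H1/H2 or H2/H2 by Euclidean distance to the expected 0/1/2
# vectors. Scores the calls against the simulated truth.

suppressMessages(library(structhap))

panel <- read_tag_panel("results/tag_panel.tsv")
g <- load_genotypes("scratch/cohort/cohort.vcf", panel)
calls <- genotype_inversion(g, min_call_fraction = 0.5)
write_inversion_calls(calls, "results/inversion_calls.tsv")

truth <- utils::read.table("results/truth.tsv", header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
h2 <- (parse_haplotype(truth$hap1)$inversion == "H2") +
  (parse_haplotype(truth$hap2)$inversion == "H2")
true_gt <- c("H1/H1", "H1/H2", "H2/H2")[h2 + 1L]

message("inversion genotype calls:")
print(table(calls$genotype))
message(sprintf("accuracy vs truth: %.1f%% (%d no-calls)",
                100 * mean(calls$genotype == true_gt),
                sum(calls$genotype == "no-call")))
message(sprintf("median call margin: %.1f distance units",
                stats::median(calls$margin, na.rm = TRUE)))
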