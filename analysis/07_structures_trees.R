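#!/usr/bin/env Rscript
# Structure clustering and dating utilities on synthetic inputs. Builds a
# synthetic panel of block decompositions emulating the locus architecture
# (shared backbone blocks, clade-specific duplicon blocks with varying copy
# number, strand-flipped reports), then: bundle filtering, structure
# grouping, length-weighted Jaccard distances, a neighbor-joining summary
# tree. Separately, nine windowed phylogenies (the three right-most sharing
# a topology, emulating suppressed recombination next to the duplication)
# are compared by Robinson-Foulds distance to pick high-LD windows, and a
# clock tree is calibrated with the 7.74 Ma human-chimpanzee split.

suppressMessages({
  library(structhap)
  library(ape)
})
dir.create("results", showWarnings = FALSE)
set.seed(99L)

# --- synthetic block decompositions (labelled synthetic throughout) --------
backbone <- data.frame(
  block_id = c("flank_L", "spacer_L", "inv_body", "spacer_R", "flank_R"),
  orientation = c("+", "+", "+", "+", "+"),
  length = c(80, 15, 300, 20, 90) * 1000)
inv_backbone <- backbone
inv_backbone$orientation[inv_backbone$block_id == "inv_body"] <- "-"
arch <- list(
  h1b1 = rbind(backbone,
               data.frame(block_id = "kansl1_beta", orientation = "+",
                          length = 60000)),
  h1b2 = rbind(backbone,
               data.frame(block_id = rep("kansl1_beta", 2), orientation = "+",
                          length = 60000)),
  h2a1 = rbind(inv_backbone,
               data.frame(block_id = "kansl1_alpha", orientation = "-",
                          length = 55000)),
  h2a2 = rbind(inv_backbone,
               data.frame(block_id = rep("kansl1_alpha", 2),
                          orientation = "-", length = 55000)))
counts <- c(h1b1 = 18L, h1b2 = 6L, h2a1 = 4L, h2a2 = 8L)
decomp <- do.call(rbind, unlist(lapply(names(arch), function(a) {
  lapply(seq_len(counts[[a]]), function(i) {
    b <- arch[[a]]
    # half the haplotypes are reported on the opposite strand
    if (i %% 2 == 0) {
      b <- b[rev(seq_len(nrow(b))), ]
      b$orientation <- ifelse(b$orientation == "+", "-", "+")
    }
    # plus an occasional private short block that filtering must drop
    if (i == 1) {
      b <- rbind(b, data.frame(block_id = paste0("priv_", a),
                               orientation = "+", length = 8000))
    }
    data.frame(haplotype = sprintf("%s_%02d", a, i),
               rank = seq_len(nrow(b)), b)
  })
}), recursive = FALSE))

filt <- filter_bundles(decomp, min_length_quantile = 0.25)
message(sprintf("bundle filter: %d -> %d block records (min length %.0f bp)",
                nrow(decomp), nrow(filt), attr(filt, "min_length")))
groups <- group_structures(filt)
message(sprintf("%d unique structures among %d haplotypes",
                nrow(groups$groups), length(groups$assignment)))
utils::write.table(groups$groups, "results/structure_groups.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

jac <- jaccard_matrix(filt, groups)
utils::write.table(round(jac$dist, 4), "results/structure_jaccard.tsv",
                   sep = "\t", quote = FALSE)
nj <- nj_tree(jac$dist)
write.tree(nj, "results/structures_nj.nwk")
summ <- summary_structures(jac, h = 0.1)
message(sprintf("%d summary structures at dendrogram cut 0.1",
                length(unique(summ))))

# --- windowed-tree LD selection and calibration ----------------------------
shared <- rcoal(20, tip.label = sprintf("hap%02d", 1:20))
windows <- c(lapply(1:6, function(i)
               rcoal(20, tip.label = sprintf("hap%02d", 1:20))),
             lapply(1:3, function(i) shared))
rf <- rf_matrix(windows)
utils::write.table(rf, "results/window_rf_matrix.tsv", sep = "\t",
                   quote = FALSE)
sel <- select_ld_windows(rf, k = 1)
message("windows in highest topological LD with the right-most window: ",
        paste(sel, collapse = ", "))
win_bed <- data.frame(contig = "chr17",
                      start = 45600000L + (sel - 1L) * 50000L,
                      end = 45600000L + sel * 50000L)
utils::write.table(win_bed, "results/selected_windows.bed", sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)

# clock tree with two outgroup tips; calibrate the root split at 7.74 Ma
ingroup <- rcoal(10, tip.label = sprintf("hum%02d", 1:10))
ingroup$edge.length <- ingroup$edge.length /
  max(branching.times(ingroup)) * 0.4
tree <- read.tree(text = paste0(
  "(", sub(";", "", write.tree(ingroup)), ":0.6,",
  "(chimp1:0.55,chimp2:0.55):0.45);"))
cal <- calibrate_node_ages(tree, tree$tip.label, age = 7.74)
ages <- data.frame(node = names(cal$ages), age_ma = round(cal$ages, 4))
utils::write.table(ages, "results/calibrated_node_ages.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
root_id <- as.character(length(tree$tip.label) + 1L)
ingroup_mrca <- as.character(getMRCA(tree, sprintf("hum%02d", 1:10)))
message(sprintf(
  "root (human-chimp split) calibrated at %.2f Ma; ingroup MRCA %.2f Ma",
  cal$ages[root_id], cal$ages[ingroup_mrca]))
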