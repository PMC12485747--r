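# structhap

Inference of complex structural haplotypes at inversion +
segmental-duplication loci — modelled on human 17q21.31 — from short-read
derived data, for population geneticists working with cohort VCFs,
read-depth tracks, time-stamped (ancient DNA) samples and
assembly-derived block decompositions.

The 17q21.31 locus carries a ~970 kb inversion with two deeply diverged
orientation clades (direct H1, inverted H2), clade-specific partial
duplications of *KANSL1* (β on H1, α on H2) and copy-number variation of
*NSF*. Short reads cannot assemble these structures, but they can be
inferred: tag SNPs in near-perfect LD with the orientation give the
inversion genotype; normalized read depth gives duplicon copy numbers; and
the two integrate into a diploid structural genotype such as
`H1.β1 / H2.α2`.

## What the package computes

* **Inversion genotyping** — code panel genotypes 0/1/2, assign each
  individual the genotype `g ∈ {H1/H1, H1/H2, H2/H2}` minimizing the
  Euclidean distance ‖x − e_g‖ to the expected vectors e = all-0 / all-1 /
  all-2, restricted to non-missing sites (`genotype_inversion`).
* **Copy number from depth** — 1,000 bp windows sliding by 100 bp,
  normalized to a copy-number-invariant control region; sector CN =
  2 × mean normalized depth (α, β), NSF CN = 2 × (sum of means over the
  two reference copies); QC caps at CN 20 (*KANSL1*) and 50 (*NSF*)
  (`window_depth`, `normalize_depth`, `sector_cn`, `nsf_cn`).
* **Complex genotypes** — nearest entry of an explicit expectation table
  (L1 distance on integer CNs), ties broken by a rarity ranking; trio
  validation by Mendelian transmission (`integrate_genotype`,
  `trio_check`).
* **Recombination scan** — per-window PC1 of the centered genotype matrix,
  per-genotype 5–95% envelopes, runs of ≥ 2 outlier windows reassigned and
  classified single vs double (`scan_recomb`).
* **Frequency trajectories** — multinomial logistic regression of the four
  simplified classes (H1.β1, H1.β2+, H2.α1, H2.α2+) on time in kiloyears
  BP, fitted by the package's own Newton solver; predicted trajectories and
  fold changes with delta-method intervals (`fit_multinomial`,
  `fold_change`).
* **Structure clustering & dating** — singleton/length-quantile bundle
  filtering, strand-canonical structure grouping, length-weighted Jaccard
  distances, neighbor joining, Robinson–Foulds window comparison and
  split-time calibration (18.13 / 7.74 Ma) (`filter_bundles`,
  `jaccard_matrix`, `nj_tree`, `rf_matrix`, `calibrate_node_ages`).
* **Synthetic cohorts** — a generator with known truth (haplotype draws,
  tag panels, Poisson depth, divergent SNP pools, implanted recombinant
  tracts, temporal sampling) emitting standard formats (VCF, bedGraph,
  TSV), so the whole pipeline is testable without external data
  (`sim_config`, `draw_cohort`, `simulate_*`).

## Worked example

The numbered scripts under `analysis/` run the full pipeline on a simulated
300-individual cohort (run them in order from the repository root; bulky
intermediates go to `scratch/`, tables to `results/`):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_genotype_inversion.R
Rscript analysis/03_copy_number.R
Rscript analysis/04_complex_genotypes.R
Rscript analysis/05_recombination_scan.R
Rscript analysis/06_trajectory.R
Rscript analysis/07_structures_trees.R
```

Step 02 genotypes the inversion from the cohort VCF:

```
inversion genotype calls:
H1/H1 H1/H2 H2/H2
  172   112    16
accuracy vs truth: 100.0% (0 no-calls)
```

Step 04 integrates calls and copy numbers into diploid structural
genotypes and tabulates the simplified haplotype frequencies
(2n = 600 haplotypes):

```
diploid genotype recovery: 100.0% of 300 individuals
  category Freq  frequency
1    H1.β1  266 0.44333333
2   H1.β2+  190 0.31666667
3    H2.α1   26 0.04333333
4   H2.α2+  118 0.19666667
```

Step 05 implants six exchange tracts and re-detects them blind; e.g. a
110 kb interior tract in heterozygote S0008 is recovered with exact
breakpoints and classified as a double event, while a tract touching the
region boundary in S0015 is classified single:

```
  sample    start      end length_bp  class  from    to
2  S0008 45650000 45760000    110000 double H1/H2 H1/H1
6  S0015 45600000 45700000    100000 single H1/H2 H1/H1
```

Step 06 fits the temporal model to 1,252 time-stamped haplotypes simulated
over the past 12 ky (duplication-carrying classes rising from 8% to 50%):

```
duplication-carrying classes: 0.070 at 12 kya -> 0.534 today, fold 7.61 (95% CI 5.18-11.17)
```

i.e. the fitted frequency of *KANSL1*-duplication haplotypes at 12 kya, the
fitted frequency today, and their ratio with its delta-method interval
(simulated truth: 6.25-fold).

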