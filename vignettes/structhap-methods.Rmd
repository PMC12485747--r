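---
title: "Methods: inferring structural haplotypes at an inversion + segmental-duplication locus"
author: "structhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring structural haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structhap)
```

# The locus and the inference problem

Human 17q21.31 carries a ~970 kb inversion polymorphism with two deeply
diverged orientation clades, the direct H1 and the inverted (ancestral) H2.
Each clade accumulates its own partial duplications of *KANSL1* — the β
duplicon segregates exclusively on H1 backgrounds and the α duplicon
exclusively on H2 — and both carry copy-number variation of *NSF*. A
*structural haplotype* is therefore a pair (orientation clade, duplicon copy
count), written `H1.β1`, `H1.β2`, `H2.α2`, and so on (suffix 1 =
unduplicated). Short reads cannot assemble these structures, but three
signals recover them indirectly:

1. **Tag SNPs.** Suppressed recombination between the clades keeps a panel
   of SNPs in essentially perfect LD with orientation. Coding genotypes 0/1/2
   (alternate-allele count, with polarity normalized so 2 = two H2-tagging
   alleles), an individual's observed panel vector is compared by Euclidean
   distance with the three expected vectors — all-0 (H1/H1), all-1 (H1/H2),
   all-2 (H2/H2) — and assigned to the argmin.
2. **Read depth.** Sequencing depth scales with local copy number. Depth is
   averaged in 1,000 bp windows sliding by 100 bp, normalized per sample to
   the mean depth of a large copy-number-invariant control region
   (chr17:42.80–46.00 Mb), so normalized depth 1.0 ≡ diploid CN 2. Diploid
   copy number of the α (chr17:46.143–46.238 Mb) and β (chr17:46.095–46.123
   Mb) unique regions is twice the mean normalized depth of overlapping
   windows; for *NSF*, where the reference already has two copies, CN is
   twice the *sum* of the means over the two reference copies (baseline 4).
3. **Integration.** The inversion call and the integer α/β copy numbers
   jointly identify the diploid haplotype pair through an explicit
   expectation table (β CN = 2 + extra β copies on the H1 side, α likewise
   on H2).

Downstream of genotyping, the package models three population-level
phenomena: recombination between clades inside the inversion (sliding-window
PCA), temporal change of haplotype frequencies in time-stamped cohorts
(multinomial logistic regression), and clustering/dating of assembled
haplotype structures (weighted Jaccard + neighbor joining, Robinson–Foulds
tree comparison, split-time calibration).

# Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_size` / `step` | 1000 / 100 | bp | depth windowing |
| control region | chr17:42.8–46.0 Mb | — | depth normalization |
| `cn_max_kansl1` / `cn_max_nsf` | 20 / 50 | copies | QC caps; larger estimates are artifacts |
| `min_call_fraction` | 0.5 | — | minimum usable panel fraction for an inversion call |
| scan `window` | 10,000 | bp | non-overlapping PCA windows |
| scan `low` / `high` | 5 / 95 | percentile | per-genotype PC1 envelopes |
| scan `min_run` | 2 | windows | shortest reassignable outlier run |
| trajectory time scale | kiloyears BP | — | positive slope = rising toward the present |
| bundle `min_length_quantile` | 0.25 | — | drops the shortest quartile of blocks |
| calibration ages | 18.13 / 7.74 | Ma | orangutan and human–chimpanzee splits |

# The synthetic cohort generator

Every stage is exercised end to end on cohorts with known truth. The
generator emulates, at the level the pipeline consumes:

* **Haplotype draws** — two i.i.d. draws per individual from configured
  frequencies. Defaults are present-day European frequencies of the four
  simplified classes (H1.β1 0.47, H1.β2 0.29, H2.α1 0.03, H2.α2 0.21),
  matching the modern endpoint of the default trajectory.
* **Tag genotypes** — genotype = H2-count at every panel SNP, each
  haplotype's allele flipping independently with error ε (default 0.01);
  the default panel size is 1271 SNPs.
* **Depth** — Poisson counts per 100 bp tile with mean `coverage × CN/2 ×
  width`, at the real GRCh38 sector coordinates; the control region is CN 2
  by construction. Simulating at tile rather than read level is deliberate:
  the estimator only ever sees windowed means, so read-level simulation
  would add cost without exercising more code.
* **Inversion-interior SNPs** — two divergent allele-frequency pools. Each
  site gets a base frequency and the H1/H2 pools differ by exactly the
  configured divergence (default 0.8), with the high pool chosen at random
  per site. SNP density defaults to 3/kb, typical of cohort VCFs at this
  locus — roughly 30 variants per 10 kb scan window, enough for a stable
  per-window PC1.
* **Recombinant tracts** — an interval, a donor clade and a carrier
  individual; alleles on the carrying haplotype (the first whose orientation
  differs from the donor, matching a double crossover on one chromosome)
  are drawn from the donor pool inside the tract.
* **Temporal sampling** — ages uniform over the configured range and
  category draws from a two-endpoint multinomial-logit trajectory (log-odds
  linear in time), so fitted coefficients can be compared with exact truth.

What the generator does **not** emulate: GC and mapping bias, batch effects
across cohorts, linkage disequilibrium decay within a pool, relatedness
(outside the explicit trio generator), imputation uncertainty in ancient
genotypes, and reference bias. Green tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
robustness to every artifact of real short-read data.

# The recombination scan, made explicit

Per non-overlapping 10 kb window, PCA is run on the column-centered (not
variance-scaled) genotype matrix of that window's variable biallelic sites.
Two conventions make per-window scores comparable:

* **Orientation.** A principal component's sign is arbitrary, so each
  window's PC1 is oriented so the H2/H2 group mean is ≥ the H1/H1 group
  mean (falling back to the heterozygote mean when a homozygote class is
  absent). Without a fixed rule, runs of scores across windows would be
  meaningless.
* **Ambiguity.** Per window and genotype group we record mean, median and
  the 5th/95th percentiles of PC1. A window where any two groups'
  [5th, 95th] envelopes intersect — or with fewer than `min_variants`
  variable sites, or zero variance — is flagged ambiguous and excluded.

A sample's window is a candidate outlier when its PC1 exits its own group's
envelope *toward* another group: heterozygotes below their 5th percentile
(toward H1/H1) or above their 95th (toward H2/H2); homozygotes when they
cross the heterozygote envelope's near boundary. Only maximal runs of ≥ 2
adjacent candidate windows with a common target are considered, and runs
separated by a single ambiguous window are merged. A run is *confirmed* only
if its mean PC1 lies closer to the target group's per-window medians than to
its own group's. This last condition is what keeps the scan specific: by
construction ~5% of scores per group exit the envelope by chance, and with
~20 analyzed windows per sample, percentile-exit alone would fabricate about
3 two-window "events" per 100 samples. A chance excursion hovers just
outside its own envelope, far from the other cluster; a genuine exchanged
tract moves all the way. The confirmation step encodes that distinction and
brings the null rate to ≤ 0.5 events per 100 samples, which the acceptance
suite verifies on null cohorts.

Confirmed runs flanked on both sides by concordant windows are *double*
events (two crossovers or a long gene-conversion tract — the data cannot
distinguish these); runs touching a boundary of the analyzed region are
*single* events. Manual curation in the original analysis is replaced here
by these machine-readable filters plus a per-event report.

# The trajectory model

Each resolved individual contributes its two haplotypes as independent
observations (a deliberate simplification — no within-individual
correlation term). For categories *k* with reference category 1,

$$\log\frac{p_k(s)}{p_1(s)} = a_k + b_k s, \qquad s = -\text{age}/1000,$$

so *s* is time in kiloyears oriented toward the present and a positive
slope means a rising frequency. The likelihood is maximized by a damped
Newton iteration written in the package — likelihood, gradient and Hessian
are part of the tested surface — with step halving to guarantee ascent,
convergence at a log-likelihood change < 1e-8 and a hard cap of 100
iterations (non-convergence is reported on the model object, never silently
accepted). Standard errors come from the inverse observed information;
fold changes of summed category frequencies between two times carry
delta-method intervals on the log scale. Degenerate inputs are handled
explicitly: a constant time covariate switches to the closed-form
intercept-only fit (slopes exactly 0); a category absent from the data is
pinned at frequency 0 with a warning; single-category data is reported as
complete separation with no finite estimates. An independent implementation
(`nnet::multinom`) is used in the test suite as a cross-check oracle, never
as the estimator.

# Structure clustering and tree utilities

**Bundle filtering.** Blocks private to a single haplotype are removed
first; then blocks whose representative (median) length falls below the
0.25 quantile of the remaining blocks' lengths. The resolved threshold is
stored on the result and reused verbatim when the filter is re-applied —
mirroring how such cutoffs are frozen as concrete numbers (e.g. "< 23 kb")
once derived from a dataset — which makes the filter idempotent; a
recomputed quantile would otherwise chew further into the distribution on
every pass.

**Grouping and distances.** A structure is the ordered sequence of
(block id, orientation) pairs, canonicalized against strand by taking the
lexicographic minimum of the sequence and its reverse-complement reading.
Distance between structures is a length-weighted multiset Jaccard:
$d(A,B) = 1 - \sum_b \ell_b \min(c_{Ab}, c_{Bb}) / \sum_b \ell_b
\max(c_{Ab}, c_{Bb})$. This block-level distance stands in for a base-level
graph similarity; it ignores sequence divergence *within* shared blocks, so
it can only under-estimate distances between structures that share their
block inventory — the direction of error to keep in mind when reading the
dendrogram. Summary structures are a height cut on the average-linkage
dendrogram of this matrix; the cut height is configuration, as no universal
threshold exists.

**Neighbor joining and Robinson–Foulds.** Both are implemented in the
package because the pipeline needs contracts the standard libraries leave
unspecified: NJ ties on the Q criterion break toward the lexicographically
lowest taxon-index pair and negative branch lengths clamp to zero (count
recorded); RF is the plain symmetric difference of nontrivial bipartitions
(unrooted, unnormalized, polytomies allowed), with a normalized variant
dividing by 2(n−3). The test suite checks NJ against exact recovery of
additive matrices and `ape::nj`, and RF against brute-force bipartition
enumeration (edge deletion + flooding) — dual routes kept strictly
separate. Window selection against the right-most (anchor) window sorts by
RF distance with ties broken toward the genomically nearer window; an
ordination of the RF matrix, where one is wanted, is classical MDS.

**Calibration.** For an approximately clock-like rooted tree, each node's
depth is its tip-count-weighted mean distance to descendant tips; ages
scale linearly so the calibration node (MRCA of a named clade) hits its
assigned age exactly — 18.13 Ma for the orangutan split or 7.74 Ma for the
human–chimpanzee split in the great-ape setting. Ages are invariant to
rescaling all branch lengths; deviation from a clock beyond a 10% relative
spread in root-to-tip depths triggers a warning rather than an error.

# Numerical and tie-breaking conventions

* Coordinates are 0-based half-open internally; VCF is written 1-based.
* Integer copy-number calls round half away from zero (2.5 → 3); no
  rounding rule is canonical here, so the choice is stated rather than
  implied.
* Inversion-call ties (two expected vectors exactly equidistant) are
  no-calls: a tie carries no information.
* Copy-number ties in the integrator break by rarity rank (duplicon copy
  suffix): between equally fitting pairs, the pair whose rarer member is
  commoner wins, so β CN 4 on H1/H1 resolves to β2/β2 rather than β1/β3.
* Missing panel SNPs restrict both the observed and expected vectors to
  the non-missing sites; distances are also reported divided by √n for
  cross-sample comparability.
* Time bins are half-open `[kw, (k+1)w)` in years BP.

# Problem sizes

The test and acceptance suites run at sizes chosen to give stable
statistics on a single core in seconds: cohorts of 200 individuals (500 tag
SNPs, ε = 0.01, coverage 30×) for genotyping recovery; 100 trios for
Mendelian validation; five cohorts of 200 with three implanted 40–60 kb
tracts each for scan sensitivity, plus a 200-sample null cohort; 100
replicate fits of 600 haplotype observations for trajectory coverage and
fold-change calibration; 200 random tree pairs (≤ 7 leaves) against the
brute-force RF oracle; additive matrices of 4–8 taxa for NJ. The depth
simulations use a compact sector layout with the same relative arrangement
as the real locus for unit tests, and the real GRCh38 coordinates in the
analysis scripts.

# Known limitations

* *NSF* duplications are reported as diploid totals only; short-read depth
  cannot phase them onto haplotypes, so no γ suffixes are assigned.
* The scan cannot separate double crossover from long gene conversion, and
  its envelope statistics assume exchanged tracts are rare; a cohort where
  a substantial fraction of one genotype group carries the same tract
  would contaminate the percentile envelopes.
* The trajectory model pools populations by default and treats haplotypes
  as independent; it estimates frequency change, not selection
  coefficients.
* The block-level Jaccard distance is blind to divergence within shared
  blocks (see above).
* Dating assumes a molecular clock after a single linear rescaling.
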