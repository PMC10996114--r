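---
title: "Methods: population methylome analysis with methylpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population methylome analysis with methylpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylpop)
```

# Scope and model

methylpop analyses a three-stage domestication panel — wild, landrace
and improved accessions — through five coupled stages: methylome
assembly, DMR calling, selective-sweep scanning, meQTL mapping, and
methylation–expression correlation. This vignette documents the models,
the parameters that matter, the numerical choices, and what the
synthetic validation does and does not demonstrate.

## Methylome assembly

The atomic observation is one cytosine in one sample: strand, context
(CG/CHG/CHH), methylated and total read counts. Levels are always
pooled-count ratios, never means of ratios: the level of any site set is
Σ n_meth / Σ n_total. This weights sites by their read support and makes
a region's level identical whether computed from the matrix or from raw
counts (a conservation property the tests assert).

Choices worth knowing:

* **Replicates are pooled by summing counts**, not by averaging levels.
  Whether upstream tools average or pool is usually unstated; pooling is
  the maximum-likelihood choice under the binomial read model and keeps
  low-coverage replicates from dominating.
* **Coverage filter is strict**: a site needs *more than* `min_reads`
  (default 3) pooled reads. `n_total = 3` is dropped; 4 is kept.
* **Presence filter**: a site is retained only when non-missing in at
  least 70% of the accessions of *each* population (mirroring the
  companion SNP missing-rate filter; configurable).
* **CG dyads are not merged across strands.** No merging rule is part of
  the method definition, and strand-resolved records are the more
  conservative representation.
* **Coordinates** are 0-based half-open internally; file formats
  (cytosine reports, VCF, GFF3) convert at the I/O boundary; BED stays
  0-based as BED defines.
* The **paired t-test across populations** of unequal size is
  ill-defined; accessions are paired by rank of genome-wide mean within
  population, truncated to the smaller n, and the unpaired Welch test is
  reported alongside. Zero-variance paired differences report p = 0 (with
  a warning) when the shift is non-zero, p = 1 when everything is equal.

Metaprofiles use 20 upstream, 40 body and 20 downstream bins; flanks are
fixed 2 kb, body bins scale fractionally with feature length, and
minus-strand features are reflected so bin 1 is always 5′-most. Bin
values average site levels within a feature first, then across features.

## DMR calling

A DMR between two populations must satisfy three rules: at least 8
cytosines, every adjacent pair < 300 bp apart (strict), and an absolute
population mean-level difference above 0.25, with corrected p < 0.01.

The caller proceeds in four steps:

1. **Candidate blocks**: maximal runs of same-context sites with
   adjacent gaps < 300 bp; runs under 8 sites are discarded immediately.
2. **Segmentation**: recursive binary segmentation of the per-site
   difference signal d_i = mean_b(i) − mean_a(i). Among breakpoints
   leaving ≥ 8 sites in each child, the one maximising |mean_L − mean_R|
   is chosen; the split is accepted while it raises the larger child
   |mean| above the parent's by more than ε = 0.02. Restricting
   breakpoints to viable children is deliberate: unconstrained splitting
   lets single noisy sites be shaved off one at a time (any one-site
   child beats the parent mean by more than ε almost surely), which can
   dissolve a genuine region into sub-threshold fragments. With the
   restriction every leaf is a testable candidate.
3. **Testing**: each accession contributes its mean level over the
   segment's sites; the two groups are compared by a two-sided
   Mann–Whitney U (exact when the smaller group has ≤ 8 accessions and
   no ties; normal approximation with tie correction otherwise, via
   `stats::wilcox.test`).
4. **Correction and filtering**: Benjamini–Hochberg across all tested
   segments of one comparison/context (Bonferroni selectable), then the
   three rules. Direction is *hyper* when the later domestication stage
   is higher.

The segmentation is an equivalent-by-criteria caller: the published
acceptance rules, not any specific tool's internals, define what a DMR
is here, and the test suite verifies every emitted DMR against
exhaustive enumeration of contiguous ≥ 8-site windows.

A practical power note: with the exact test, two groups of 6 have a
minimum two-sided p of 2/C(12,6) ≈ 0.0022, which rarely survives BH at
q < 0.01 across hundreds of segments. Twelve accessions per population —
the panel scale this package defaults to — give ample power at
Δ = 0.4.

## Sweep scanning

Per-site π is 2j(n−j)/(n(n−1)); window π divides the summed site values
by the window span (per-bp, 10 kb windows, 1 kb step). F_ST is
Weir–Cockerham: per-site variance components a (among populations),
b (among individuals within) and c (within individuals) from sample
sizes, allele frequencies and observed heterozygosity, windowed as the
ratio of sums Σa / Σ(a+b+c); negative estimates are kept (they are
informative about sampling noise, and clamping would bias window means).

Sweep regions are windows exceeding *both* the empirical top-decile
π-ratio (π_ancestral/π_derived) and top-decile F_ST thresholds,
merged when overlapping or book-ended. The thresholds are data
properties recomputed per dataset and echoed in the run report. Windows
with zero derived-population π are excluded from the ratio ranking
rather than given infinite ratios; their count is reported. Non-selected
regions (NSRs) are the interval complement of DMRs ∪ DSRs.

Aggregate diversity per region class is bp-weighted (Σπ over all regions
of a class / Σbp): at desk scale individual DMRs span only a few hundred
bp and carry 0–3 SNPs, so an unweighted per-region mean would be
dominated by small-sample noise.

## meQTL mapping

Traits are per-DMR, per-accession pooled-count levels, transformed by
the rank-based inverse normal transform Φ⁻¹((r − 3/8)/(n + 1/4)) (Blom
offset; average ranks on ties; missing stays missing). Kinship is
identity-by-state: K_ij = mean(1 − |d_i − d_j|/2) over SNPs non-missing
in both samples.

The null model y = Xβ + u + ε with u ~ N(0, σ²_g K) is fitted by REML
after eigendecomposition of K: the profiled criterion is evaluated on a
100-point grid of log δ ∈ [−10, 10] (δ = σ²_e/σ²_g) and refined by
Brent's method in the bracketing interval. The scan then fixes the
variance components at this null (the EMMAX approximation — O(SNPs) per
trait) and tests each SNP by a GLS Wald test in the rotated, whitened
model, two-sided p from t on n − rank(X) − 1 df. Missing dosages are
mean-imputed per SNP; monomorphic SNPs are skipped. With K = I the scan
reduces exactly to OLS (asserted to 1e−6 in the tests).

Population structure enters as the top two genotype principal
components as fixed covariates. Admixture proportions would be the
classical alternative; genotype PCs are the accepted equivalent and keep
the package self-contained.

Significance is Bonferroni α/N over the SNP count (α = 0.01).
Significant tags are clumped greedily in p-value order: the best
remaining SNP is kept, and SNPs within 1 Mb with genotype r² ≥ 0.25 to
any accepted SNP are discarded (no ordering is canonical; p-ranked
clumping is the plink convention). Locality uses the distance from the
SNP to the nearest DMR edge (0 inside): ≤ 1 Mb on the same chromosome is
*local*, otherwise *distal*. The pure-DMR fraction is computed after
clumping — clumping only removes redundant tags, so the fraction is
insensitive to this choice.

## Annotation and expression

Genomic composition assigns each bp one label by precedence
exon > intron > TE > flank > intergenic: a TE inside an intron counts as
intron under the gene-centric default (a TE-priority ordering is
selectable). "Flank" (2 kb either side of a gene) is reported separately
from intergenic rather than conflated, with both views derivable.

Cross-context overlap groups (o_CG_CHG / u_CG / u_CHG) partition the DMR
set by ≥ 1 bp overlap under half-open logic (touching regions do not
overlap). Co-evolution correlation takes, per DMR, the CG and CHG levels
over the region and correlates across DMRs, per population and pooled.

PCA of accessions is centred, unscaled, with per-site mean imputation of
missing cells — complete-case deletion can empty a realistic matrix.

Expression quartiles cut genes by mean expression across accessions into
four near-equal groups (stable tie-break by gene order; all-zero genes
forced to "low"; with n genes, rank r maps to group ⌈4r/n⌉). DMR–gene
correlation uses log2(FPKM + 1) — Pearson correlation on raw FPKM is
dominated by high-expression outliers; a raw-scale option exists. The
grouping pools all accessions; per-population grouping is available by
subsetting.

# The synthetic panel

`simulate_panel()` is first-class, tested code, not a fixture. Its
defaults are the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes × 2 Mb | large enough for 10-kb/1-kb sliding windows, small enough for CI |
| accessions | 12 per population, 2 replicates | matches the power regime of a ~40-accession panel with pooled duplicate libraries |
| cytosine sites | 8000/context/chromosome | mean gap 250 bp, so adjacency runs form naturally |
| baselines | CG 0.5, CHG 0.35, CHH 0.1 | typical plant leaf methylome ordering; CHH low and skewed to unmethylated |
| stage shift | +0.02 per stage | a modest global gain, wild < landrace < improved |
| planted DMRs | 30, Δ = 0.4, 12 sites at 60-bp spacing | comfortably above the 0.25/8-site acceptance floor, in gene promoters so expression coupling is testable |
| hyper fraction | 2/3 | planted directions mirror the hyper-dominated counts expected under a global methylation gain |
| CG–CHG coupling | 0.5 | about half of CG DMRs get a co-located CHG partner, emulating observed cross-context overlap |
| SNPs | 20 000 (1 per 200 bp) | realistic resequencing density; ~50 SNPs per 10-kb window keeps window estimates informative |
| F_ST target | 0.1 | Balding–Nichols differentiation typical of crop populations |
| sweeps | 6 × 60 kb, heterozygosity ×0.1 | ~9% of the genome under selection; all derived populations are dragged toward the same allele (one sweep event) |
| meQTL | 1 planted DMR, +0.15/allele | keeps planted meQTLs ≤ 5% of called DMRs, so the pure-DMR fraction stays high |
| expression coupling | 10 genes, ρ = −0.7 | promoter methylation represses expression; noise tuned analytically to the target ρ on the log2 scale |
| accession jitter | Beta, concentration 50 | between-accession level variance is not reported for real panels; 50 gives realistic spread and non-degenerate rank tests, and is exposed in the config |

Two deliberate design points:

* **Planted regions get explicit ancestral/derived levels** (0.3 vs
  0.3 ± effect) rather than baseline ± effect, so the realised difference
  equals the nominal effect exactly, free of clipping at the [0,1]
  boundary — the effect-recovery oracle then has a clean target.
* **Direction asymmetry is planted, not emergent.** A small global stage
  shift (0.02) cannot by itself turn symmetric ±0.4 planted effects into
  asymmetric *called* counts, so the generator plants 2/3 hyper
  directions to emulate the methylation gain it models.

What the simulation does **not** emulate: spatial autocorrelation of
methylation beyond planted regions, bisulfite conversion error,
alignment artefacts, context-dependent coverage, linkage disequilibrium
decay within populations (SNPs are exchangeable given frequencies),
TE-driven methylation spreading, or any real genome's composition.
Passing tests therefore demonstrate the *statistical machinery* —
calibration, recovery, bookkeeping — not biological conclusions about
any real panel.

# Numerical choices and degenerate inputs

* Segmentation improvement threshold ε = 0.02 (well under the 0.25
  acceptance floor; raising it only coarsens candidate segments).
* Mann–Whitney: exact only when min(n) ≤ 8 *and* no ties; otherwise the
  tie-corrected normal approximation.
* Kinship eigenvalues are floored at 1e−6 (with a warning if genuinely
  negative) before REML.
* Constant traits transform to zeros with a warning; all-identical
  groups test at p = 1; regions with no covered sites return flagged
  missing values, never silent zeros.
* Empty DMR sets, empty sweep sets and empty matrices propagate as
  explicit empty results with warnings, not errors; fewer than 10
  windows or fewer than 3 accessions for PCA are errors.
* All randomness flows from a single seed in the config; the same seed
  reproduces byte-identical written datasets (checksummed in tests).

# Problem sizes

The default end-to-end run (2 × 2 Mb genome, 36 accessions, ~48 000
retained sites, ~18 500 post-filter SNPs) completes in under a minute on
one CPU. The test suite validates the caller's oracle equivalence on 100
random blocks of ≤ 30 sites, DMR recall over 10 seeds at n = 12 per
population, sweep recovery over 10 seeds, mixed-model calibration on a
41-accession × 10 000-SNP panel, and planted-meQTL recovery over 10
seeds at 2 000 SNPs — sizes chosen so the full suite runs in about a
minute while each check retains statistical teeth.

# Known limitations

* The caller's segmentation is mean-difference-based; callers guided by
  other statistics may delimit boundaries differently, though any region
  passing the three acceptance rules is recoverable.
* Pooled-panel diversity inside sweeps is only moderately reduced when
  the wild population retains variation; the bp-weighted aggregate and a
  realistic SNP density are what make the DMR/DSR diversity contrast
  detectable at desk scale.
* The EMMAX approximation understates per-SNP variance-component
  uncertainty; at panel sizes of ~40 accessions this is the standard
  trade-off for an O(SNPs) scan.
* With one planted meQTL the local/distal split of significant
  associations is a single observation per run; the classifier itself is
  exercised exhaustively on constructed fixtures instead.
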