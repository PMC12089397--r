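---
title: "Models and methods behind scdeplete"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scdeplete}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scdeplete)
```

`scdeplete` models targeted CRISPR depletion of abundant molecules from
droplet scRNA-seq libraries. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
fixtures do and do not establish about real data.

## The depletion model

A 3' droplet library is a pool of barcoded cDNA molecules. A Cas9 sgRNA
panel cleaves molecules belonging to four categories — carried-over rRNA,
mitochondrial and ribosomal protein-coding genes, curated non-variable
genes (NVGs), and recurrently covered intergenic intervals — before
amplification and sequencing. Because sequencing is (approximately)
uniform random sampling from the molecular pool, removing a fraction *f*
of molecules re-allocates that sampling effort: at matched sequencing
depth the expected number of reads available to non-targeted
("informative") molecules increases by a factor

$$\mathrm{FC} = \frac{1}{1-f},$$

which is 2-fold at *f* = 0.5. `deplete_counts()` implements this at the
UMI-count level: per cell, panel-gene counts are zeroed and a fresh
multinomial of the target depth is drawn over the non-panel genes with
probabilities proportional to that cell's observed non-panel counts —
removed molecules are replaced according to relative abundance. With
`per_cell_depth = "match"` the per-cell total is conserved exactly, every
panel gene ends at exactly zero, and the realised informative fold change
equals `1/(1 - f̂)` for the realised targeted share `f̂`.

Two properties of this resampling model deserve emphasis:

* **Support restriction.** The multinomial redraws from the *observed*
  non-panel counts of a cell, so it can never detect a gene the cell did
  not already show. Applied directly to a sequenced matrix at matched
  depth, depletion therefore cannot increase the genes-per-UMI complexity
  ratio — detected genes can only be lost (the panel genes, plus
  singletons that happen to drop out). The complexity gain reported for
  real libraries arises because sequencing samples a molecular pool much
  deeper than the read depth. To reproduce that comparison in simulation,
  treat a deep count matrix as the molecular library and resample *both*
  arms to the same shallower sequencing depth: the control arm with an
  empty panel, the treated arm with the panel. Both the top-N decrease
  and the complexity increase then reproduce robustly, and this is the
  construction our directional tests use.
* **Emptied cells.** Cells whose counts are entirely panel-derived have
  no non-panel abundance to resample from; they are dropped with a
  warning, never imputed.

At the read level, `classify_reads()` stands in for alignment against the
depletion reference: a read is assigned to the first category whose
reference shares at least θ of the read's canonical k-mers (defaults
k = 21, θ = 0.5, both configurable; category priority is the order of the
reference list). This is a deliberate desk-scale substitute for a
two-pass spliced aligner plus a dedicated rRNA screen; result-equivalence
with an aligner is not claimed, and any externally produced read→label
table can be used in its place. `deplete_reads()` then removes targeted
reads (the 100%-efficiency assumption), and `downsample_pairs()`
subsamples uniformly without replacement — reads are a fixed sequencing
run, whereas count re-allocation uses with-replacement multinomial draws
because it models molecule replacement by relative abundance.

## Guide design

Candidates are all 20-mers immediately 5' of an NGG PAM, on both strands
(`enumerate_protospacers()`). Composition filtering removes candidates
with GC outside [0.25, 0.75], a homopolymer run of 4 nt or more, or a
perfect dinucleotide tandem of 4 units or more; the bounds are
conventional IVT guide-pool QC values and all are configurable. The
off-target screen (`count_offtargets()`) counts Hamming-distance ≤ 3
matches in exonic exclusion sequence, requiring an NGG immediately 3' by
default (`require_pam = TRUE`) since cleavage needs a PAM; the toggle
exists because published screens do not always state this. Matching is
delegated to `Biostrings::matchPattern()` and is verified result-identical
to a brute-force position-by-position Hamming scan in the test suite. Any
candidate with a non-zero count is disqualified.

On-target scoring is a pluggable registry. The default
`"position_weight"` scheme is a fixed positional-nucleotide weight table
mapped through a logistic link — deterministic, documented
(`position_weight_table()`), and a stand-in for proprietary scorers such
as CRISPick, with which equivalence is explicitly not claimed. A
`"uniform"` scheme (0.5 for every guide) supports tests and neutral
selection. `select_spaced_guides()` finally picks guides greedily in
descending score (ties: ascending coordinate, then lexicographic
protospacer), accepting a guide only if its start is at least
`min_spacing` nt (default 30) from every selected start on that target.
With uniform scores this reduces to leftmost-first interval scheduling,
which is optimal; with arbitrary scores greedy selection is within a
factor 2 of the optimum, which the suite checks against exhaustive
search.

## Panel curation

**Non-variable genes.** Per dataset, counts are normalised to 10,000 per
cell; genes are ranked by normalised dispersion (variance/mean, z-scored
within ~20 equal-frequency mean bins — clamped so small inputs keep ≥ 5
genes per bin); the top `n_hvg` variable genes are excluded; the rest are
ranked by mean expression. Across datasets a gene's aggregate rank is its
*worst* per-dataset rank: a gene must be uniformly abundant and
non-variable in every dataset to be selected. Worst-rank aggregation is
the package's choice of a conservative intersection — it guarantees no
selected gene is highly variable (or absent) anywhere.

**Genomic intervals.** Reads overlapping any protein-coding gene span are
discarded; the remainder are accumulated into fixed 500-bp windows by
read start (O(1) binning; span-overlap accumulation would differ only for
reads straddling a window edge). The shared score of a window is its
minimum depth across datasets (strict sharing), and the selection is the
top `n_shared` shared windows plus each dataset's top `n_per_dataset`
specific windows (defaults 100 and 10; the source counts are not
published). Windows touching protein-coding genes are never reported.

**Depletion reference.** One record per panel gene — the unspliced
genomic span ±100 bp flank, clipped at contig ends, strand ignored
because the nuclease cuts double-stranded cDNA — plus one record per
interval and per rRNA sequence (rRNA entries resolve against dedicated
genome records first, annotation second).

## Library metrics

* Read buckets: targeted (any `targeted_*` label), informative (retained,
  transcript-derived), genomic (retained, no transcript of origin);
  origins come from truth labels or an external read→gene table.
* `top_n_umi_fraction()` ranks genes library-wide (total UMIs across
  cells) by default; whether published top-N curves used a library-wide
  or per-cell ranking is ambiguous, so `ranking = "cell"` provides the
  alternative.
* `complexity_profile()` reports genes detected per cell, the ratio of
  median genes to median UMIs, and genes per 1000 UMIs; medians use the
  midpoint convention.
* `signal_components()` normalises to 10k, log1p-transforms, standardises
  genes, and counts eigenvalues of the gene-gene correlation (via SVD
  across cells) above the Marchenko–Pastur edge `(1+√γ)²`, γ =
  genes/cells. Standardisation makes unit variance exact, so the edge
  needs no variance estimate; sparsity-corrected refinements of the MP
  law are out of scope. Note the MP null assumes independent cells:
  duplicating every cell halves γ and shrinks the edge while leaving the
  spectrum unchanged, so borderline noise eigenvalues can cross the
  reduced edge even though the planted structure is unchanged — the tests
  assert persistence of true components, not exact count invariance,
  under duplication.

## Applicability scoring

Tau tissue specificity uses `log2(x+1)` on TPM with an expression floor
of 1 TPM (genes never reaching the floor are reported missing, not zero);
the flagging threshold defaults to τ ≥ 0.8. The published analysis names
the metric without parameters, so all three are exposed as arguments.
Preranked enrichment is the classic weighted Kolmogorov–Smirnov running
sum (hit weight |statistic|^1, uniform miss decrement). The null is
gene-label permutation — random same-size gene sets — because the input
is a preranked list with no phenotype labels to permute; NES divides ES
by the mean |null ES| of the same sign, and with a single gene set the
FDR reduces to the p value (add-one smoothed). Equal-interval binning
places a value lying exactly on an interior edge into the lower bin.

## Synthetic fixtures and their limits

`library_spec()` defaults describe the study conditions used throughout:
1,000 cells × 2,000 genes at 2,000 UMIs per cell, log-normal (σ = 1)
baseline abundances, and a planted panel holding an expected 50% of UMIs.
Generators are pure functions of (spec, seed): genomes lay genes
head-to-tail with intergenic gaps, hotspots on the 500-bp window grid
past the gene region, and rRNA-like records outside the annotation; reads
are drawn from unspliced gene spans (matching the reference convention)
with exact truth labels. Acceptance-style checks run at reduced sizes
where closed forms make the scale irrelevant (e.g. 40-cell datasets for
category-share recovery; 20 replicates of the full 1,000 × 2,000 spec for
the fold-change closed form).

What the fixtures do **not** model: sequencing errors and quality scores
(qualities are preserved verbatim, never interpreted), PCR duplicates and
amplification bias, partial (< 100%) cleavage efficiency, splicing,
doublets and ambient RNA. Passing tests therefore establish correctness
of the algorithms under the stated generative model — not that a real
library will show a specific fold change, which depends on its actual
targeted fraction and molecular diversity.

## Numerical and degenerate-input choices

* Seeds are explicit arguments everywhere; the global RNG state is saved
  and restored around every stochastic operation.
* Pseudobulk comparisons use pseudocount 1 and multinomial downsampling
  to the smaller total (a library already at the target depth is left
  untouched, so identical inputs give exactly zero log2FC and r² = 1).
  No size-factor normalisation is offered in the off-target module, on
  purpose: a global re-allocation looks like a depth change to
  size-factor methods, which would mask both the benefit and the
  off-targets.
* Degenerate inputs error early and loudly: empty FASTA, mismatched
  MatrixMarket labels, single-tissue tau, constant binning statistics,
  all-zero matrices, k larger than the read length, sampling more pairs
  than exist.
* Ties are broken deterministically (documented lexicographic or
  coordinate order) so every result is reproducible bit-for-bit under a
  fixed seed.
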