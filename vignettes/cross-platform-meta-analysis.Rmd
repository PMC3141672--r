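---
title: "Cross-platform meta-analysis of transcriptome profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform meta-analysis of transcriptome profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xplatde)
```

# Scope and model

`xplatde` integrates differential-expression evidence for one paired
contrast (treated vs control, three biological replicates) measured on
several long-oligo microarray platforms and on a DpnII/MmeI digital gene
expression (DGE) tag-sequencing library. All platforms are reduced to a
common currency — per-gene `log2ratio` values for each paired comparison,
keyed by official gene symbols of a single reference transcriptome — and
then combined by a rank-based meta-analysis that never compares raw
intensities across platforms. The core assumptions are:

* the design is **paired**: each treated sample has its own control, so
  one-channel and two-channel platforms become comparable after forming
  per-pair log2ratios, and the per-gene null hypothesis is a zero mean on
  the log2ratio scale;
* probes and tags identify genes through **sequence**, not through vendor
  annotation: a probe or tag that matches transcripts of two different
  gene symbols carries no usable gene-level information and is discarded
  rather than resolved;
* platforms overlap only partially in gene coverage, so the merged matrix
  is **stratified by coverage signature** (the exact set of platforms
  measuring a gene) and each stratum is analyzed with the columns that
  actually exist — genes are never imputed into platforms that do not
  measure them.

# Sequence-level processing

## Probe cross-mapping

`map_probes()` reports every ungapped, sense-strand alignment of a probe
to a transcript with Hamming distance ≤ 2. Two mismatches accommodate the
divergence between probe-design-era sequence sources and the current
reference (natural variation, database errors, design artifacts).
Internally the scan is seeded by pigeonhole: an alignment with at most
*m* mismatches leaves at least one of *m*+1 disjoint probe segments
exact, so candidate positions come from an exact k-mer index and are then
verified by full Hamming comparison — the hit set is provably identical
to a brute-force scan, which the test suite confirms against an
independent matcher (`Biostrings::vmatchPattern`). Matching is
sense-strand only because probes and transcripts share orientation in the
reference; genome-coordinate mapping and spliced alignment are out of
scope.

`assign_genes()` keeps a probe only if all its hits agree on one gene
symbol (multiple hits within a gene — isoforms, repeats — are fine).
`summarize_gene()` aggregates probe log2ratios by the median; with an
even number of probes the two central values are averaged (conventional
choice), and missing cells propagate: a gene-level cell is missing only
when every contributing probe is missing.

## The DGE tag pipeline

The library protocol captures transcripts on oligo-dT beads, cuts with
DpnII (recognition site `GATC`), ligates an MmeI-containing adapter and
releases 17-18 bp fragments anchored at the transcript's 3'-most GATC.
The pipeline mirrors each step:

* **Adapter trimming** (`trim_adapter()`): the leftmost start at which an
  adapter prefix aligns with total cost ≤ 1 is the tag boundary, where a
  mismatch at offset *j* of an aligned region of length *l* costs
  (*l*−*j*)/*l* — errors near the read's 3' end, where base quality
  degrades, are penalized least. Alignments shorter than 5 nt are not
  considered (an adapter match that short is uninformative), and when no
  alignment qualifies the read is truncated to the maximum tag length of
  18 nt, which also caps all returned tags.
* **Reduced reference** (`build_reduced_reference()`): one window per
  GATC occurrence per transcript — the site ± 36 nt, truncated at the
  transcript ends — with the last site flagged 3'-most.
* **Tag counting** (`count_tags()`): a tag of length *t* (10-18 nt after
  trimming) is compared from every GATC anchor inside every window over
  `min(t, bases available)` positions, keeping the minimal mismatch count
  up to 2. The "all possible product sizes" of the original iterative
  mapping reduce, under anchored comparison, to this single rule; ties
  prefer the longer alignment and then the 3'-most site, reflecting the
  biochemistry (the sequenced fragment is the bead-proximal, 3'-most
  one). Tags whose best matches span two or more gene symbols are counted
  as ambiguous and excluded from the matrix. The per-sample mapping
  statistics satisfy `total = unambiguous + ambiguous + no-match` and
  `unambiguous = 0mm + 1mm + 2mm` by construction, asserted on every run.
* **Window filter** (`filter_low_probes()`): within each sample and gene,
  windows whose count falls below `mean − SE` of the gene's windows in at
  least ⌈0.9 · n⌉ samples are removed. The SE of a single value is
  defined as 0, so single-window genes are never removed; for two windows
  `mean − SE = min(count₁, count₂)` algebraically, so two-window genes
  are safe as well. The comparison carries a 10⁻⁹ relative tolerance so
  floating-point jitter cannot violate that identity.
* **Normalization** (`normalize_totals()`): each sample is scaled to make
  its total equal the median library total — the original study's
  normalization, kept deliberately simple. A zero-total sample is an
  error naming the sample.
* **Gene summation and ratios**: window counts are summed per gene symbol
  (column totals conserved) and paired log2ratios are formed with a 0.5
  pseudocount; a cell with zero counts in both members of a pair is
  missing rather than 0, since the gene was simply not observed there.

# Statistics

## Per-platform SAM-style test

`sam_test()` computes `d = mean(y) / (se(y) + s0)` per gene, with the
fudge factor `s0` defaulting to the median of all genes' standard errors.
The null is each gene's own sign-flip distribution — exhaustive over the
2ⁿ assignments for n ≤ 12 columns, Monte-Carlo beyond — with two-sided p
and BH q across genes. With three paired replicates this p is very
granular (minimum 2/8); the function exists to quantify exactly that
weakness of single-platform testing, not to replace the meta-analysis.
Genes with fewer than two observed values are excluded and counted in a
warning.

## Rank-product meta-analysis

Within a stratum, `rank_product()` ranks genes 1..G per column
(decreasing values for "up", increasing for "down"; ties averaged;
missing values ranked worst) and forms the geometric mean of each gene's
ranks. Because only within-column orderings enter, the statistic is
invariant under any strictly monotone per-column transform — the property
that makes cross-platform pooling legitimate.

`rankprod_significance()` builds the null by independently permuting each
column's observed ranks. `E` is the expected number of null rank products
at or below the observed one per permutation round, `pfp = E / rank
position` (the proportion of false prediction), and the nominal p is
`min(1, E/G)`. For G ≤ 5 genes and ≤ 3 columns the null is computed
exactly: over all (G!)^k column permutations a gene's rank is uniform
over the observed ranks and independent across columns, so the full
enumeration collapses to a G^k grid — the test suite verifies equality
with a literal (G!)^k enumeration. Monte-Carlo mode uses 1000 rounds by
default; comparisons against null values use a 10⁻⁹ log-scale tolerance
so ties are counted identically in both modes.

`meta_rankprod()` runs both directions within every stratum, pools the
nominal p-values of all genes and both directions, BH-adjusts them
jointly, and calls a gene regulated when adjusted p < 0.05 **and** its
median linear fold change `2^(median log2ratio over all its
measurements)` passes 1.2 (up) or 1/1.2 (down). Pooling nominal p-values
(rather than pfp) across strata, and treating all genes equally in the
joint BH regardless of how many columns measured them, are deliberate
choices where the original description is silent; they keep the adjusted
quantity a p-value and avoid weighting schemes with no stated rationale.
Strata with fewer than two genes cannot be ranked and are skipped with a
warning.

## Concordance diagnostics

`gsea()` implements the weighted-KS running sum: hits add
|metric|^p normalized over the set (p = 1 by default, the tool's default
weighting, since the original setting is not stated), misses subtract
1/(N−|S|); ES is the signed extremum. The null relabels the gene set —
random sets of equal size — because phenotype permutation is degenerate
with three replicates. NES divides ES by the mean same-sign null ES, and
the nominal p is the same-sign exceedance fraction; with a single set the
multi-set FDR machinery degenerates to that same fraction, which is what
`fdr_q` reports. `cat_curve()` and `overlap_summary()` are exact set
arithmetic; `stratified_correlation()` compares per-gene DGE log2ratios
(mean over pairs) with the unweighted mean of the array platforms'
log2ratios, over all tag-detected genes and again over genes reaching 32
counts in at least one sample — strata with fewer than three genes
return `NA` rather than failing.

## Pathway testing and the interconnection network

For paired data the two-group GlobalAncova reduces to a one-group
hypothesis — all gene means zero — and the F statistic compares
`RSS0 = Σ y²` against the gene-means model `RSS1 = Σ (y − ȳ_g)²`:
`F = ((RSS0 − RSS1)/|S|) / (RSS1 / Σ(n_g − 1))`, with rows using their
available columns when cells are missing, `F = 0` for an all-zero block
and `Inf` when the gene means explain everything. The null flips the
sign of whole columns (the same ε ∈ {−1, +1}ⁿ for every gene), which
preserves the gene-gene correlation the test's theory requires —
column-label permutation would not. Exhaustive mode enumerates all 2ⁿ
flips (used up to n = 12 columns inside `test_pathways()`); Monte-Carlo
mode reports `(1 + #{F* ≥ F})/(1 + B)`, never exactly zero. Pathways are
tested on the all-platform intersection stratum only, where every gene is
measured on every column; the family-wise Holm correction — deliberately
conservative because the test is sensitive — gates significance at 0.01.
`build_network()` joins significant pathways sharing at least 2 regulated
genes, with the shared count as edge weight; isolated significant
pathways remain as degree-0 nodes, and both the degree and the weighted
degree ("connections") are reported, since printed accounts of such
networks vary in which one they quote.

# The synthetic-data generator

`simulate_study()` emulates the study design the pipeline expects: three
array platforms covering a random ~90% of genes each (so all coverage
strata are populated) plus a DGE pseudo-platform covering exactly the
GATC-bearing genes, three paired replicates, and a ground truth of 200
differentially expressed genes (half up, half down) at |log2FC| = 1 in a
2000-gene reference by default. Specifics worth knowing:

* **Transcripts** are random sequences with GATC sites planted explicitly:
  a transcript carries ≥ 1 site with probability `dpn_site_prob`
  (default 0.95) and is guaranteed site-free otherwise, with the 3'-most
  site placed ≥ 14 nt from the end so a full tag exists. This makes "gene
  invisible to tag sequencing" a designed, testable state rather than an
  accident.
* **Array noise** follows
  `log2ratio = effect + a(gene, replicate) + b(probe, replicate)` with
  both standard deviations defaulting to 0.3 — replicate noise shared
  across a gene's probes, probe noise independent. "Bad" probes
  (default 5%) are cross-gene chimeras: half the probe from another
  gene's transcript, so they match nothing unambiguously and exercise the
  discard path end to end; their planted rate is recovered exactly by the
  tests.
* **DGE libraries** sample transcripts multinomially with log-normal
  baseline abundances multiplied by 2^effect in treated samples; reads
  are the 17- or 18-mer canonical tag plus adapter, truncated to 36 nt,
  with independent per-base substitution errors at 1%. The default
  library size is 10⁵ reads per sample, scaled to the 2000-gene
  reference so that per-gene counts sit in the tens and the 32-count
  detection threshold separates a meaningful fraction of genes.
* **Reproducibility**: every generator derives its random stream from
  `(seed, generator, platform/sample, ...)`, so the same seed gives
  byte-identical output and adding a platform never perturbs another's
  draws.

What the generator does **not** emulate: intensity-scale artifacts
(scanner saturation, dye bias, GC effects), dye-swap technical
duplicates, isoform-level differential expression, quality-score
structure in reads, and biological correlation between genes. Passing
tests therefore demonstrate that the algorithms are implemented correctly
and behave as designed under the stated noise model — not that the
pipeline is robust to every failure mode of real arrays or sequencers.

# Problem sizes and calibration checks

The test suite and the acceptance script run, on one CPU: oracle
comparisons at 1000 probes / 5000 tags against a 200-transcript
reference; exact-enumeration equivalence on 3-5-gene rank-product
instances and ≤ 10-column sign-flip blocks; null calibration with 20
merged matrices of 2000 genes × 4 platforms × 3 replicates (1000
permutation rounds each) plus 200 null pathway blocks and 200 null gene
sets; and parameter recovery over 10 simulated studies at the default
design. These sizes were chosen so the whole cycle completes in minutes
while keeping every Monte-Carlo standard error well inside the margins
being asserted.

# Known limitations

* The matcher is transcriptome-only and ungapped; probes spanning splice
  junctions of an incomplete reference would be lost rather than
  reconciled against a genome.
* Median-total normalization is the original study's choice and is kept
  for fidelity; composition effects that motivate modern count
  normalizations are not addressed.
* The per-gene sign-flip SAM p cannot fall below 2⁻ⁿ⁺¹, so per-platform
  lists at three replicates are rank-based rather than
  threshold-based — which is precisely the weakness the meta-analysis
  exists to overcome.
* `pfp` is reported per stratum while the regulated-gene call uses the
  pooled BH-adjusted nominal p; the two agree in ordering but are not
  interchangeable quantities.
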