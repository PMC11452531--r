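---
title: "Calling and characterising broad binding regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and characterising broad binding regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broadbind)
```

## The analysis in one paragraph

Some genome-maintenance proteins — FANCD2 of the Fanconi anemia pathway is
the motivating example — do not bind the genome as isolated point peaks.
Under DNA replication stress their ChIP-seq peaks cluster across hundreds of
kilobases, typically spanning the bodies of very large (0.5–1.5 Mb) genes
that replicate late, undergo mitotic DNA synthesis (MiDAS), and are hotspots
for copy-number variation (CNV). `broadbind` turns a standard narrowPeak
file into ranked **broad binding regions (BBRs)** by gap-merging peaks, and
then quantifies everything one asks next: which genes the BBRs cover and how
their sizes compare to the genome-wide distribution, how strongly the BBRs
overlap external region sets (MiDAS, CNV, late-replicating intervals), what
the TSS-anchored binding profile looks like, and whether the bound genes
change expression between two genotypes.

## The BBR model

A BBR is the transitive closure of the relation "two peaks lie within
`merge_gap` base pairs of each other", computed per chromosome on 0-based
half-open intervals. The default `merge_gap` of 50,000 bp is the merge
distance used in the replication-stress ChIP-seq literature for this class
of broad domains; bookended intervals merge (the `bedtools merge -d`
convention), and since the boundary inclusivity of the published merges is
not documented, a gap of exactly `merge_gap` merges here too.

Each BBR is scored by its **PSCORE**, the −log10 of the product of its
member peaks' enrichment P values, i.e. the sum of the per-peak −log10 P
that narrowPeak column 8 already stores:

$$\mathrm{PSCORE} = -\log_{10}\prod_i P_i = \sum_i -\log_{10} P_i .$$

The product-of-P reading is the only one under which a "cumulative" peak
score is additive over cluster members; it makes the score monotone in both
peak count and peak strength, which is what a broad-domain ranking needs.
Ranking is by descending PSCORE with ties broken by (chromosome, start), so
it is deterministic.

Gene assignment uses ≥ 1 bp overlap with gene bodies (no promoter
extension): one overlapping gene name makes the BBR `single_gene`, two or
more `multi_gene`, none `intergenic`. Multiple transcript records sharing a
gene name count as one gene; the recorded length of an assigned gene is the
longest genomic span among its records — a conservative choice that never
inflates a gene's size class by bridging isoforms. Size classes are
cumulative (a > 1.0 Mb gene is also > 0.5 Mb), and the skew of bound-gene
sizes against a background gene set is summarised by the two-sample
Kolmogorov–Smirnov statistic
$D = \sup_x |\hat F_\mathrm{bound}(x) - \hat F_\mathrm{background}(x)|$
computed by a direct ECDF scan, with the direction of the shift reported
alongside.

## Overlap statistics

Overlap with an external region set is reported in the two coordinates the
field plots side by side: the fraction of query regions with at least 1 bp
of intersection (*region overlap*), and the fraction of query base pairs
covered by the subject (*bp overlap*). The subject set is merged before bp
accounting so overlapping subject intervals are not double-counted; a query
region touching several subject intervals counts once. The denominators are
always query-side, so the two roles are not interchangeable — this matches
the "coverage of first dataset by second" semantics of the Galaxy-style
coverage tools used for published MiDAS and CNV comparisons. CNV gains and
losses can be compared separately and pooled; gene-level sharing between
datasets is reported as a full Venn partition that carries, for every
dataset combination, both the exclusive count and the total intersection
count, so either reading of a published "shared genes" figure can be
checked.

Replication timing enters as a bedGraph track thresholded into
late-replicating intervals (`threshold_track_to_intervals`). Published
analyses display timing as browser tracks without a printed cutoff, so the
default threshold is the genome-wide median of the track — an explicit,
reproducible stand-in that the user can override.

Chromosome naming is never reconciled silently: a query and subject sharing
no chromosome names yields zero overlap with a warning, and renaming is
opt-in via `rename_chroms()`. Silent "chr" stripping is a classic source of
quietly-zero overlap results.

## Signal tracks and TSS profiles

Tags are extended 3′-ward to the library's average fragment length (default
200 bp) and counted into fixed 32-bp bins; a fragment touching a bin by 1 bp
counts in it, matching extended-tag density conventions. Sample/input
comparison uses `log2((s + c)/(i + c))` after scaling both tracks to
counts-per-million (pseudocount `c = 1`); CPM-plus-pseudocount is the
documented default behaviour of the standard bigWig-comparison tools. An
unscaled mode is available for exact arithmetic on raw counts.

The TSS matrix takes one row per gene model record (no isoform collapsing),
spanning ±5,000 bp around the TSS — gene start on the plus strand, gene end
on the minus strand — in 50-bp columns (200 columns; the published heatmaps
do not state their column width, and 50 bp resolves a 32-bp track without
aliasing badly). Minus-strand rows are flipped so column 1 is always
upstream. Columns that fall off the chromosome are zero-filled and flagged,
and flagged cells are excluded from the mean profile. Note one geometric
consequence of this layout: the TSS base sits on the boundary between the
two central columns, so a perfectly symmetric binding peak centred on the
TSS produces near-identical values in both central columns and the profile
maximum legitimately lands in either.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth, at a default
scale chosen to mirror the structure of a replication-stress occupancy
study while running in seconds: one 20-Mb chromosome, 40 genes of which a
quarter are "large" (0.5–1.5 Mb uniform; the rest 5–100 kb), 8 peak
clusters planted inside distinct large genes, 30 isolated background peaks,
per-peak −log10 P drawn as 4 + Exp(1) (MACS2-style calls at P ≤ 1e-4), and
comparison sets that overlap each planted cluster with probability 0.7.
Structural guarantees hold by construction and are asserted after
generation: inter-gene gaps exceed the merge gap plus 1 kb (clusters in
neighbouring genes can never merge), intra-cluster peak gaps stay below the
merge gap, and background peaks keep more than the merge gap from
everything. The large-gene count is the rounded fraction rather than a
Bernoulli draw so the planted clusters always have enough hosts at toy
scale. Each generator stage seeds its own RNG stream from the master seed,
so changing one stage's parameters leaves the other stages' draws intact.

Two arms of the generator deserve comment:

* **Unbiased-binding control.** For the gene-size-skew contrast the
  generator can draw each cluster's host gene uniformly with replacement
  (`cluster_genes = "uniform"`). An ECDF comparison needs a bound-gene list
  comparable in size to the gene universe to resolve a *small* D: a handful
  of uniformly chosen genes cannot produce D below ~0.2 simply because its
  ECDF moves in steps of 1/n. The control arm therefore plants one cluster
  per gene on average (40 clusters over 40 genes, ~25 distinct bound
  genes), at which size an unbiased draw typically yields D < 0.15 while
  the biased arm sits at D ≥ 0.75.

* **TSS enrichment.** Planted fragments have centres drawn from a normal
  distribution centred exactly on the TSS (sd = `tss_window`/3, truncated
  at ±`tss_window`), so the expected coverage after extension is a
  symmetric peak with its mode on the TSS; `tss_fold = 1` plants nothing.
  The planted tag count per TSS is set so the local rate is about
  `tss_fold` times background.

* **Expression.** Counts are negative-binomial (default depth 500,
  dispersion 0.05) around log-normal baselines, with a planted ±2 log2
  fold change in a 20% subset. The default of five replicates per genotype
  comes from a power calculation: the package's deliberately simple
  fallback test (Welch t on log2(normalized + 1), Benjamini–Hochberg
  adjusted) needs n ≥ 5 at this depth and dispersion to recover ±2 effects
  with ≥ 90% sensitivity; at n = 3 the per-gene variance estimate is too
  unstable. When an externally computed statistics table is available it
  should always be preferred over the fallback.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level error and mappability structure, GC
and copy-number bias in input chromatin, overdispersed peak background,
correlated replicate structure in expression data, isoform-level gene
models, and inter-chromosomal heterogeneity. The generator validates the
algebra and the end-to-end plumbing, not the biology of any particular
dataset.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; GTF input is converted on
  read. Chromosome order is natural-number aware (chr2 < chr10), with ties
  in sorting broken by (start, end, name).
* `merge_with_gap` is idempotent; merging never decreases covered bp.
* An empty query yields an overlap report with zero fractions and an
  explicit `empty_query` flag rather than NaN.
* `log2_ratio` refuses a zero pseudocount when the input track contains
  zero bins rather than emitting infinities.
* Genes on chromosomes absent from a track are skipped with a warning;
  malformed BED/narrowPeak rows fail with the offending line number.
* The fallback DE test returns p = 1 for genes with identical constant
  counts in both genotypes instead of NA from a degenerate t-test.

## Validation scales

The shipped validation suite exercises: 1,000 random interval sets (n ≤
200) against per-base brute-force oracles; exact recovery of the 8 planted
clusters with PSCORE-rank agreement; a 200-cluster / 0.7-co-occurrence
genome over 20 seeds against the binomial interval; TSS profiles from 2–3
million fragments over 200 genes (peak position, ≤ 2% mirror asymmetry,
flat-profile max/min < 1.1); the size-skew contrast over 20 seeds; and
500-gene expression tables (100 planted effects) for ≥ 0.9 sensitivity with
zero sign errors. These sizes were chosen as the smallest at which the
binomial and ECDF statistics in question are informative.

## Known limitations

* The published worked examples that depend on the article's supplementary
  tables (shared-gene counts, size-class counts, expression-change counts)
  can only be recomputed when those tables are supplied by the user; see
  the README.
* No interval trees: all operations are sorted sweeps, linear after an
  O(n log n) sort, which is ample at BBR scale (tens to hundreds of
  regions) but not designed for hundred-million-interval workloads.
* BAM and bigWig are out of scope as binary containers; tags arrive as
  TSV/BED and tracks as bedGraph.
* The fallback DE test is not a count-model engine: no dispersion
  shrinkage, no independent filtering. It exists so the pipeline runs end
  to end without external statistics, and its results should be read
  accordingly.
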