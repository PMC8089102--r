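---
title: "Calling super-bivalent genes and comparing epigenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling super-bivalent genes and comparing epigenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epibivalent)
```

## The problem

Bivalent promoters carry both the active mark H3K4me3 and the repressive
mark H3K27me3, keeping developmental genes poised. In epiblast-stage
pluripotent cells a subset of these promoters shows something stronger:
an H3K4me3 domain that is both unusually broad and, averaged over a
10-kb promoter, more enriched than the average housekeeping promoter,
together with strong H3K27me3 — *super-bivalency*. Counting and comparing
these genes across cell states (naive ES cells, formative-state cells,
primed epiblast stem cells, in vivo epiblast) is a useful fingerprint of
formative pluripotency, alongside genome-wide DNA-methylation similarity
and group-specific expression.

`epibivalent` implements that classification end to end, from aligned
read intervals to call sets, together with the surrounding comparisons,
and ships a synthetic-data generator with planted ground truth so every
step can be validated quantitatively without multi-gigabyte sequencing
input.

## The classification procedure

For each sample:

1. **Promoter enrichment.** Reads (deduplicated, uniquely mapped; BED
   intervals) are assigned to windows by their midpoint, and enrichment
   is RPKM: `count / (window_kb) / (library_millions)`. Two promoter
   windows are used: TSS ± 2.5 kb for mark *presence*, and the 10-kb
   promoter (TSS ± 5 kb) for the super-bivalency comparison, which must
   see domain breadth.
2. **Bivalent universe.** Either a curated bivalent gene list is taken
   as given (when replicating published sets), or bivalent genes are
   derived as those with both marks present in the ± 2.5-kb promoter
   (`RPKM >= 1` for each mark by default).
3. **Z-score baseline.** The 10-kb H3K4me3 RPKM of *all* genes is
   standardized per sample (population SD). Standardizing over all
   genes, not only bivalent ones, keeps the housekeeping baseline on the
   same scale — the baseline is the mean z-score of the housekeeping
   set. Because z-scoring is a monotone per-sample transform, the
   comparison is threshold-free across samples with different library
   sizes.
4. **Super-bivalent call.** A bivalent gene is super-bivalent iff its
   H3K4me3 z-score is *strictly* greater than the housekeeping baseline
   and its 10-kb-promoter H3K27me3 RPKM is *strictly* greater than 1
   (both rules read as "higher than", so ties are excluded). The
   H3K27me3 side uses plain RPKM, not a z-score.
5. **Set comparison.** Overlap between call sets is reported as the
   shared count and the rounded percentage of the first set.

Breadth itself is visualized with strand-aware TSS meta-profiles:
per-gene binned RPKM across the 10-kb window, minus-strand genes
reversed, averaged, and divided by the housekeeping mean 10-kb RPKM.
Normalizing this way makes profiles comparable across samples; by
construction the housekeeping set normalized by its own mean averages
exactly 1 over the window, which the tests assert as an identity. The
breadth summary is full width at half maximum (FWHM) of the profile.

## Methylome and expression comparisons

DNA methylation is summarized in 10-kb bins as the coverage-weighted CpG
methylation fraction; bins with summed coverage below `min_coverage`
(default 3, configurable — callers rarely state this; 3 keeps toy
genomes usable) are missing and handled pairwise-complete. Sample
similarity for clustering is the **uncentered correlation**
`sum(x*y) / sqrt(sum(x^2) * sum(y^2))` (the Cluster 3.0 convention;
scale-invariant but not shift-invariant), clustered with average
linkage on `1 - s`. Average linkage is monotone, so merge heights never
invert; samples are sorted lexicographically first so the tree does not
depend on input order. Pairwise sample agreement is reported as plain
Pearson *r* over shared bins (the smoothed-scatter rendering seen in
publications is a plotting choice, not part of the statistic).

Expression uses FPKM matrices over exactly three groups. The
one-versus-rest filter assigns a gene to a group iff its group-mean FPKM
is ≥ 1.5× the mean of *each* other group and ≥ 3 FPKM. Means over
replicates (not per-replicate requirements) are the comparison unit —
the defensible reading where the source is silent. A fold change against
a zero mean counts as infinite. For any fold-change threshold above 1,
mutual domination is impossible, so each gene receives at most one
label. Significance testing (negative-binomial DE) is deliberately out
of scope: the filter is the classifier here. qPCR support is the
2^−ΔCt formula only.

## Numerical and convention choices

* **Coordinates** are 0-based half-open everywhere (BED convention);
  GTF input (1-based closed) is converted on read, and the TSS of a
  minus-strand gene is `end − 1`. One convention end to end eliminates
  off-by-one drift.
* **Midpoint assignment** of reads to windows makes genome binning a
  partition: bin counts sum exactly to the library size (asserted), and
  it is standard for short ChIP fragments.
* **Library size** is the count of supplied reads; no input subtraction
  or spike-in scaling — enrichment is plain RPKM. No pseudocounts: a
  zero stays zero, and downstream z-scoring absorbs spread. A sample
  with zero reads yields an all-zero column with a warning rather than
  an error.
* **Degenerate z-scores**: a constant enrichment vector yields all-zero
  z-scores with a warning instead of crashing on toy inputs.
* **Promoter windows** are clipped at chromosome ends and RPKM uses the
  clipped width, avoiding inflated boundary densities. "10-kb promoter"
  is read as TSS ± 5 kb (window asymmetry is configurable but not the
  default; the symmetric reading is the natural one).

## What the generator emulates — and what it does not

`sim_config()` defaults define the study conditions used by the test
suite and the acceptance script: one 10-Mb chromosome, 190 genes on a
50-kb grid with shuffled classes (40 housekeeping, 40 bivalent, 30
super-bivalent, 40 active, 40 silent), 50-bp reads. H3K4me3: 2-kb
domains at 500 reads/kb for housekeeping/active and 150 reads/kb for
bivalent genes; 8-kb domains at 500 reads/kb for super-bivalent genes —
so super-bivalent promoters are broader *and* stronger over 10 kb than
housekeeping ones, while typical bivalent promoters sit clearly below
the housekeeping average, as they do in real chromatin. H3K27me3: 8-kb
domains at 250 reads/kb on bivalent, super-bivalent and silent genes.
Background is 0.02 reads/kb genome-wide. These depths give per-mark
libraries of ~210–220k reads, at which a single stray background read
in a ± 2.5-kb window stays below RPKM 1, so presence thresholds remain
meaningful at this scaled-down library size. The separate bivalent-class
H3K4me3 depth is essential, not cosmetic: if bivalent and housekeeping
promoters shared one depth, half the bivalent genes would exceed the
housekeeping mean by symmetry and no classifier could distinguish
super-bivalency from noise.

The methylome places CpGs every 100 bp at fixed coverage 20, methylated
at 0.8 globally and 0.1 inside 10-kb valleys centered on bivalent-class
promoters (emulating DNA-methylation valleys at developmental genes).
Expression is log-normal FPKM with CV 0.2 around planted class/group
means (9 vs 3 for one-group-high classes, 5 uniform), two replicates per
group, so planted genes pass the FC ≥ 1.5 / FPKM ≥ 3 filter in
expectation and exactly at CV 0.

What passing tests on this generator shows: the *procedure* — windowing,
normalization, thresholds, set logic, clustering — recovers planted
structure essentially perfectly under the model's assumptions, and every
closed-form quantity is exact. What it does not show: robustness to real
peak shape, nucleosome structure, mappability/GC bias, input-dependent
background, replicate disagreement, or annotation ambiguity, none of
which are modeled (read placement is uniform within rectangular
domains). Dataset-level published counts (e.g. a specific number of
super-bivalent genes in a given cell line, or a specific genome-wide
methylation correlation against an in vivo sample) depend on the
original sequencing libraries and a prior curated bivalent list, and are
therefore not reproduced at this scale.

## Problem sizes and determinism

Stochastic checks use 20 independent replicates at the default
conditions (~0.5 s each end to end), and law-of-large-numbers checks use
200 draws on a one-gene genome; both sizes make sampling error a small
fraction of the asserted margins. Every generator consumes a seed
derived from `sim_config(seed)` plus a stable stream label (mark,
sample), so reruns are identical record for record, different streams
are independent, and the pipeline's text outputs are byte-identical
across reruns — which the tests assert with file checksums.

## Known limitations

* The bivalent universe derived by thresholding is a convenience, not a
  substitute for a curated bivalent list when replicating published
  sets; both paths are supported and logged.
* Uncentered-correlation clustering operates on as few as two samples
  but is only informative with several; the pipeline emits trees only
  when at least two samples are present.
* No peak calling, no DMV segmentation, no differential-methylation
  testing, no GO enrichment — these sit outside the classification
  procedure this package owns.
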