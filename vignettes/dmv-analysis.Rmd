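---
title: "Calling and interpreting DNA methylation valleys with dmvscape"
author: "dmvscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and interpreting DNA methylation valleys with dmvscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
    library(dmvscape)
    library(GenomicRanges)
})
```

## Background

Plant genomes carry cytosine methylation in three sequence contexts — CG,
CHG and CHH (H = A, C or T) — maintained by distinct methyltransferase
pathways and typically present at very different background levels
(CG ≫ CHG ≫ CHH). Against this methylated background, *DNA methylation
valleys* (DMVs, also called unmethylated regions) stand out as stretches
where methylation is nearly absent in **all three** contexts. Valleys are
largely stable across tissues and developmental stages, concentrate over
developmental regulator genes, and are where most histone-modification
peaks land, so they are read as a map of the genome's regulatory potential.
dmvscape implements the full desk side of such a study: valley discovery
from per-cytosine bisulfite calls, cross-tissue conservation, gene-centred
annotation, tissue-specificity scoring of an expression atlas, and
peak/valley overlap statistics — together with a seeded simulator that
makes every stage testable without sequencing data.

## The valley-calling procedure

For each tissue the genome is scanned with a sliding window of
`windowSize` = 1000 bp advanced in `step` = 200 bp increments; the final
window of each chromosome is truncated at the chromosome end, giving
`ceil(max(L - 1000, 0)/200) + 1` windows for a chromosome of length `L`.
Within a window, a cytosine *qualifies* when its read depth is at least
`minCoverage` = 5. The window is *considered* only when **each** of CG, CHG
and CHH has at least `minCytosines` = 5 qualifying cytosines. The weighted
methylation level of a context is the ratio of summed methylated to summed
total read counts over its qualifying cytosines; counts from both strands
are summed, which is arithmetically identical to strand pooling for a
ratio of sums. A considered window is a valley window when its level is
**strictly below** `maxLevel` = 0.05 in all three contexts — a window at
exactly 5.0% in any context is rejected. Overlapping or book-ended valley
windows are merged into maximal intervals and the per-context levels are
recomputed over each merged region.

Two points in this procedure were genuinely open and are package decisions:

* **The site filter is applied per context.** The alternative — five
  qualifying cytosines pooled across contexts — would let a window pass
  with, say, one covered CHG cytosine, making that context's level an
  unstable estimate from a single site while the sub-5% rule still has to
  hold for it. Requiring five sites in each context keeps every one of the
  three thresholded quantities estimable. The filter is exposed via
  `DMVParams()` so the pooled reading can be emulated by setting
  `minCytosines = 1` if desired.
* **Book-ended windows merge.** Because `step < windowSize`, neighbouring
  qualifying windows always overlap; book-ending can only arise against a
  truncated terminal window, and treating it as contiguous avoids splitting
  a valley at a chromosome end.

The *conserved* valley set across tissues is the per-base intersection of
the per-tissue valley sets — a base is conserved when every tissue's
valleys cover it — with runs shorter than one window discarded, since an
interval the caller itself could never emit should not be reported as a
valley. The per-tissue *shared fraction* is the fraction of a tissue's
valleys that overlap (≥ 1 bp) a valley of at least one other tissue.

## Relating valleys to genes

`classifyDMVs()` assigns each valley one category with fixed precedence
**genic > promoter > downstream > distal**: overlap with any gene body
wins; otherwise overlap with a strand-aware upstream window
(`promoterBp` = 2000) or downstream window (`downstreamBp` = 2000);
otherwise the valley is *distal* when the gap to the nearest gene body is
at least `distalMinBp` = 2000. The precedence order resolves valleys that
span several features in favour of the stronger claim; with the default
window sizes the residual "proximal-unclassified" bin is empty by
construction (any gap below 2 kb lies inside a flanking window) and only
becomes reachable when `distalMinBp` exceeds the window sizes. Distances
count the bases strictly between interval edges, 0 for overlap; nearest
genes are chosen by minimal gap with ties broken deterministically by
smaller gene start, then lexicographic gene id.

A *DMV gene* (`callDMVGenes()`) is a gene whose body extended by
`flankBp` = 1000 on both sides — clipped at chromosome bounds — lies
entirely within a single merged valley. Since merged valleys are maximal,
containment across two valleys cannot occur. *Promoter-DMV genes* are
genes that fail that containment but whose upstream 2-kb window overlaps a
valley; the two categories are disjoint, so their counts add.

## Tissue specificity

The expression atlas is a gene × tissue FPKM matrix. Genes are *expressed*
at ≥ 0.5 FPKM in at least one tissue, and per-tissue expression is
summarised in the bins [0.5, 5), [5, 10), [10, 100) and [100, ∞). Two
per-gene summaries drive specificity:

* **Z-scores**, `(X_i − μ)/σ` across tissues with the sample (n−1)
  standard deviation; constant rows map to all-zero vectors rather than
  errors.
* **Shannon entropy**, `H = −Σ P_i log2 P_i` with `P_i = X_i / Σ X`, in
  bits: 0 for single-tissue expression, `log2(n)` for a uniform profile.
  Entropy is invariant to rescaling a gene's vector, so it measures shape,
  not magnitude. The base-2 choice makes the bounds readable (a 16-tissue
  atlas tops out at 4 bits).

Genes with maximum FPKM below `expCutoff` = 2 are omitted. A candidate is
called *tissue-specific* when `H ≤ entropyMaxBits` (default 2 bits — at
most four tissues' worth of effective spread) **and** its peak z-score is
at least `zThreshold` = 2; the peak tissue is the FPKM argmax. The
published analyses this mirrors used the SEGtool package, whose internal
detection rule is not described in its calling interface; this
entropy-plus-z rule is the package's own transparent stand-in, built from
the same two statistics those analyses present as the evidence of
specificity, with all thresholds exposed in `SpecificityParams()`. Counts
produced under it are therefore not comparable gene-for-gene with SEGtool
output.

Stage profiles of specific genes are clustered by agglomerative
hierarchical clustering of z-profiles (Euclidean distance, complete
linkage — unstated in the motivating analyses, chosen as the common
default and exposed in the call), cut at `nClusters` = 9; cluster labels
are reordered by the stage at which each cluster's mean profile peaks.
Enrichment of a gene set (e.g. tissue-specific TFs) within DMV genes uses
the Pearson χ² test on the 2×2 membership table, 1 df, no continuity
correction; a zero marginal is an error rather than a silent 0 statistic.

## Peaks, fractions and meta-profiles

A peak lies *within* the valley union when at least `minFrac` = 0.5 of its
length overlaps it. Published valley studies report "peaks within DMVs"
without stating the rule; majority-overlap is robust to 1-bp touches and
is therefore the default, with a midpoint rule available
(`OverlapParams(withinRule = "midpoint")`). The within-fraction is
monotone non-increasing in `minFrac`. A gene is *marked* by a histone mark
when any peak of that mark overlaps the gene ± 1 kb by at least 1 bp.
Differential peaks are consumed as upstream input (e.g. MAnorm output),
never computed, and are summarised with the same rules.

`metaProfile()` averages signal over a region set: each region's body is
rescaled to `nBodyBins` = 40 bins, flanks of `profileFlankBp` bp (1 kb for
valley profiles, 2 kb for gene-style profiles) are split into
`nFlankBins` = 20 absolute bins, and minus-strand regions are flipped so
bin 1 is always 5′. Signal is per-base peak coverage (0/1) by default,
score-weighted density, or — for `CytosineCalls` input — the weighted
methylation level per bin; bins are computed on fractional coordinates, so
regions shorter than the bin count are handled exactly rather than
erroring. With `max1` normalization the profile is divided by its maximum,
matching the convention of scaling each mark's enrichment to 1; an
all-zero profile cannot be normalized and raises an error pointing to
`raw`. Control regions (`randomControlRegions()`) match the valley length
multiset exactly and are placed uniformly in valley-free space, seeded.

## The synthetic study design

`defaultSimulationPlan()` encodes the study conditions the package is
tested under: a 2-Mb genome in two scaffolds; cytosine densities CG 0.04,
CHG 0.04, CHH 0.12 per bp; background methylation means CG 0.80, CHG 0.40,
CHH 0.10; per-cytosine true levels drawn from a beta around the regional
mean with concentration 50 (enough spread to be realistic, far too little
to push background below the 5% threshold); Poisson(20) coverage and
binomial methylated counts; 20 planted valleys of 2–10 kb at true level
0.01, identical across five tissues (leaf, root, embryo and two endosperm
stages — a typical WGBS design), mirroring the strong cross-tissue
conservation of real valleys; gene models inside and outside valleys; a
16-tissue atlas of 2000 genes with 200 planted single-tissue genes
(on-FPKM 50, off-FPKM 0.1, log-normal noise sd 0.2); and five histone-mark
peak sets coupled to valleys with probabilities 0.87–0.97, the range real
marks show. Background atlas genes receive a gene-specific log-normal
baseline (meanlog 1, sdlog 1.5 across genes) times milder tissue noise
(sdlog 0.6): separating across-gene from across-tissue variance is what
real atlases look like — expression levels span orders of magnitude
between genes, while a constitutive gene varies a few-fold between
tissues.

Cytosine positions are drawn once per plan and shared by all tissues;
per-tissue randomness uses a sub-stream derived from the plan seed and
tissue index, so any tissue is reproducible in isolation and identical
plans are byte-identical end to end.

What the simulator deliberately does not emulate: transposon-driven
methylation structure, gene-body CG methylation gradients, correlated
coverage (GC bias, mappability), bisulfite non-conversion error,
allele-specific methylation, and correlated expression programs beyond
single-tissue spikes. Passing tests therefore demonstrate the
correctness of the procedures under the stated statistical structure, not
that real castor-bean-scale data would yield any particular counts — the
headline numbers of methylome studies depend on the deposited reads and
on upstream alignment choices that are out of scope here.

One separation property deserves a caveat: with background CG 0.80 and
planted level 0.01, considered windows separate into two clean modes, but
windows *straddling a valley edge* necessarily average the two and fall in
between. The test suite asserts that every window observed between the
modes straddles an edge and that fully-inside/fully-outside windows
separate strictly, which is the attainable form of the bimodality claim.

## Numerical and degenerate-input choices

* Weighted levels are undefined (NA) when a context has no covered
  cytosines in a region; such windows are never considered.
* All-zero expression vectors have undefined entropy: NA with a warning,
  never specific.
* `max1` normalization of an all-zero profile errors with advice, rather
  than producing NaNs.
* Nearest-gene ties break by smaller gene start, then gene id; valleys on
  gene-free chromosomes are reported distal at infinite distance and
  dropped (with a message) from distal-gene pairing.
* Coordinates are handled as 1-based closed `GRanges` internally — the
  native convention of the R genomics stack — with BED/bedGraph 0-based
  half-open input converted at the single parse boundary and written back
  out on the BED convention, so files round-trip exactly.
* Problem sizes in the shipped tests — 200-kb oracle chromosomes, the 2-Mb
  five-tissue recovery design, 2000-gene atlases, 2000-peak calibration
  sets — were chosen as the smallest sizes at which the binomial/LLN
  margins in the assertions are comfortable.

## Limitations

The package consumes methylation calls, peak sets and FPKM tables; it does
not align reads, call methylation, call peaks, or compute differential
peaks. The specificity rule is a transparent stand-in, not a SEGtool
reimplementation. Conserved-valley derivation uses strict all-tissue
intersection; studies that report a reference-tissue or majority rule will
count differently.
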