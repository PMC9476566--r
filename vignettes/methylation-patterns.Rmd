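---
title: "Gene-body methylation patterns in sparsely methylated genomes"
author: "sparseMethylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-body methylation patterns in sparsely methylated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseMethylome)
```

## The analysis problem

Vertebrate genomes methylate most of their CpG dinucleotides and use that
methylation largely to silence transposons. Many invertebrates — cephalopods
prominently among them — do the opposite: fewer than 10% of CpGs carry
5-methyl-cytosine, transposons are essentially unmethylated, and the signal
concentrates on the bodies of a subset of genes whose expression tends to be
high and stable across tissues. Analysing such a methylome is a pipeline of
small, well-defined steps: read per-cytosine bisulfite calls, classify sites,
place them in genomic context, summarize profiles over scaled gene
coordinates, cluster genes by their body methylation, and relate the clusters
to expression. This package implements that pipeline as composable functions
over Bioconductor containers, with a synthetic-data generator that emulates
the statistical structure of a sparse methylome so that every stage can be
verified against known truth without any external download.

## Data model and conventions

A `CpGTable` holds one row per strand-specific CpG cytosine: position,
strand, methylation percent, methylated and total read counts. Internally
positions live in a width-1 `GRanges`, hence 1-based coordinates — the
Bioconductor convention — and all conversion from external dialects (CGmap's
1-based positions and nucleotide-column strand encoding, Bismark coverage
rows, GFF's 1-based inclusive spans, 0-based BED on export) happens only at
the I/O boundary, where round-trip tests pin it down. The two strands of a
CpG dyad are kept as distinct sites throughout, matching how genome-wide CpG
counts are conventionally reported (both strands); an optional
`destrandCpGs()` merges dyads by summing counts but nothing downstream
requires it.

Classification uses the conventional thresholds for sparse methylomes:
below 20% unmethylated, above 80% methylated, everything else intermediate.
Both inequalities are strict, so a site at exactly 20% or 80% is
intermediate; the boundary convention is asserted in the tests because
published descriptions of these cutoffs alternate between "below/above" and
"</>" wording.

Genomic context is assigned with precedence promoter > exon > intron >
intergenic over the union of all transcripts, the behaviour of mainstream
annotation toolkits, which keeps the map single-valued when transcripts
overlap. The promoter is 2,000 bp upstream of the TSS by default — the same
width as the flank used in gene-level heatmaps — and is a parameter, since
no universal definition exists. Intergenic CpGs are further split into
transposable-element CpGs (DNA, LTR, LINE, SINE), non-TE-repeat CpGs
(Satellite, Simple repeats, other repetitive elements) and repeat-free
CpGs; a CpG under both a TE and a non-TE repeat counts as TE.

## Metaplots

Regions of unequal length are rescaled to `B` equal bins (30 for
transcripts, 15 for repeats, following the conventional choice by average
region length); a position at strand-aware distance `d` from the 5' end of
a length-`L` region falls in bin `floor(B * d / L)`, clamped to the last
bin. Each bin pools the methylation percentages of every CpG falling in it
across all regions, and is summarized by a winsorized mean: values outside
the bin's 1st-99th percentile range (percentiles by linear interpolation)
are clipped to those percentiles before averaging, which keeps a handful of
fully methylated outlier CpGs from dominating a mostly unmethylated bin.
With limits (0, 100) the winsorized mean is exactly the arithmetic mean,
which the tests use as a degenerate-case anchor. The shaded band is the
normal-approximation 95% confidence interval for the mean,
`1.96 * sd / sqrt(n)`, computed on the clipped values; winsorization
granularity (per bin, on pooled values) and the CI's use of clipped values
are choices this package fixes and documents, since "winsorized mean
(1-99 percentile)" alone does not determine either.

`flankedMatrix()` builds the per-transcript display matrix behind
methylation heatmaps: 20 fixed 100-bp windows across a 2,000-bp upstream
flank, 30 length-scaled body bins, 20 downstream windows, upstream always
on the left. Flank resolution is a parameter; 100-bp windows are simply a
reasonable default at the 2-kb flank width.

## Methylation patterns by one-dimensional k-means

The clustering input is deliberately minimal: the mean methylation percent
of all covered CpGs between TSS and TTS of each transcript ("body mean").
The flanked matrix is used only for display; clustering on the scalar body
mean is what "k-means on the methylation average across each transcript"
means, and it makes the problem one-dimensional.

`kmeansPatterns()` runs Lloyd's algorithm with k-means++ seeding,
best-of-10 restarts by within-cluster sum of squares, followed by an exact
boundary refinement that the one-dimensional structure affords: at any
k-means fixed point the clusters are contiguous runs of the sorted values,
so each cluster boundary can be re-optimized exactly given its neighbours
(coordinate descent on the run boundaries) until no move improves the
objective. On small instances this reliably attains the global optimum
computed independently by dynamic programming, which the test suite checks
on random instances; plain restarted Lloyd misses the optimum on a few
percent of such instances, which is why the refinement pass exists.
Clusters are then relabelled 1..k by strictly descending center — pattern 1
(MP1) most methylated, MP4 unmethylated — and ties in nearest-center
assignment break toward the lower label. `k = 4` is the default because
four patterns is what gene-body methylation in this kind of genome
resolves into: fully methylated (MP1), methylated except at the TSS (MP2),
unmethylated over the 5' third (MP3), unmethylated (MP4). The
transcript-inclusion rule is a parameter (`min_cpgs`, default 1: any
covered CpG qualifies a transcript), since published pattern counts imply
some transcripts are dropped without the rule being stated.

A clustering defined in one reference sample is carried to other samples
with `applyReferenceOrder()`, which keeps each transcript's reference label
and reports the other samples' body means under that fixed grouping —
cross-sample comparisons re-use the reference ordering rather than
re-clustering.

## Expression integration

Expression enters as TPM matrices and is analysed as `log2(TPM + 1)`.
The percentile curve ranks transcripts by expression (average ranks for
ties, deterministic id tie-break), cuts them into 100 equal-frequency
groups, and plots each group's mean body methylation — the standard way to
show that methylation tracks expression through the mid-range. Differences
in expression between patterns are tested with the unpaired Kruskal-Wallis
test followed by Dunn's pairwise z statistics on the shared tie-corrected
ranking; the pairwise p-values are Bonferroni-adjusted by default (the
adjustment is a parameter — "Dunn's multiple comparisons test" does not fix
one). Tissue transcriptomes are clustered on row z-scores with Euclidean
distance and complete linkage (the common heatmap default; linkage is a
parameter), cut at k = 13. GO over-representation uses the upper-tail
hypergeometric test with Benjamini-Hochberg adjustment and reports the
gene ratio observed/expected, with the universe defaulting to all genes
carrying at least one term — parameterized, as published analyses rarely
state their universe.

## The synthetic-data generator

`generatorConfig()` encodes the study conditions; `generateGenome()`
produces a genome in which those conditions hold by construction, plus the
complete ground truth. Design highlights:

- **Binary site model.** 5-methyl-cytosine is a binary mark per site, so a
  compartment's methylation "level" is modelled as the *fraction of its
  sites that are methylated* (true level 0.95) versus unmethylated (0.02).
  Inside gene bodies that fraction is honoured exactly per gene segment
  (random positions, exact count), so a gene's realized body mean carries
  only the designed per-gene variability (`gene_level_sd`, 5 points) and
  not additional binomial sampling noise; elsewhere sites are independent
  Bernoulli draws. A configured fraction of CpGs (7%, matching the
  intermediate fraction such methylomes show) instead receives a uniform
  intermediate level, emulating tissue heterogeneity; these are placed
  outside gene bodies so the archetype body means stay crisp.
- **Archetypes.** Four piecewise-constant positional profiles over
  promoter / body / downstream in relative coordinates: MP1 at level 0.75
  throughout; MP2 depleted over the promoter and the 5' third of the body,
  0.75 elsewhere; MP3 depleted over the 5' third, then a half-level and
  full-level 0.60 step (a coarse 3' ramp); MP4 at background 0.02. The
  implied analytic body means — 75, 50.7, 30.7, 2 percent, computed by
  `archetypeBodyMeans()` — are what the k-means centers recover on
  generator output, and they sit where the four patterns' centers fall in
  real sparse methylomes. Mixture weights default to the observed relative
  pattern sizes (about 14/23/17/46%).
- **Genome layout.** Gene cassettes (2-kb flank, CpG-dense 600-bp body cut
  into 3 exons, 2-kb flank) are packed deterministically, followed by an
  intergenic zone holding TE insertions (level 0.05), satellite arrays
  (0.15 — the repeat exception), simple/other repeats (0.04) and
  repeat-free space (0.03), sized so 85% of CpGs are intergenic. The
  background sequence contains no CG dinucleotide except the planted ones,
  so the truth catalog *is* the genome's CpG complement — `countGenomeCpGs`
  on the emitted FASTA equals twice the catalog size exactly.
- **Read model.** Per strand and site: depth ~ Poisson (WGBS mean 30;
  RRBS retains a random 3% of dyads at mean 40), per-read methylation
  probability ~ Beta centred on the site's true level (precision 100),
  methylated reads ~ Binomial. RRBS is modelled as random dyad retention
  rather than explicit restriction digestion: the downstream analyses
  depend only on sparsity, not fragment chemistry.
- **Expression coupling.** Expected log2(TPM+1) rises linearly with the
  gene's true body methylation (intercept 0.5, slope 0.055 per percent),
  with tight cross-tissue noise for archetypes 1-3 and zero-inflated bursts
  for archetype 4 — reproducing high stable expression of methylated genes,
  silencing or erratic expression of unmethylated ones, and a monotone
  methylation-expression relation through the 1.5-4.5 log2(TPM+1)
  mid-range.

All randomness flows from one master seed, so equal configurations produce
byte-identical outputs. What the generator does *not* emulate — and what
passing its tests therefore cannot certify about real data — includes
realistic sequence composition and repeat families, overlapping and nested
transcripts, TEs inside introns, bisulfite conversion failure, coverage
biases along fragments, and any biological coupling between methylation and
expression beyond the designed monotone trend.

## Numerical choices and degenerate inputs

Percentiles use linear interpolation (`quantile` type 7). Empty metaplot
bins report a missing mean with `n = 0`; single-value bins report CI 0.
k-means refuses fewer distinct values than clusters and reports which
degeneracy it hit; strictly descending centers are enforced after
relabelling. Transcripts without covered CpGs are excluded from body means
and listed in an exclusion report rather than silently dropped. Zero-depth
simulated sites are simply not covered. File-level rounding is tolerated at
0.01 percentage points when checking a coverage file's percent column
against its counts, and methylation percentages are recomputed from counts
on read so full precision survives the round trip.

## Problem sizes used in the checks

The packaged checks run the full pipeline on the default configuration
(2,000 genes, 4 scaffolds, about 1 million CpG dyads, 13 tissues) once and
reuse it; structural and oracle checks use reduced instances (120-300
genes, a few hundred CpGs) where exhaustive or brute-force reference
implementations are feasible. Statistical calibration uses 1,000 null
simulations of 4 groups of 200.

## A worked run

```{r example, eval = FALSE}
cfg <- generatorConfig()
sim <- generateGenome(cfg)

wgbs <- simulateMethylome(sim, "WGBS", "brainA", seed = 11)
wgbs <- classifyCpGs(wgbs)
summarizeMethylome(wgbs, countGenomeCpGs(sim$genome))

wgbs <- partitionIntergenic(annotateCpGs(wgbs, sim$features), sim$repeats)
contextComposition(wgbs)

means <- transcriptMeanMethylation(wgbs, sim$features)
patterns <- kmeansPatterns(means, k = 4, seed = 3)
patterns

tpm <- simulateExpression(sim, seed = 5)
expr <- logTpm(tpm[, 1]); names(expr) <- rownames(tpm)
mpExpressionTest(expr, patterns)$kw
percentileMethylationCurve(expr, means)
```

## Known limitations

The pipeline treats methylation symmetrically across the dyad and does not
model strand asymmetry; Bismark coverage strand is only resolved when a
genome is supplied. There is no differential-methylation statistic between
samples (cross-sample work is descriptive: common-site joins and reference-
ordered pattern transfer). GO enrichment does no term-graph propagation or
semantic reduction. The k of the expression clustering and of the pattern
clustering are user choices; nothing in the package selects them
automatically.
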