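---
title: "Methods: miRNA target-site distribution across gene classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA target-site distribution across gene classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical procedure the package implements,
the conventions and numerical choices behind it, what the synthetic-data
generator does and does not emulate, and the known limitations. It states
no empirical result beyond what the package's own tests and the
acceptance script compute.

## The procedure

The object at the center of everything is the binary gene-by-miRNA
incidence matrix of one species. From a table of predicted sites, weak
predictions are first removed per category: conserved sites above the
50th percentile of score strength and nonconserved sites above the 75th
are retained (context+ scores are negative, more negative meaning
stronger predicted repression, so "strength" is the negated score).
Surviving records collapse to incidence: several sites of the same miRNA
in one 3'UTR count once, while a single site recognized by k distinct
miRNAs contributes to k matrix entries. The per-gene row sum
`n_g` — the distinct-miRNA count — is the statistic every downstream
analysis stratifies on:

* **Quartile tails.** Q1 holds genes with `n_g` strictly below the
  nearest-rank 25th percentile of the count distribution, Q4 those
  strictly above the 75th. Strict inequalities mean genes sitting exactly
  on a threshold belong to neither tail; with heavily tied counts both
  tails can legitimately be empty (the function warns).
* **Vigintiles.** Genes sorted ascending by `(n_g, gene_id)` and split
  into 20 contiguous bins whose sizes differ by at most one. The
  gene-id tie-break makes the assignment deterministic. Vigintile scatter
  plots pair the bin mean of `n_g` with the bin mean of a gene-level
  covariate (CV, GC, dinucleotide ratio, conservation), and the monotone
  association is summarized by the Spearman correlation of the 20 bin
  means.

Around this core:

* **Expression variability** is the coefficient of variation
  `theta = sigma / mu` per gene across samples, with the sample
  (n-1) standard deviation. Expression is used on the scale provided;
  `log2_transform = TRUE` is available because public intensity panels do
  not always document their scale. Q1-vs-Q4 distributions are compared
  with the two-sample Kolmogorov-Smirnov test.
* **Promoter noise proxies** are computed on +/-1 kb of the TSS: the GC
  fraction (N bases excluded from numerator and denominator) and the
  ratio of nucleosome-favoring (GC, CG, GG) to disfavoring (AA, CA, AC)
  dinucleotides, counted over all overlapping length-2 windows (so "GGG"
  contains GG twice); windows containing N are skipped. A zero
  disfavoring count leaves the ratio undefined and the gene is excluded
  from bin averages rather than imputed.
* **Conservation** is the length-weighted mean track score over a gene's
  3'UTR (and separately CDS) intervals. Bases the track does not cover
  are excluded from the denominator, because conservation tables score
  only aligned bases; treating gaps as zero would conflate alignment
  coverage with conservation.
* **Repeats.** A gene is flagged when >= 1 bp of an LTR or SINE element
  intersects its 3'UTR (half-open intervals, so abutting features do not
  touch). Reported: flag fractions in Q1/Q4 and a within-Q4 rank-sum
  comparison of `n_g` between flagged and unflagged genes.
* **Co-localization.** A miRNA locus is co-localized with a gene when it
  intersects the gene's full genomic span — introns included, since
  host-gene co-transcription is the mechanism of interest — extended by
  20 kb on both sides. With the half-open convention a locus starting
  exactly 20 kb upstream is included.
* **Cross-species trends.** Within each species, `n_g` is divided by the
  mean count over all genes present in that species' matrix (so the
  normalized counts average to exactly 1 per species); species with
  different numbers of annotated miRNAs become comparable. Group means of
  normalized counts, ordered by distance rank from the reference, are
  summarized by a Spearman trend statistic. Distances enter only as an
  ordering — no branch lengths.

## Statistical tests

* **Hypergeometric** enrichment (`P(X >= x)`) and depletion
  (`P(X <= x)`) via `stats::phyper`, which computes in log space, so
  p-values far below double precision of 1 survive. The universe is a
  required argument: enrichment against an unstated universe is
  meaningless, and reasonable choices (all matrix genes vs. all expressed
  genes) genuinely differ.
* **Wilcoxon rank-sum** with midranks. For pooled size n + m <= 16 the
  p-value is exact by full enumeration of the `choose(n+m, n)` midrank
  sums — `stats::wilcox.test` has no exact path under ties, which tied
  count data hit constantly. Above 16, the normal approximation with tie
  correction and continuity correction is used (it matches
  `wilcox.test(exact = FALSE)` to 10 digits in the untied case). The
  crossover at 16 keeps the enumeration below ~13k subsets, i.e.
  effectively instant. At n = m = 8 the approximation sits within about
  0.011 of the exact enumeration for mid-range p-values.
* **Kolmogorov-Smirnov**: D is the sup distance of the two ECDFs over the
  pooled points; the p-value uses the asymptotic Kolmogorov distribution
  with effective size nm/(n+m), evaluated by the alternating series for
  t >= 1 and the Jacobi-theta transform for t < 1 (the alternating series
  converges too slowly there).
* **Spearman** is the Pearson correlation of midranks; a constant vector
  makes it undefined and the functions return `NA` with a notice instead
  of a fabricated 0.

All p-values are raw. The analyses report a handful of planned tests, not
a genome-wide scan, so no multiplicity correction is applied anywhere by
default; `adjust_bh()` exists for users who want FDR control.

## Conventions and degenerate inputs

All genomic coordinates inside the package are 0-based half-open; GTF
input (1-based inclusive) is converted at the parse boundary, and the TSS
of a minus-strand gene is its rightmost transcript coordinate. Interval
lists are union-normalized on entry.

Two percentile conventions coexist deliberately. Quartile thresholds use
nearest-rank (`sorted[ceil(p/100 * n)]`). The site filter asks a subtly
different question — "is this site *above* the p-th percentile?" — and
uses the threshold `sorted[floor(p/100 * n) + 1]` with ties kept, so that
the retained fraction is within 1/n of (100-p)/100 (for distinct scores)
and an all-tied category is retained whole. A single convention cannot
satisfy both behaviours at once.

Degenerate inputs are handled explicitly rather than silently: empty site
categories make the filter a no-op with a notice; constant counts empty
both quartile tails with a warning; genes with non-positive mean
expression are dropped from CV computation with a count; all-N sequences
and zero-disfavoring promoters yield `NA` features; constant trajectories
yield `NA` trends. Record counts for every drop are surfaced so the
accounting is visible in the pipeline report.

Promoter sequences are interpreted on the gene's annotated strand
(minus-strand promoters reverse-complemented before counting) because "a
gene's promoter composition" reads most naturally sense-stranded; GC
content is strand-symmetric anyway, and `strand_mode = "plus"` switches
to counting sequences exactly as given. The mirSVR cutoff for
miranda-dialect tables defaults to -0.1 and is user-configurable, since
"a good mirSVR score" has no canonical numeric value. The cross-species
normalization mean is over all genes in the species' matrix (not only
genes with sites) — "the average number of sites in that species" reads
as the full per-species distribution — with `nonzero_only = TRUE`
available. When several species tables are analysed, the score-percentile
filter is applied per species, each table being filtered against its own
score distribution. CDS conservation is averaged gene-level and
length-weighted across a gene's CDS intervals rather than per-exon.

## The synthetic generator

`synthetic_config()` fixes the study conditions; every generator is a
deterministic function of it (same configuration, byte-identical output;
each generator derives its own RNG stream from the seed, so the parts can
be regenerated independently).

One latent noise level per gene, drawn from a truncated normal whose mean
differs by class (regulatory 0.7, non-regulatory 0.3, SD 0.12), drives
all three planted relationships: promoter per-base GC probability
`0.4 + 0.3 * noise`, lognormal expression `sdlog = 0.1 + 0.8 * noise`,
and the per-gene site rate
`lambda_g = rate_class * exp(1.5 * (noise - class mean))` with class
rates 60 (regulatory) and 12 (non-regulatory). The shared latent
reproduces the mutual correlations among counts, CV and GC without
asserting any causal direction. The continuous rate coupling matters:
with purely class-determined rates the fifteen non-regulatory vigintile
bins would have exchangeable covariate means, which caps the bin-level
Spearman near 0.75 no matter how strong the class contrast is; the
log-linear term gives the within-class gradient that makes the vigintile
scatters monotone throughout, as the planted relationships intend.

Species evolve on a star topology read from a shared ancestor: the
reference genome is the *endpoint* of site turnover along its own
lineage, so a species at distance rank d (which diverged before part of
that turnover) retains each regulatory-gene site of the reference with
probability `exp(-0.06 d)` and carries `Poisson(0.8 d)` additional
ancestral miRNAs per non-regulatory gene. This is what makes Q1
trajectories rise and Q4 trajectories fall with distance: the mechanism
is loss in non-regulatory and gain in regulatory genes along the
reference lineage, observed from increasingly ancestral vantage points.
Conservation is planted in 25-bp bins (3'UTR means 0.75/0.35 and CDS
means 0.5/0.8 for regulatory/non-regulatory — the CDS contrast
deliberately inverted); LTR/SINE elements are dropped into 3'UTRs with
class probabilities 0.6/0.17, plus occasional LINE decoys the class
filter must ignore; miRNA loci land inside regulatory gene spans with
probability 0.2 plus uniform background loci. Duplicate site records
(probability 0.3, second 3'UTR position) exercise the collapsing rule.

`null_config()` keeps the dimensions and removes every coupling: equal
class rates, zero slopes, zero turnover, class-independent conservation
and repeat probabilities. It exists to verify the pipeline does not
manufacture signals (binning, normalization and filtering are all
rank-based operations with ample opportunity for artefacts).

What the generator does **not** emulate: sequence-level site matching
(sites are abstract gene-miRNA records, as in the binary matrix itself),
linkage between neighbouring genes, array normalization artefacts and
batch structure in expression, realistic repeat length/nesting
distributions, phylogenetic correlation between species (the star
topology makes species independent given the reference), and ortholog
loss (the map is identity). Passing the recovery tests therefore shows
the pipeline correctly extracts planted structure of the assumed form —
not that real data satisfy those assumptions.

## Problem sizes in the test suite

The stochastic validation runs at 2000 genes, 300 miRNAs, 100 expression
samples and 10 species, with 20 generator seeds for the recovery and
null-safety checks and 5000 replicates (n = m = 30) for the type-I-error
calibration of the rank-sum and KS wrappers; exactness checks (oracle
enumeration, invariants) use small randomized cases where full
enumeration is feasible (universe <= 12 for the hypergeometric, pooled
n <= 16 for the rank-sum, tracks <= 1 kb for conservation). These sizes
were chosen so the planted effects are comfortably detectable while the
whole suite runs in a few minutes on one CPU.

## Limitations

* The analyses are correlational by construction; nothing here
  distinguishes the "selective inclusion" reading (regulatory genes
  retained/gained sites) from confounded alternatives — the package
  quantifies the associations, it does not adjudicate the mechanism.
* Prediction tables are taken at face value: no re-scoring, no
  sequence-level validation, and the binary matrix discards score
  magnitude after filtering by design.
* The KS p-value is asymptotic; with the group sizes these analyses see
  (dozens to hundreds) that is adequate, but for very small groups an
  exact variant would be preferable.
* bigWig conservation tracks are not read directly; convert to bedGraph
  first.
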