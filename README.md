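# mirsites

Analysis of how predicted miRNA target sites distribute across genes.

Animal miRNAs repress messenger RNAs through short complementary sites in
3'UTRs, and target-prediction tools (TargetScan, miRanda) emit large tables
of such sites per species. A recurring observation in regulatory genomics
is that this targeting is not allocated uniformly: genes encoding
regulatory proteins (transcription factors in particular) tend to carry
sites for many more *distinct* miRNAs than housekeeping or structural
genes, and this bias tracks expression variability, promoter sequence
composition, 3'UTR conservation and evolutionary distance. `mirsites`
packages that whole analysis as tested, composable R functions for anyone
who wants to run it on their own prediction tables — plus a seeded
synthetic-data generator so the full pipeline can be validated end to end
with no external downloads.

## What it computes

Starting from per-species site tables (TargetScan "site context+ score"
layout, miRanda/mirSVR, or a generic TSV):

1. **Site filtering and the binary interaction matrix.** Weak sites are
   removed per category — sites above the 50th percentile of context+
   score strength are kept for conserved sites, above the 75th for
   nonconserved. Records then collapse to a binary gene x miRNA incidence
   matrix: several sites of the same miRNA in one 3'UTR count once; a site
   shared by k distinct miRNAs counts k times. The per-gene row sum is the
   *distinct-miRNA count* n_g used everywhere downstream.
2. **Stratification.** Genes split into quartile tail groups (Q1: n_g
   strictly below the nearest-rank 25th percentile; Q4: strictly above the
   75th) and into vigintiles (20 equal-size rank bins of n_g).
3. **Expression variability.** Per-gene coefficient of variation across a
   sample panel, theta = sigma/mu (sample SD over mean), compared between
   Q1 and Q4 with a two-sample Kolmogorov-Smirnov test.
4. **Promoter noise proxies.** Over +/-1 kb of the TSS: GC fraction, and
   the ratio of nucleosome-favoring (GC, CG, GG) to disfavoring (AA, CA,
   AC) dinucleotides, both read as proxies for nucleosome occupancy and
   intrinsic transcriptional noise.
5. **Genomic overlays.** Length-weighted mean conservation over 3'UTR and
   CDS intervals (uncovered bases excluded from the denominator); LTR/SINE
   repeat overlap flags with quartile fractions and a within-Q4 rank-sum
   comparison; 3'UTR length vs n_g; co-localization of miRNA loci within
   -/+20 kb of gene spans.
6. **Cross-species trajectories.** Per species, n_g is normalized by the
   species' mean count; group means of the normalized counts, ordered by
   evolutionary distance rank, are summarized by a Spearman trend
   statistic (+1 = monotone increase with distance).
7. **Statistics.** Hypergeometric enrichment/depletion (explicit universe
   required), Wilcoxon rank-sum (exact enumeration with midranks for
   pooled n <= 16, tie-corrected normal approximation otherwise), KS
   (asymptotic), Spearman. All p-values are reported raw.

Every user-facing function takes a data frame first and returns a tibble,
so stages chain with the pipe; result objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(mirsites)

cfg <- synthetic_config(seed = 42, n_genes = 300, n_mirnas = 80,
                        n_samples = 30, n_species = 5)
sim <- simulate_study(cfg)

sites <- filter_sites_by_percentile(sim$sites$s00)
mat <- build_interaction_matrix(sites, species_id = "s00",
                                gene_universe = sim$labels$gene_id)
mat
#> <interaction_matrix> s00: 300 genes x 80 miRNAs, 3304 interactions

strata <- assign_quartile_groups(mat)
strata
#> <gene_strata> thresholds 4/14: Q1 52 genes (< 4), Q4 74 genes (> 14)

cv <- expression_cv(sim$expression)
cv_group_comparison(cv, strata)
#> # A tibble: 1 x 6
#>    ks_D  p_value mean_q1 mean_q4  n_q1  n_q4
#>   <dbl>    <dbl>   <dbl>   <dbl> <int> <int>
#> 1 0.904 4.27e-22   0.296   0.704    52    74
```

The thresholds 4/14 are the nearest-rank quartile cut-offs of the
distinct-miRNA counts; the KS distance 0.90 (p = 4.3e-22) says the
coefficient-of-variation distributions of the low- and high-count groups
barely overlap — highly targeted genes are the variable ones, exactly the
structure the generator plants. The orchestrator runs every stage at once
and records skipped inputs explicitly:

```r
rep <- run_pipeline(sim)
rep
#> <mir_report>
#>   matrix                 ok
#>   stratify               ok
#>   promoter               ok
#>   expression             ok
#>   gene_set_enrichment    ok
#>   conservation           ok
#>   repeats                ok
#>   utr_length             ok
#>   colocalization         ok
#>   cross_species          ok
rep$summary$cross_species[c("q1_trend", "q4_trend")]
#> $q1_trend [1] 0.7   $q4_trend [1] -1
```

Positive Q1 and negative Q4 trends mean sparsely targeted genes carry
relatively more sites in distant species while heavily targeted genes
carry relatively fewer — the signature of site loss in non-regulatory
genes and gain in regulatory genes along the reference lineage.

On-disk workflows use the same functions through
`write_simulation_bundle()` / `bundle_inputs()` (plain TSV, FASTA, BED,
bedGraph formats) and `write_report()`, which emits a versioned
`report.json` plus one TSV per backing table, byte-identical across
re-runs on the same inputs.

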