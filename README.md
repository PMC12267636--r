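# darlinker

Downstream integration of ATAC-seq and RNA-seq for aging and
insulin/IGF-like signaling (IIS) studies in *C. elegans*-scale genomes.
`darlinker` takes peak-by-sample and gene-by-sample count tables and turns
them into a joined regulatory story: which regions change accessibility,
which of those changes are *transcriptionally relevant* (the closest gene
changes expression concordantly), where in the genome they sit, which
transcription factors could bind them, and what the matching lifespan data
say.

It is written for analysts who already have consensus peaks, counts and
annotation (from any upstream pipeline) and want a tested, scriptable R
workflow for the integration, enrichment and survival statistics — plus a
synthetic-data generator with planted ground truth, so every stage can be
exercised and benchmarked without any external download.

## What it computes

**trDARs.** A differentially accessible region (DAR) is called from counts
with a common-dispersion negative-binomial Wald test (TMM normalization,
Benjamini–Hochberg FDR). A DAR is *transcriptionally relevant* (a trDAR)
when its closest gene is a significant DEG in the concordant direction:

    (accessibility, expression) ∈ {(open, up), (closed, down)}

**Genomic context.** Each region gets exactly one category by precedence
Promoter > 5' UTR > 3' UTR > Exon > Intron > Distal Intergenic, with the
promoter window spanning −1500/+500 bp around the TSS (strand-aware).
"distNC" (distal non-coding: Intron or Distal Intergenic, and nothing
higher) is the enhancer proxy.

**Directional overlaps.** For two contrasts x and y, "x > y" asks whether
regions *open* in x coincide with regions *closed* in y more often than
chance, via a two-sided Fisher exact test on the shared consensus-peak
universe — the machinery behind anti-concordance questions such as "do
regions opening under reduced IIS close during normal aging?".

**Enrichment.** One exact-Fisher engine serves chromatin-state enrichment
(with `ov_da` / `ov_nda` / `tot_tgt` bookkeeping and state aggregation by
summed counts), TF-motif enrichment (Homer-format PWMs, exact
score-distribution thresholds computed by dynamic programming, both-strand
scanning), ChIP-peak overlap enrichment, and gene-set overlap against
cell-type signatures (> 100 counts), age-regulated DEG lists (p < 0.05,
fold change above/below 1) or GO-style collections.

**Lifespans.** Kaplan–Meier product-limit estimates with Greenwood
variance, two-sided log-rank tests, and the bootstrap median procedure:
100 resamples of individuals, an interpolated median per replicate
(linear between the two step points straddling 50% survival), the median
of those replicate medians as the point estimate and their standard
deviation as its SE. Reporting helpers give percent median-lifespan change
and suppression percentages.

## Worked example

```r
library(darlinker)

# a synthetic study: 240 peaks/genes, two contrasts (aging, reduced IIS),
# anti-concordant effects planted in distal non-coding regions only
res <- run_trdar_pipeline(seed = 1)

glance(res$trdars$iis)
#> # A tibble: 1 × 5
#>   n_trdars n_open_up n_closed_down n_genes n_distnc
#>      <int>     <int>         <int>   <int>    <int>
#> 1       59        52             7      59       42

res$overlap$distNC |> dplyr::filter(relation == "x_gt_y",
                                    contrast_x == "iis")
#> # A tibble: 1 × 10
#>   contrast_x contrast_y relation   n_x   n_y  n_xy n_universe odds_ratio
#>   <chr>      <chr>      <chr>    <int> <int> <int>      <int>      <dbl>
#> 1 iis        aging      x_gt_y      42    61    36        240       41.5
#> # ℹ 2 more variables: p <dbl>, fdr <dbl>

res$survival
#> # A tibble: 3 × 8
#>   group           n n_events median    se median_full pct_change logrank_p
#>   <chr>       <int>    <int>  <dbl> <dbl>       <dbl>      <dbl>     <dbl>
#> 1 control       150      143   17.6 0.418        17.6      -49.8  8.37e-61
#> 2 daf2          150      140   34.9 1.52         35.0        0   NA
#> 3 daf2_lin39i   150      144   18.2 0.533        18.2      -47.8  3.66e-56
```

Reading the output: of 240 consensus peaks, 59 are trDARs under reduced
IIS (52 opening with an induced closest gene); 36 of the 42 IIS-opening
trDARs overlap aging-closing trDARs in distNC regions (odds ratio 41.5) —
the planted anti-concordance — while the same test restricted to promoters
is null. The lifespan table shows the reduced-IIS group living twice as
long as control (bootstrap median 34.9 vs 17.6 days) and the knockdown
group losing 47.8% of that median (two-sided log-rank p ≈ 4e-56), close to
the configured 50% reduction.

Every result type has `tidy()` / `glance()` methods and an `autoplot()`
(volcano for differential tests, dot plot for enrichments, step curves
with confidence bands for survival fits).

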