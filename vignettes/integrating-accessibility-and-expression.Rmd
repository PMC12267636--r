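---
title: "Integrating chromatin accessibility, expression, regulatory context, and lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating chromatin accessibility, expression, regulatory context, and lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darlinker)
```

`darlinker` implements the downstream half of a multi-omics aging study:
given consensus ATAC peaks, count tables, genome annotation, chromatin
states, TF motifs and lifespan scoring tables, it identifies
transcriptionally relevant accessibility changes, places them in genomic
and regulatory context, and quantifies the matching survival phenotypes.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic benchmark does and does not establish.

## The model, stage by stage

### Differential counts

Both ATAC peaks and genes are tested the same way. Let $c_{ij}$ be the
count for feature $i$ in sample $j$. Samples are scaled by *effective size
factors* $f_j$ — library size times the trimmed-mean-of-M-values (TMM)
factor, rescaled to geometric mean one — so normalized counts
$y_{ij} = c_{ij}/f_j$ share one scale. The TMM computation is delegated to
`edgeR::calcNormFactors()` (reference sample by upper-quartile proximity,
30% trim on M-values, 5% on A-values, precision-weighted mean).

Counts are modelled as negative binomial with a **common dispersion**
$\phi$ shared by all features — deliberately *not* tagwise: with two or
three replicates per group, per-feature dispersions are noise, and the
common-dispersion configuration is the one this analysis is built around.
$\phi$ is estimated by method of moments,

$$\hat\phi = \operatorname{median}_i \;
  \max\!\left(0, \frac{s_i^2 - \bar\mu_i \, c_f}{\bar\mu_i^2}\right),$$

with $s_i^2$ the pooled within-group variance, $\bar\mu_i$ the overall
normalized mean and $c_f$ the mean inverse size factor (the Poisson term
under scaling). Two numerical details matter here:

* $s_i^2$ is *within-group*, so real group differences do not inflate
  $\hat\phi$;
* the median of a variance estimate with $d$ degrees of freedom sits at
  $q_{\chi^2_d}(0.5)/d$ of its mean, so $s_i^2$ is divided by that factor
  first. Without this median-unbiasing the dispersion is ~15% low at
  $n = 3$ vs 3 and the test becomes anticonservative (empirical type-I
  ~0.075 at nominal 0.05; ~0.05 after the correction — the test suite
  checks the band [0.03, 0.07] on 2000 null features).

Significance is a two-sided Wald test on
$\log_2(\hat\mu_B/\hat\mu_A)$ with the delta-method standard error under
$\mathrm{NB}(\mu, \phi)$, followed by Benjamini–Hochberg adjustment. A
half-count is added to each group's total so fold changes stay finite;
features with zero counts everywhere are excluded and reported. The FDR
threshold defaults to 0.05 and is configurable.

For the per-cell-type single-cell comparison the package provides the
Wilcoxon rank-sum test instead (`wilcoxon_de()`), exact (by dynamic
programming over midranks, equivalent to full enumeration) up to 25
observations and normal-approximated with tie and continuity correction
above.

### Annotation and trDARs

Regions live in 0-based half-open coordinates (BED-native; GFF3 is
converted on read). Classification assigns the first matching category in
the precedence order Promoter > 5' UTR > 3' UTR > Exon > Intron > Distal
Intergenic, where a category matches if the region shares one base or more
with any feature of that kind. The promoter window covers signed TSS
distances $[-1500, +500)$ by default, oriented by gene strand; region
strand is ignored (ATAC peaks are unstranded). "distNC" — the enhancer
proxy — is Intron or Distal Intergenic and nothing higher.

The closest gene is the gene whose TSS is nearest the region midpoint,
with equidistant ties resolved to the lexicographically smallest gene id
for determinism. This midpoint-TSS rule is a documented design choice: the
annotation tool used upstream of analyses like this one has
multiple-overlap behavior that is not fully specified by its arguments, so
the package fixes the simplest reproducible rule rather than imitating an
underdetermined one. Regions on chromosomes absent from the annotation are
flagged Distal Intergenic with no closest gene and a warning — never
silently dropped.

A **trDAR** is then definitional: a significant DAR whose closest gene is
a significant DEG in the concordant direction (open with up, closed with
down). Discordant pairs and DARs whose gene is missing from the DEG
universe are tallied in a diagnostics attribute.

### Directional overlaps and enrichment

All overlap questions run through one exact two-sided Fisher engine
(`fisher_two_sided()`): hypergeometric probabilities of all tables with
the observed margins are summed where they do not exceed the observed
table's probability (with a $1 + 10^{-7}$ relative guard against ties lost
to floating point). The odds ratio reported is the sample odds ratio
$ad/bc$; degenerate margins give $p = 1$ and a flagged undefined odds
ratio.

*Directional overlap* ("x > y": open in x, closed in y) forms the 2×2
table over the shared consensus-peak universe: in both sets, x only, y
only, remainder. When the two contrasts were not called on the same
universe, region identity falls back to one-or-more-base overlap. BH
correction is applied across all pairs and relations tested in a run.

*Chromatin-state enrichment* counts, per state, the subset regions
(`ov_da`) and background regions (`ov_nda`) overlapping that state, and
keeps the state's interval count (`tot_tgt`). Sub-states annotating the
same kind of element can be merged by summing these three quantities and
re-testing — the aggregation used for, e.g., paired Polycomb-repressed
states.

*Gene-set overlap* tests a query list against named collections with
background universe minus query. Builders apply the field's selection
rules: cell-type signatures keep genes with strictly more than 100 counts;
age-regulated sets keep genes at p < 0.05 with fold change above 1 (up) or
below 1 (down) on the linear scale — a log-scale switch is provided, and
fold changes exactly at the null value fall in neither set. GO-style
enrichment is the same machinery on a user-supplied term-to-genes table;
no ontology-graph logic is attempted.

One calibration caveat is worth stating: exact Fisher p-values on small
tables are discrete and conservative, so their null distribution is *not*
uniform — a goodness-of-fit test against the uniform would reject in the
conservative direction. Calibration is therefore asserted as what matters
operationally: the fraction of nominal calls under the null stays at or
below the nominal level.

### Motifs

Homer-format PWMs are parsed with a zero guard: rows containing
probabilities below the pseudocount ($10^{-3}$) or not summing to one are
renormalized as $(p + \epsilon)/(\sum p + 4\epsilon)$; well-formed rows
pass through bit-exactly, so write/read round-trips are stable.

Scan thresholds are not heuristic: for each motif the exact distribution
of the log-odds score of a background-model sequence is computed by
dynamic programming over a discretized score lattice (default grid
$10^{-3}$ bits), and the threshold is the smallest score with tail
probability at most $\alpha$ (default $10^{-4}$ per window). If $\alpha$
is below the probability of the maximum score — possible for very short
motifs — the maximum score is returned with a warning. Scanning uses the
same discretized scores (so threshold semantics are exact), covers both
strands, and skips windows containing `N`. The test suite verifies the DP
against complete $4^L$ enumeration.

Enrichment is then binary per region (any window at/above threshold) with
the Fisher engine, motifs BH-corrected together; ChIP mode substitutes
peak overlap for motif hits. Background base frequencies are estimated
from the pooled background sequences with a pseudocount. The default
background for motif questions is the non-trDAR consensus peaks of the
same genomic category; this is configurable, since published enrichment
backgrounds are often underspecified.

### Lifespan statistics

`km_fit()` computes the product-limit estimator with Greenwood variance;
individuals censored at an event time remain at risk at that time.
Confidence bands are log-log (complementary log-log transform), the
convention behind "95% confidence interval" ribbons on survival figures.

The median is *interpolated*: between the two step points
$(t_1, S_1 > 0.5)$ and $(t_2, S_2 \le 0.5)$,
$\hat m = t_1 + (S_1 - 0.5)/(S_1 - S_2)\,(t_2 - t_1)$. A step landing
exactly on 0.5 returns that time; a crossing at the first event returns
the first event time (there is no earlier step to interpolate from — this
also makes the degenerate all-deaths-at-one-day case return that day).

`bootstrap_median()` resamples individuals — `(time, event)` pairs, not
event times — 100 times by default, takes the interpolated median per
replicate, and reports the median of replicate medians as the point
estimate with their standard deviation as SE. Replicates whose survival
never crosses 0.5 are dropped and counted; more than half undefined is an
error. The full-data interpolated median is reported alongside, since
"the bootstrap distribution was used to calculate the median" can be read
either way; both are exposed and the bootstrap summary is the default.
The log-rank test is the standard observed-minus-expected statistic with
hypergeometric variance, $\chi^2_1$ reference.

Reporting helpers mirror the field's figure-box arithmetic:
`percent_median_change()` (one decimal) and `suppression_percent()`
(nearest integer; opposite-sign inputs warn).

## The synthetic benchmark

`simulate_genome()` lays out a small multi-chromosome genome
(240 genes of 6 kb with three exons, UTRs and introns, by default) and
places one 200 bp consensus peak per gene according to a category mix.
The planted structure mirrors the biology the pipeline is meant to
detect:

* half of the distNC peaks close with "aging" (log2FC −2), and 60% of
  those reopen under "reduced IIS" (+2) — the anti-concordance;
* promoter peaks change in each contrast on *disjoint* peak sets with
  random directions — anti-concordance exactly zero, the built-in
  negative control for category-restricted overlap tests;
* every planted peak's closest gene changes concordantly (one peak per
  gene, so the truth table is unambiguous);
* an 8-bp consensus motif is planted in half of the IIS-reopening
  regions; an "enhancer" state covers planted distNC peaks with
  probability 0.9.

`simulate_counts()` draws NB counts (defaults $n = 3$ vs 3, baseline mean
100 with log-normal feature variation, $\phi = 0.1$).
`simulate_lifespans()` draws Weibull lifespans with shape 4 — the steep,
worm-like mortality curve — scaled to target medians (defaults: control
17 d, reduced-IIS 34 d, knockdown-in-reduced-IIS 17 d, i.e. a configured
50% reduction; n = 150 per group, 5% uniform censoring). NB counts and
Weibull lifespans are modeling choices of the benchmark harness, not
claims about real data. All randomness flows from one seed through fixed
stage offsets, so runs are bit-reproducible.

The problem sizes (240 features, 3 replicates, 150 animals per group,
100 bootstrap replicates, 20 decoy motifs) were chosen as the smallest
configuration at which the planted effects are comfortably detectable by
design — 4-fold effects at these settings give Wald z-scores around 5 —
so recovery failures indicate implementation regressions, not sampling
bad luck.

**What passing these benchmarks shows — and what it does not.** Recovery
of planted structure demonstrates that the joining, overlap, enrichment
and survival machinery is correct and calibrated under the generator's
assumptions. Real data differ in ways the generator deliberately omits:
peaks overlap several genes, library sizes and GC content vary,
dispersions are feature-dependent, motif instances degenerate, censoring
is informative. Conclusions about real datasets still require the usual
diagnostics on those datasets.

## Known limitations

* The NB test supports two-group comparisons with a common dispersion; no
  GLM design matrices, batch covariates or tagwise shrinkage. External
  differential tables can be supplied to every downstream stage instead.
* Annotation is gene-level; isoform structure and nested genes beyond the
  precedence rule are out of scope.
* Printed genome-wide DAR/trDAR counts from any specific study depend on
  the upstream read processing and the exact differential-binding
  implementation used there; this package's calls are designed to be
  *calibrated and reproducible*, not to replicate another tool's feature
  lists number for number.
* Right-censoring at the scored day is assumed; interval censoring from
  every-2–3-day scoring is not modelled.
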