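---
title: "Rare-variant filtration, burden comparison and gene-level recurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant filtration, burden comparison and gene-level recurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varburden)
```

## The analysis problem

In a case-control germline exome study — cases from high-risk families
negative for the known major susceptibility genes, matched population
controls — the question is whether rare, functionally severe variants
are enriched in cases, and in which genes. Raw variant calls are far
too noisy and too numerous for direct comparison, so the analysis
proceeds in three steps:

1. **Per-call filtration** down to confident, rare, coding-relevant
   observations.
2. **Burden comparison**: per-sample variant counts per functional
   category, compared between groups.
3. **Gene-level prioritisation** of recurrently mutated genes carrying
   the most damaging variant classes.

`varburden` implements this pipeline over a canonical tab-delimited
representation of annotated calls (one row per sample-variant
observation), with VCF import as a convenience. Read alignment,
variant calling and functional annotation are upstream concerns: the
pipeline consumes their output, modelling only the recalibration PASS
flag, the per-call read support, the population frequencies, and the
functional categories an annotator assigns.

## Filtration model

Stage 1 retains a call only if **all** of the following hold
(defaults in `filter_config()`; all retention bounds inclusive):

| criterion | default | meaning |
|---|---|---|
| VQSLOD | pass | survived the 99.9% tranche sensitivity recalibration |
| region | exonic or splice-site | splice-site = within ±2 bp of an exon-intron border |
| depth | ≥ 10 reads | total coverage at the site |
| alt reads | ≥ 2 | reads supporting the variant allele |
| VAF | 0.20–0.80 | variant allele fraction, the heterozygous band |
| MAF | ≤ 1% | in *every* population database reporting the variant |

A variant reported in no database counts as MAF 0: rarity is the
absence of evidence of commonness, which is how rare-variant studies
treat unobserved alleles. Rejections are attributed to the *first*
failing criterion in the order above, so the filter report's tallies
plus the retained count always reproduce the input count exactly.

Stage 2 removes variants carried by more than 10% of samples in
**both** groups. A variant that common in both arms of a matched
design is far more plausibly a systematic sequencing or alignment
artifact — or population-private common variation the public databases
missed — than a risk allele. The rule is deliberately conjunctive and
symmetric: a variant frequent in cases only is exactly the signal the
study is looking for, and must survive. Carrier fractions use
distinct-sample counts over the registry group sizes; samples flagged
`excluded` (e.g. internal positive controls) count in neither
numerator nor denominator.

Stage 3 classifies each retained call into a single category.
Missense calls are triaged on the PolyPhen-2 HDIV probability:
probably damaging at ≥ 0.957, benign at ≤ 0.452, possibly damaging in
between. The published three-decimal class bounds leave open gaps
(0.452–0.453, 0.956–0.957); scores landing there go to the middle
class, the only assignment that contradicts neither boundary. When
annotations conflict across transcripts, a fixed severity precedence
(frameshift > nonsense > stop-loss > splice-site > in-frame indel >
missense > synonymous > other) makes `categorize()` total and
deterministic — the most severe consequence is the one a
prioritisation pipeline must not lose.

**PDAVs** (protein-damaging allelic variants) are the top of that
ordering: frameshift indels, nonsense and splice-site variants.
Stop-loss substitutions are included by default — they destroy the
termination codon and extend the protein, which is functionally of the
same kind — with `include_stop_loss = FALSE` available for the strict
three-class definition.

## The virtual gene panel

Exome-wide burden signals are diluted across ~20,000 genes. The
packaged cancer-associated gene panel (CAGP, `cagp_panel()`) restricts
attention to 492 genes aggregated from seven published cancer-gene
lists; 177 of them (36%) appear on at least two lists.
`panel_summary()` reports that membership accounting, and
`restrict_to_panel()` keeps calls whose gene symbol is on the panel
(falling back to coordinate overlap when the symbol is missing). The
shipped panel's gene symbols and membership counts follow the
published aggregation; its genomic intervals are synthetic
placeholders, so symbol-based restriction is the supported use.

## Burden comparison

`count_by_sample_category()` produces the samples × categories count
matrix (zero-filled, with an `all` column), and `burden_report()`
compares groups per category: means as group totals over group sizes,
the case/control fold-change ratio, and **both** the equal-variance
Student t-test (df = $n_1 + n_2 - 2$) and the Welch t-test
(Welch–Satterthwaite df), two-sided. The source analyses report
sometimes one test, sometimes the other, without a stated selection
rule; computing both and selecting none keeps the report deterministic
and lets the reader apply whichever convention their field prefers. No
multiple-testing correction is applied (none is applied in the source
design either); the number of categories tested is attached to the
report so users can correct downstream.

Count data are not normal, but with dozens of samples per group the
t-test on per-sample counts is the standard pragmatic choice and its
calibration is verified empirically by the package's own null
simulations (below). Means and ratios are kept at full precision;
rounding to two decimals (four for p-values) happens only in the print
method.

## Gene-level recurrence

`gene_pdav_carriers()` counts, per gene, the *distinct* case and
control samples carrying at least one PDAV — carriers, not variant
occurrences, so two hits in one sample count once.
`select_candidates()` flags genes under a two-arm rule: at least 3
case carriers with 0 control carriers, or at least 4 case carriers
with at most 1 control carrier. The two arms encode the trade-off
that a single control carrier is forgivable only when the case signal
is stronger; both arms are exposed as parameters because the right
thresholds scale with cohort sizes. `pdav_summary()` produces the
cohort-level view of a PDAV set: record, patient and gene counts,
novelty (no dbSNP id), splice-site count, genes with control carriers,
and the distribution of patients by number of mutated genes — the
summary shape in which validated-variant tables are reported. A
transcription of the study's validated table ships as
`pdav_validated_records()`.

## The synthetic cohort generator

No raw exomes are deposited for this design, so the pipeline carries
its own cohort generator (`simulate_cohort()`), and every stage is
tested against data whose ground truth is known by construction.

The generator's defaults *are* the study conditions: 54 cases, 120
controls; per-sample per-category Poisson counts whose rates are the
published control-group means (exome-wide, e.g. synonymous 149.09,
frameshift 8.77, nonsense 6.40 per sample; panel-wide the published
group totals over 120, e.g. panel nonsense 13/120 ≈ 0.108); and a
single injected signal, a 2.39-fold case enrichment of panel nonsense
variants — the effect size the analysis is meant to detect. Depth is
Poisson around 100× (the cohorts' median mean-coverage was ~101–107×),
alt reads binomial around 0.5 of depth clamped to the heterozygous
band, and population MAF mostly unreported with a rare-valued
admixture. Poisson was chosen because the published summaries imply
only means; a negative-binomial switch (`nb_size`) is available for
overdispersion but off by default.

Noise is injected constructively. A tenth of generated calls
(`artifact_fraction`) violate exactly one stage-1 criterion each —
failed recalibration, intronic position, shallow depth, out-of-band
VAF, or a common MAF — so the filter's rejection tallies have an exact
expected value. (A call violating *only* the minimum-alt-reads rule
cannot exist under the default thresholds: fewer than 2 alt reads with
VAF ≥ 0.20 forces depth below 10, so that tally is exercised by unit
tests instead.) Five variants are planted in more than 10% of both
groups to give the cohort-recurrence filter true targets. Cases and
controls come from two independently seeded streams, which makes
group-swap symmetry tests exact and lets a replicate be reproduced
from two integers.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage and haplotype
structure (every call is independent), shared common variation between
samples beyond the planted artifacts, gene-length and coverage
heterogeneity (all genes get equal-width intervals and the same depth
distribution), annotation error, and relatedness between cases from
the same family. The generator validates the *pipeline's* arithmetic
and statistical behaviour, not the biology.

## Statistical guarantees, with problem sizes

Two Monte-Carlo experiments back the pipeline's statistical claims;
both run the *full* filtration-to-burden chain, not just the test
statistic, on panel-scale simulations (off-panel rates zeroed — the
scale at which the burden comparison of interest operates, and 500
replicates of it run in about a minute each):

- **Type-I error** (`typeI_error_rate()`): 500 null cohorts (all
  enrichment factors 1), Student t at α = 0.05 on the per-sample
  totals. The rejection fraction must sit within 3 binomial
  Monte-Carlo standard errors of 0.05.
- **Effect recovery** (`enrichment_recovery()`): 500 cohorts with the
  injected 2.39-fold panel-nonsense enrichment. The recovered
  fold-change must land within 5% of the injected factor.

One estimator subtlety: with expected control-group *totals* of only
~13 nonsense calls, the per-replicate ratio of means is upward biased
by roughly the reciprocal of that total (~8%), a textbook small-sample
property of ratio estimators — averaging per-replicate ratios would
overshoot no matter how many replicates are run. The recovery
experiment therefore reports, and the package's checks assess, the
pooled estimate (Monte-Carlo mean of case means over Monte-Carlo mean
of control means), which is consistent for the injected factor; the
biased mean-of-ratios is also returned, labelled as such, because the
contrast is instructive.

## Numerical and degenerate-input choices

- All retention comparisons at stated bounds are inclusive
  (≥ 10 reads, ≥ 2 alt reads, VAF in [0.20, 0.80], MAF ≤ 0.01);
  cohort-recurrence removal is strict (> 10%). Whether the published
  VAF bounds were inclusive is not stated; inclusive mirrors the
  printed operators.
- Zero-variance categories (e.g. no stop-loss calls anywhere) yield
  `NA` test fields rather than an error inside `burden_report()`;
  calling `student_t()` directly on degenerate vectors errors
  explicitly. The fold-change is `NA` when the control mean is 0.
- Duplicate (sample, chrom, pos, ref, alt) tuples are rejected at
  construction; the generator resolves position collisions
  deterministically by cyclic nudging within the gene interval.
- Coordinates are VCF-convention 1-based with anchor bases for indels;
  panel and exon intervals are BED-convention 0-based half-open;
  conversions happen only at I/O boundaries.
- Left-normalisation of indels is assumed done upstream (as by
  standard callers); duplicate detection is exact-tuple.

## A worked run

```{r pipeline, eval = FALSE}
panel <- cagp_panel()
sim <- simulate_cohort(sim_params(panel_only = TRUE, seed = 1), panel)
res <- analyze_cohort(sim$cohort, filter_config(), panel = panel)

res$stage1_report          # rejection tallies match injected artifacts
res$panel$burden           # nonsense ratio near the injected 2.39
res$panel$recurrence       # candidate genes under the two-arm rule
res$panel$summary          # cohort-level PDAV summary
```

## Known limitations

- The burden model is a t-test on counts: no covariates, no
  overdispersion correction, no zero-inflation — matching the source
  design, not the state of the art in rare-variant association.
- Panel restriction is symbol-based in practice; the shipped panel's
  intervals are placeholders.
- The recurrence candidate rule is a hard threshold, not a test; with
  54 cases, 3 carriers of truncating variants in one gene is a signal
  worth follow-up, not significance.
- HGVS labels are opaque pass-through strings; splice-effect
  prediction and pathway over-representation are out of scope.
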