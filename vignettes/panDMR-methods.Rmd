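---
title: "Calling pan-cancer differentially methylated regions with panDMR"
author: "panDMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling pan-cancer differentially methylated regions with panDMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(panDMR))
```

## The problem

Some genomic regions acquire DNA methylation in tumors of many different
tissues of origin, which makes them candidate pan-cancer biomarkers.
Detecting them from Illumina 450K-style array data takes a pipeline:
normalize beta-value matrices across samples, test every CpG probe for a
tumor/normal difference within each cancer-type cohort, screen probes by
their diagnostic value (AUROC) averaged across cancer types, and collapse
the surviving probes into regions by their order on the array manifest.
panDMR implements that pipeline as composable functions on Bioconductor
containers (`GRanges` manifests, `SummarizedExperiment`-derived cohort
sets), together with a seeded simulator so every stage can be exercised and
calibrated without downloading arrays.

## The model, stage by stage

### Rank-based quantile normalization

The default `"rank-mean"` mode of `quantileNormalize()` builds its
reference as the **sorted vector of per-probe means across all samples**;
each sample's value of within-sample rank $k$ is then replaced by the
$k$-th smallest reference value. Every output column carries an identical
multiset of values and within-sample rank order is preserved exactly. Ties
receive the mean of the reference values at the tied rank positions, which
makes the result deterministic and independent of input order.

This variant differs from classical quantile normalization, whose
reference is the mean of the per-sample sorted columns; that form is
available as `mode = "classic"`. Two consequences worth knowing:

* classic mode is exactly idempotent (its reference is a fixed point of
  its own output), while rank-mean mode is not, because the per-probe
  means of the normalized matrix mix reference values across ranks;
* any quantile normalization assumes that only a small fraction of probes
  differ between groups. When a large share of probes is shifted in one
  group, the shift itself deforms the shared reference and the per-probe
  group difference is attenuated. On a real 450K array a few hundred
  differential CpGs out of ~450,000 are harmless; in small simulated
  manifests the planted fraction should be kept low (the package's test
  fixtures keep planted probes around a tenth of the manifest).

Cohorts whose normal or tumor group falls below `minGroupSize` (default
30 samples, the conventional floor for per-group cohort inclusion) are
removed by `filterCohorts()` before testing; a whole-dataset floor (e.g.
60 samples for validation-style series) is available via
`perDataset = TRUE`. The boundary is inclusive: a group of exactly 30
passes.

### Per-CpG statistics

For each cohort, `cohortSiteStats()` computes per probe:

* a two-sided Welch $t$-test p-value comparing tumor against normal beta
  values (unequal variances, Satterthwaite degrees of freedom) —
  implemented row-vectorised for speed and checked in the test suite
  against `stats::t.test` and an independently coded Welch formula;
* a Benjamini–Hochberg q-value, adjusted within the cohort across all
  probes;
* the AUROC with tumor as the positive class and the beta value as the
  score, computed exactly from midranks as
  $\mathrm{AUC} = P(\beta_T > \beta_N) + \tfrac12 P(\beta_T = \beta_N)$
  (the Mann–Whitney $U$ statistic divided by the number of pairs);
* delta-beta, the tumor-minus-normal difference of means.

`panCancerDms()` aggregates across cancer types: a probe is a pan-cancer
differentially methylated site (DMS) iff its q-value is below 0.01 in at
least `minSignificantFraction` of the cohorts (default: all of them — the
target is regions shared across cancers) **and** its mean AUC across
cohorts is at least 0.75. Both thresholds are inclusive at the boundary,
and both are exposed. Whether per-cohort FDR significance should be
required in every cohort or only the AUC average is genuinely ambiguous as
a matter of study design; requiring all cohorts is the stricter reading
and is the default, with the fraction exposed for sensitivity analyses.
The default direction mode is `"hyper-only"` (raw mean AUC, tumor
positive), matching a hypermethylation screen; `"symmetric"` gates on
$\max(\mathrm{AUC}, 1-\mathrm{AUC})$ instead.

### Region calling

`callDmrs()` walks the manifest in (chromosome, position) order. A
candidate run is a maximal stretch of consecutive manifest probes all
flagged as DMS — a single intervening non-DMS probe breaks the run, and no
maximum genomic gap is imposed inside a run (sparse runs are handled by
the density gate instead). A run is reported iff

* it contains at least 10 member sites (inclusive), and
* its CpG density, members per kilobase of span, is at least 3
  (equivalently 0.003 per bp, inclusive).

Span length is defined as `end − start`, the distance between the first
and last member probe, and the stored density is the per-bp ratio
`n_dms / length`; `dmrTable()` prints that per-bp value rounded half-even
to 5 decimals. These conventions reproduce published DMR tables
column-for-column (the worked-example table prints per-bp densities under
a per-kb header; the package reproduces the printed numbers and documents
the discrepancy here).

`mergeDmrs()` combines same-chromosome regions whose gap
(`next start − previous end`) is at most `maxGapBp`, summing member
counts and recomputing length and density; it is idempotent. The default
of 1000 bp is an explicit assumption chosen to capture coordinately close
regions separated by a few tens of bp with wide margin; it is exposed in
the configuration. `intersectCollections()` reads the stored 1-based
inclusive spans as half-open intervals and keeps regions of one collection
overlapping the other by at least 1 bp, which is how a discovery
collection is validated against an independent one. BED export converts
to 0-based half-open coordinates (`bed_start = start − 1`).

### Co-expression block disruption

A methylation boundary inside an ordered gene cluster predicts a change in
the cluster's co-expression structure. The published evidence for this is
a pair of heatmaps (modular in normal tissue, disordered in tumors); to
make that claim testable the package defines an explicit statistic.
`blockContrast()` takes a Pearson correlation matrix and a gene-to-block
assignment and returns

$$\mathrm{contrast} = \overline{r}_\text{within} -
\overline{r}_\text{between},$$

the mean off-diagonal correlation inside blocks minus the mean correlation
across blocks, with an optional label-permutation p-value. The default
block split follows the cluster's observed structure (HOXA1–HOXA6 versus
HOXA7–HOXA13). `distalAssociation()` tests a distal gene (e.g. TAX1BP1,
~700 kb downstream of the HOXA locus) against each cluster gene with the
standard $t$-transform of the Pearson correlation ($n-2$ degrees of
freedom, two-sided, $\alpha = 0.05$). `coexprDisruption()` summarizes both
per cohort and group.

## The synthetic-data generator

The generator exists so the pipeline's operating characteristics can be
measured against known truth.

* **Manifests** (`generateManifest()`): probes spread over chromosomes
  with gaps drawn as $1 + \mathrm{Poisson}(\bar g - 1)$, mean spacing
  $\bar g$ defaulting to 500 bp.
* **Beta cohorts** (`generateBetaCohorts()`): each probe draws one
  baseline from Beta(0.85, 0.85) — the bimodal methylation landscape
  typical of 450K data — shared across cohorts to model tissue-of-origin
  maintenance. Per-sample noise is Gaussian on the logit scale
  (sd 0.5) and back-transformed, which keeps values strictly inside
  (0, 1) without mass at the clip bounds; a per-cohort offset
  (sd 0.02 on the beta scale) emulates mild batch/tissue heterogeneity.
  Planted runs (`plantedDMR()`) shift the tumor mean by `deltaBeta` in the
  first $\lceil f \cdot n_\text{cohorts} \rceil$ cohorts; their baselines
  are drawn in the unmethylated range (0.10–0.40) for positive shifts —
  a CpG-island-like locus acquiring methylation — and mirrored for
  negative shifts, so the stated delta is fully expressed.
  The defaults (3 cohorts, 40 normal / 40 tumor samples, $\Delta\beta =
  0.3$) describe a modest multi-cancer design with cohort sizes above the
  inclusion floor.
* **Expression cohorts** (`generateExpressionCohorts()`): multivariate
  normal draws on a log-expression scale via the Cholesky factor of a
  validated target correlation matrix — within-block correlation 0.8 in
  normal and 0.2 in tumor, between-block 0.1, and a distal gene
  uncorrelated in normal but correlated at 0.35 with every cluster gene in
  tumor. The target matrix is checked for positive semi-definiteness and
  rejected with an informative error otherwise (which is why the distal
  correlation default is 0.35: substantially higher values are
  geometrically impossible against a weakly correlated cluster).

All generators run from one master seed with deterministic per-cohort,
per-group sub-seeds, so a single matrix can be regenerated independently
of generation order. No distributional choice mimics array chemistry:
there are no detection p-values, probe-type effects or cross-reactive
probes, so passing tests demonstrate correct statistics and calling logic,
not robustness to platform artifacts.

## What the tests establish

* The worked-example surface: all nine published region rows (member
  counts, spans, lengths, printed 5-decimal densities) are reproduced
  exactly from their first/last coordinates, and the two coordinately
  close chr7 regions (45 bp apart) merge into one 23-site, 1334-bp span.
* Planted-truth recovery: a seeded 3-cohort, 40/40 build planting one
  hypermethylated run per published row recovers all nine regions with
  exactly the planted spans, and eight regions after merging.
* Oracle agreement: AUROC equals exhaustive pair counting on random
  instances with ties; BH equals a hand-coded step-up rule on all
  permutations of four p-values; Pearson correlations match a two-pass
  covariance oracle to 1e-10; Welch p-values match `stats::t.test` to
  1e-10.
* Calibration: under the global null the pan-cancer DMS and DMR counts
  are 0 in at least 19 of 20 seeded replicates, and the distal-gene
  false-positive rate stays within binomial bounds of $\alpha$.
* Disruption recovery: the normal-minus-tumor block contrast exceeds 0.3
  at $n = 200$ per group in at least 19 of 20 seeded replicates.

Simulated problem sizes (manifests of a few hundred to ~2,000 probes,
3 cohorts, 40 samples per group) were chosen so the whole suite
runs in well under a minute while keeping every gate operating away from
degenerate regimes; all sizes are parameters, and nothing in the
implementation depends on them.

## Numerical and degenerate-input conventions

* Welch test with zero variance in both groups: p = 1 when means agree
  (no evidence, by convention, with a message), p = 0 when they differ.
* Quantile-normalization ties: tied probes receive the mean of the
  reference values at the tied positions.
* `density * length = n_dms` holds exactly before rounding; printed
  densities round half-even.
* Missing beta values are never imputed: the probe is dropped across all
  samples (logged), before normalization.
* Zero-variance genes make correlation matrices an explicit error, not a
  silent `NaN`.
* All thresholds are inclusive at their boundary except the FDR cut,
  which is strict (`q < 0.01`), matching the usual reading of "adjusted
  p set at 0.01".

## Limitations

* The two-group test is an unpaired Welch $t$ on beta values; logit-scale
  (M-value) testing is a config alternative in spirit but beta-scale
  testing is the default to keep delta-beta on the reported scale.
* The simulator does not reproduce probe-type chemistry, purity, or
  cell-composition effects; conclusions about those require real arrays.
* Merging and intersection conventions (1000 bp gap, 1 bp half-open
  overlap) are explicit assumptions exposed in `pipelineConfig()`, not
  published values.
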