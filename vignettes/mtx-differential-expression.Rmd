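---
title: "Modeling differential expression in microbial community metatranscriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling differential expression in microbial community metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxdiff)
```

## The problem

A gene's RNA read count in a shotgun metatranscriptome (MTX) is not a
direct readout of its regulation.  It also tracks the number of genomic
copies of the gene in the community, which changes whenever the encoding
species waxes or wanes (often over orders of magnitude between samples)
and whenever strains gain or lose the locus.  A model that regresses raw
relative transcript abundance on a phenotype will therefore report
"differential expression" for any gene whose *species* happens to covary
with the phenotype.  mtxdiff implements six per-feature regression models
that handle this coupling in different ways, three policies for
pre-filtering likely technical zeros, a logistic presence/absence variant,
and a synthetic community simulator for benchmarking all of the above
against known ground truth.

## The six models

Writing $f$ for a feature (a gene family, optionally stratified by its
source species), $p$ for a binary sample phenotype, and TSS for total-sum
scaling, each model is an independent per-feature regression fitted with
ordinary least squares (`glm`-style) on natural-log abundances:

* **M1** $\log \mathrm{TSS}(\mathrm{RNA}_f) \sim p$ — the naive baseline;
  community-level TSS only.
* **M2** $\log \mathrm{WT}(\mathrm{RNA}_f) \sim p$ — within-taxon TSS: the
  feature's RNA divided by the total RNA of its source species
  ("taxon-specific scaling").
* **M3** $\log \mathrm{WT}(\mathrm{RNA}_f) \sim p + \log
  \mathrm{RNA}_{\mathrm{taxon}(f)}$ — M2 plus the species' total RNA as a
  covariate, a proxy for taxon abundance when no DNA is available.
* **M4** $\log \left( \mathrm{TSS}(\mathrm{RNA}_f) /
  \mathrm{TSS}(\mathrm{DNA}_f) \right) \sim p$ — the RNA/DNA ratio
  ("relative expression", transcripts per gene copy).
* **M5** $\log \mathrm{TSS}(\mathrm{RNA}_f) \sim p + \log
  \mathrm{DNA}_{\mathrm{taxon}(f)}$ — community-scaled RNA with a
  DNA-level taxon abundance covariate.
* **M6** $\log \mathrm{TSS}(\mathrm{RNA}_f) \sim p + \log
  \mathrm{DNA}_f$ — the feature's own DNA abundance as a covariate
  ("residual expression").

M2, M3 and M5 need feature-to-taxon assignments; M4, M5 and M6 need paired
metagenome (MGX) sequencing.  M4 and M6 work for features of unknown
taxonomy, including orthogroup sums.  The phenotype coefficient is tested
with a two-sided Wald t-test on residual degrees of freedom, and
Benjamini–Hochberg FDR correction is applied across the features tested in
one analysis.  An optional log read-depth covariate, extra metadata
covariates, and a per-subject random intercept (via `lmerTest`, for
repeated-measures designs) are available on every model.

## Zeros: filtering, smoothing, and the logistic variant

MTX count tables are dominated by zeros, produced by three distinct
processes: genuine absence of expression, non-encoding (the strain in this
sample lacks the gene) and non-detection (expression below the sampling
depth).  Three masking policies separate them, consulting the feature's
RNA value and — for M3–M6 — its gene-copy estimate (taxon RNA total for
M3, taxon DNA total for M5, feature DNA for M4/M6):

* **lenient** — drop a feature only if its RNA (or copy) row is all zero;
  keep every sample otherwise;
* **semi-strict** — additionally drop a sample when RNA *and* copy are
  both zero;
* **strict** — drop a sample when RNA *or* copy is zero.

M1 and M2 carry no copy estimate, so their filters consult RNA zeros only;
this means M2 retains samples in which the species' total RNA is barely
detected, and its within-taxon values there are dominated by counting
noise — the mechanism by which M2 loses both sensitivity and specificity
relative to M3.  Zeros that survive filtering are additively smoothed by
half the feature's smallest non-zero surviving value before the log;
half-minima are computed over unmasked cells only, since masked cells are
declared non-measurements.  Features dropped by filtering are retained in
results (`status = "filtered"`) and scored as negative calls.

The logistic variant replaces the abundance response with RNA detection
(count > 0) and keeps each model's copy covariates, since presence calls
cannot be rescaled.  Two grid cells are structurally empty: M4 (a
presence call has no ratio transform) and strict filtering (removing every
RNA-zero sample leaves an all-present response).

## The simulator

`make_dataset()` generates paired MGX/MTX count tables from a gut-like
community:

1. **Species templates.** Each of 100 species has a prevalence and a
   log-normal abundance distribution.  The packaged table is parametric
   and deterministic — prevalences interpolate from 1 to 0.1 and natural-log
   mean abundances from 2.5 to −3.5 (a realistic rank-abundance skew), with
   a common log-sd of 2 reflecting the orders-of-magnitude cross-sample
   variability of gut species.  Any table with the same columns can be
   substituted (`read_species_templates()`).
2. **Pangenomes and strains.** Each species draws 1000 gene families from
   a shared pool of 2000 (orthogroup semantics), and the strain observed
   in each sample carries each gene independently with probability 0.8.
   Bernoulli carriage was chosen over fixed-size subsets as the simpler
   reading of a "randomly drawn" strain; it matches the 80% encoding rate
   in expectation.
3. **Expression.** Each feature has a reference log-mean expression
   $m \sim N(0,1)$; carried genes express $\exp(N(m, 1))$ per sample.
4. **Phenotype and spikes.** Samples are split exactly half and half
   (balance maximizes power comparability across replicates).  Selected
   phenomena — per-sample read depth, species abundances, gene
   presence/absence, expression values — are re-arranged by
   `spike_permute()` to achieve a positive Spearman correlation with the
   phenotype: 0.8/0.5/0.2 for high/medium/low strength, a monotone mapping
   chosen to preserve the qualitative power ordering.  Every spike is
   positively directed; with mixed signs the compositional side-effects of
   confounding (which community-TSS models are supposed to suffer from)
   largely cancel across spiked units.  The shuffler starts from the
   rank-extreme arrangement and bisects on the number of random swaps until
   the realized correlation is within 0.05 of target; for binary targets
   (carriage) and binary phenotypes the attainable maximum can be below the
   request (about 0.5 at an 80% carriage rate), in which case the extreme
   arrangement is used and flagged, never silently dropped.  Realized
   correlations are logged in the dataset's `spikes` table.
5. **Counts.** Reads are drawn per sample from a multinomial up to the
   sample's depth — weights proportional to species abundance (DNA) or
   species abundance × expression (RNA), over carried genes — so column
   sums equal depths exactly.  Depths are log-uniform on
   [5×10^4, 2×10^5] independently for RNA and DNA; depth-confounded
   presets spike the RNA depth.

Expression spikes define the DE-positive ground truth; everything else is
a confounder.  Eleven presets (`preset_names()`) combine the spikes: a
clean `null`; `null-bug`, `null-enc`, `null-dep` with species, gene-content
or depth confounding only; `true-exp`/`-med`/`-low` with 10% of features
DE'd at decreasing strength; two `true-combo-*` mixtures; and two
`group-*` presets in which spikes are applied consistently to every
species' copy of a gene family, taxonomy is discarded and features are
orthogroup sums (`collapse_orthogroups()`).

## Scoring

A true positive is a truth-positive feature with BH q < 0.05 —
conservatively requiring FDR significance, so TPR is computed over *all*
truth-positives and filtering can only cost sensitivity.  A false positive
is an *analyzed* truth-negative with nominal p < 0.05; features removed by
filtering are negative calls by construction and drop out of the FPR
denominator (they carry no information about the test's type-I error, and
a calibrated model should sit at 0.05 on null data however aggressively
technical zeros are filtered).  Proportions get Wilson score intervals,
which behave at the 0/1 boundaries.  `run_grid()` evaluates
presets × models × filters × responses over replicate seeds, skipping
structurally inapplicable cells with a reason, and `render_report()` draws
the TPR/FPR heatmap (undefined TPRs shown as "undef") and CI bar charts.

## Numerical and scale choices

* Natural logs throughout; the base only rescales coefficients.
* A feature is tested only with ≥ 5 surviving samples, both phenotype
  groups represented, and more observations than parameters; designs that
  are rank-deficient, constant-response, or separated (logistic) are
  flagged untestable and scored negative.
* Replicate seeds: rates from a single realization are noisy, so
  benchmark quantities are reported as means over ≥ 10 replicate
  regenerations (the acceptance script) or 2–3 (the test suite), with
  pooled Wilson CIs.
* Problem sizes: the test suite and acceptance script run a reduced
  community of 20 species × 200-gene pangenomes from a 400-family pool
  (4000 stratified features), N = 100 samples, at the full default depth
  range — deep enough that desk-scale features are sampled at least as
  well as full-scale ones.  The full 100 × 1000 community is the
  simulator default.

## What the simulation does and does not show

The generator reproduces the statistical structure that makes community DE
hard — species dominance and zero inflation, strain-level gene loss,
compositional coupling through TSS, depth confounding — but not everything
about real data: no transcript-length effects, no species-level global
transcriptional programs, no sequence-level errors, and log-normal
expression within and across species rather than empirically fitted
distributions.  Passing benchmarks here demonstrates correct *relative*
behavior of the models under the simulated mechanisms (which models
inflate false positives under which confounder, how filtering trades
sensitivity for specificity), not absolute performance on any particular
real cohort.

Two further caveats worth knowing:

* With heavy-tailed abundances and discrete low counts, the Wald t-test is
  mildly *conservative* for some model/filter cells (observed null FPR
  slightly below 0.05, especially for M1 and under lenient filtering or
  the logistic response).  This errs on the protective side.
* On data lacking taxonomy, only M1, M4 and M6 apply; M2/M3/M5 are
  refused with an explanatory error rather than silently falling back.

## A worked example

```{r example, eval = FALSE}
d <- do.call(make_dataset,
             c(list(preset = "true-exp", seed = 1), desk_scale()))
res <- run_de(d, model_spec("M6", filter = "strict"))
score_de(res, d$truth)
```

See the README for the numbers this prints and for how to regenerate the
full benchmark surfaces with `scripts/acceptance.R`.
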