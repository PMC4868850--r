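---
title: "Methods: transcriptome screens for aging and cognitive flexibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome screens for aging and cognitive flexibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CogTx)
```

## Overview

CogTx implements the post-quantification arm of a bulk RNA-seq study
design that links regional brain gene expression in rats to two
axes: chronological age (young vs aged groups) and cognitive status
among the aged animals, measured as trials-to-criterion (TTC) on an
attentional set-shift task. Higher TTC means more trials to abandon a
learned visual-cue rule for a spatial rule, i.e. worse cognitive
flexibility. The pipeline stages are:

1. gene filtering (low counts, GO annotation) and median-of-ratios
   normalization;
2. a per-gene age screen (one-way ANOVA, uncorrected p < 0.025);
3. a per-gene behavior screen (Pearson correlation with TTC over aged
   animals only, critical-r thresholding);
4. cross-study directional concordance with one-tailed directed tests
   and an expected-direction FDR;
5. composite gene-set index scores, mean-split impaired/unimpaired
   (AI/AU) classification, discrimination-index arithmetic, and
   delta-delta-Ct quantification for qPCR validation;
6. a synthetic-data generator that emulates the study's statistical
   structure with planted ground truth.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does
and does not establish.

## Screening model and scale choices

Statistics are computed on `log2(normalized + 1)` values and fold
changes on the linear normalized scale. The split follows common
practice: parametric tests behave better on the roughly
variance-stabilized log scale, while fold changes are conventionally
quoted as linear ratios. Whether a given upstream suite ran its ANOVA
on raw, normalized or log counts is often opaque, so `normalize_counts()`
records its scale explicitly and every screen accepts either.

With two groups, the one-way ANOVA F statistic equals the squared
pooled-variance two-sample t statistic; `age_screen()` computes the
vectorized pooled t and reports `F = t^2` with `p` from the F(1, n−2)
distribution. The test suite asserts this identity against
`stats::aov()` and `stats::t.test()` to 1e-10 relative error. A pooled
(equal-variance) test is used throughout for consistency with the
one-way ANOVA; it is the classical definition, and the screen threshold
(p < 0.025) is deliberately uncorrected — inference is carried by gene
sets (enrichment, concordance, composite indices), not by single genes.

The signed fold convention reports a ratio of group means `r >= 1` as
`r` and `r < 1` as `-1/r`, so 0.84 is reported as −1.19. Exactly tied
means have direction 0 and can never agree with a ±1 prediction.

## The behavior screen and the critical r

Correlations with behavior are restricted to aged animals so that age
differences cannot masquerade as behavioral signal. Significance uses
the t transform `t = r sqrt((n−2)/(1−r²))` with two-tailed p at n−2
degrees of freedom. Inverting at the critical t gives

```
r_c(alpha, n) = t_c / sqrt(n − 2 + t_c²),  t_c = qt(1 − alpha/2, n − 2)
```

which at alpha = 0.025 and n = 20 yields `r 0.499` — matching the
published cutoff for this design, which is why the two-tailed t-based p
is adopted (a one-tailed reading does not reproduce that pair). The
per-gene significance flag is exactly equivalent to `|r| >= r_c`, and
the suite checks both routes gene by gene.

Sign semantics differ by measure and are reported, never silently
assumed: for TTC, positive r means expression rising with impairment;
for the water-maze discrimination index, positive r means expression
rising with better spatial memory.

## Concordance and the expected-direction FDR

A prior study's gene list with expected directions (±1) is matched to
the detected universe case-insensitively (human SST, rat Sst); `T` is
the matched count and stays fixed — genes untestable through zero
variance remain in `T` but cannot reach significance, since `T` is
defined as "genes tested", not a post-hoc filtered set. Agreement is
tested against a 50:50 null with the plain one-degree-of-freedom
goodness-of-fit statistic, no continuity correction: Yates-corrected or
alternative-null variants of "a chi-square test" give different values,
so the exact form used here is stated and the closed form
`2 (n_same − T/2)² / (T/2)` is asserted in the tests. One-tailed pooled
t-tests in the predicted direction then give `n_sig`, and

```
FDR = (T * alpha) / n_sig
```

estimates the fraction of directed hits expected by chance. The ratio
is undefined at `n_sig = 0` and reported as not applicable. Reported
FDRs and percentages are quoted at two decimals with half-away-from-zero
rounding (`round_half_up()`); R's own `round()` rounds halves to even,
which turns 0.265 into 0.26 rather than the conventionally quoted 0.27.

## Cognitive scores and the composite index

- Discrimination index: `(G − O)/(G + O)` over percent time in goal and
  opposite quadrants; undefined when `G + O = 0`.
- Mean split: aged animals strictly above the aged-group mean TTC are
  AI, the rest AU. Ties fall to AU ("delayed shifting" reads as
  strictly greater), and labels are invariant to increasing affine
  rescaling of TTC.
- Index score: each gene in the set is z-scored across the included
  animals (aged only when reproducing the behavioral analyses — the
  correlation itself is defined on aged animals, so the index uses the
  same subset; the animal subset is an explicit argument, never
  implicit), averaged within animal, and correlated with standardized
  TTC. With one gene the index equals that gene's correlation; with
  many genes sharing a signal, independent noise averages out and the
  composite correlation exceeds typical single-gene correlations.

## qPCR arm

`delta_delta_ct()` averages technical replicates arithmetically,
computes ΔCT against the reference gene, anchors ΔΔCT at the control
group's mean ΔCT (so the control geometric-mean fold is exactly 1), and
reports `fold = 2^(−ΔΔCT)`. Group tests default to the ΔΔCT scale
(log-normal expression noise is closer to normal there); the baseline
group for each contrast (young as control for age contrasts, AU for
AI contrasts) is an explicit argument.

## The synthetic-data generator

The generator exists so that every downstream stage can be validated
against planted truth. Its defaults are fixed to the study design it
emulates and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_young`, `n_aged` | 11, 20 | animals per age group |
| `n_genes` | 15000 | GO-annotated gene universe |
| `n_age_de`, `age_lfc`, `frac_age_up` | 700, 1, 0.47 | planted age genes, log2 shift, fraction up |
| `n_behavior_genes`, `behavior_r`, `frac_behavior_up` | 400, 0.7, 0.73 | planted TTC-correlated genes, target r, fraction positive |
| `nb_dispersion` | 0.1 | NB dispersion phi (Var = mu + phi mu²) |
| `mean_log_expr`, `sd_log_expr` | 5, 2 | baseline log2 mean distribution |
| `libsize_spread` | 0.2 | log2 sd of library-size factors |
| `ttc_young_mean`, `ttc_au_mean`, `ttc_ai_mean`, `ttc_sd` | 30, 35, 75, 10 | TTC mixture components |
| `frac_aged_impaired` | 0.5 | AI mixing weight |

Counts are negative binomial with log-normal baseline means — the
standard bulk RNA-seq assumption — times per-sample size factors.
Age effects add ±`age_lfc` to the log2 mean of aged samples. Behavior
genes add `beta * z(TTC)` to aged samples' log2 means, with `beta`
solved per gene from the target correlation and the delta-method
variance of log2 NB noise, `v = (1/mu + phi)/ln(2)²`, via
`beta² = r² v / (1 − r²)`; the planted correlation therefore refers to
the observed (count-noise-attenuated) correlation, and the suite checks
the achieved mean correlation against the target. TTC floors at 8 (the
task criterion of eight consecutive correct trials makes lower values
impossible) via truncated normal sampling; TTC is real-valued by
default, keeping correlation targets exact, with an `integerize_ttc`
option. The aged TTC mixture means (35/75 at equal weights) put the
aged mean near the low 50s, the order of published splits; the exact
component values are otherwise free choices since only the mixture's
mean is anchored by published work. The spatial block-5 path length is
generated with a negative loading on the discrimination index so the
behavioral correlation table has the qualitative structure seen in
aged cohorts (longer spatial search paths with poorer probe
discrimination).

Each generator draws from its own RNG stream, seeded explicitly, and
restores the caller's RNG state; equal seeds give byte-identical
output.

What the generator does *not* emulate: read- and alignment-level
artifacts, GC/length biases, batch structure, gene-gene correlation
beyond the planted behavioral coupling, and count outliers. Passing
tests therefore demonstrate correctness of the statistics and
calibration under the stated model, not robustness to every failure
mode of real data.

## Spike-in QC

QC regresses log10 observed counts on log10 expected concentration over
detected transcripts (observed > 0) and passes only when R² exceeds 0.9
and at least 60 transcripts are detected; both gates are strict
inequalities as stated for this design. The fit excludes undetected
transcripts rather than offsetting counts by +1: a pseudo-count bends
the low-concentration end of the dose-response line and would make even
noiseless data fail exact linearity.

## Numerical and degenerate-input choices

- Low-count filter: "counts of 5 or less" is interpreted as the
  per-gene **mean** raw count (library-size comparable); `sum` and
  `max` modes are available. The boundary is inclusive: a mean of
  exactly 5 is removed.
- Median-of-ratios uses only genes with nonzero counts in every sample
  and the plain median, matching the canonical estimator (cross-checked
  against DESeq2 in the tests). No gene expressed everywhere is an
  error, not a silent fallback.
- Zero-variance rows: excluded with a warning from z-scoring and the
  index; flagged NA in correlation results; retained but untestable in
  concordance T.
- Constant behavioral scores are an error for correlation (r
  undefined).
- Validation of input files is total — a count file either parses into
  a fully validated matrix or fails with the offending line named.

## Problem sizes in the validation suite

The suite validates calibration and power at reduced but adequate
scale, chosen as the smallest sizes at which the binomial error bands
are informative: null calibration pools 20 simulated studies of 5,000
genes (both screens must sit within 3 binomial SEs of 2.5%); power uses
five studies of 3,000 genes with 200 planted genes per axis
(sensitivity ≥ 0.8 at |log2 fold| = 1, dispersion 0.1, and at r = 0.7,
n = 20); the composite-index property is checked over 100 seeds of a
46-gene module planted at r = 0.5. Oracle equivalences (F = t²,
hypergeometric vs subset enumeration, the chi-square closed form) are
exact to stated tolerances.

## Known limitations

- The concordance framework takes the prior study's mapped gene list as
  input; ortholog mapping between species is out of scope, so `T`
  depends on the mapping the user supplies.
- The expected-direction FDR is a design-level chance estimate, not a
  per-gene adjusted p-value; it assumes the directed tests are
  independent under the null.
- DAVID-style fuzzy functional clustering is intentionally not
  reimplemented; `go_enrichment()` is a plain term-level hypergeometric
  test with Benjamini-Hochberg adjustment, and cluster-level FDRs from
  such tools are not comparable to its output.
- The mean-split AI/AU classification is the field's convention for
  this task, not an optimal classifier; with well-separated mixture
  components it approaches the Bayes accuracy (checked in the tests),
  but near-overlapping components make the labels noisy by
  construction.
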