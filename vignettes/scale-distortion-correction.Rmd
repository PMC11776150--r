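---
title: "Correcting per-sample scale distortion in expression matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting per-sample scale distortion in expression matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaleleveler)
```

## Why another normalization step

Between-sample normalizations in wide use — TPM, FPKM, TMM, RLE — differ
from one another only by a per-sample multiplicative factor, which on the
log2 scale is a per-sample additive constant. Variance-stabilizing
transforms apply one common nonlinear map to every sample. Neither family
can remove a distortion that is both *per-sample* and *expression-level
dependent*. Yet block averaging of genes sorted by mean expression exposes
exactly such a structure in real cohorts: each sample deviates from the
consensus profile by a smooth curve in expression level, different from
sample to sample. Left uncorrected, these deviations inflate inter-sample
variance, shift and broaden gene–gene correlation distributions, and add a
coherent, draw-dependent component to two-population t statistics.

## Preprocessing conventions

All analysis happens on offset log values $g = \log_2(x + c)$.

* **Offset $c = 0.25$** (configurable). If true levels are approximately
  uniform below the rounding threshold 0.5, the values that round to zero
  have mean 0.25, so 0.25 is the natural imputation for an unexpressed gene.
* **Mean-expression filter, threshold 3 on the log2 scale** (raw mean above
  8). At $x = 8$ the offset inflates the raw value by at most
  $c/x = 1/32 \approx 3\%$ (`offset_distortion_bound()`), so above the
  threshold the offset is immaterial. The filter is applied once, after the
  log transform and before any correction; it is not recomputed afterwards,
  since corrections move values by at most a few tenths of a log2 unit.
* **No per-gene standardization before correction.** The bias depends on a
  gene's mean level, not its variance; dividing by per-gene standard
  deviations would scramble it beyond recovery. Standardization enters only
  inside the t statistic, after correction.
* **No outlier removal**; means and variances use all samples, with the
  unbiased $M-1$ variance denominator throughout.

These conventions are justified empirically by two diagnostics in the
package: `normality_sweep()` (a d'Agostino omnibus p-value curve; log data
is far closer to per-gene normality than raw data, and group means more so)
and `variance_profile()` (per-gene sd is roughly flat in mean expression on
the log scale, so a variance-stabilizing transform buys little for mid- to
high-expressed genes).

## The bias model and the two transforms

Write $g_{nm}$ for the measured log2 level of gene $n$ in sample $m$,
$\bar g_n$ for its across-sample mean, and $G_{nm}$ for the true level.
Block averaging $\langle\cdot\rangle_K$ — the mean over $K$ consecutive
genes in mean-sorted order, trailing remainder dropped — is the estimation
device: per-gene noise shrinks like $1/\sqrt K$ while a smooth per-sample
bias survives, and the averaged residuals are close to normal, which
licenses least squares.

**Local-leveling transform (LLT).** Assume the bias is a function of the
gene's *mean* level: $g_{nm} = G_{nm} + \beta_m(\bar g_n) + \epsilon_{nm}$
with $\beta_m$ polynomial of degree $L$. Block averaging the deviations
gives a linear model in $\langle\bar g_n\rangle_K$; weighted least squares
with weights $w_k = 1/\max(\langle \mathrm{Var}(g_{nm})\rangle_K, 10^{-8})$
estimates the coefficients (between-sample expression variability is the
dominant error source, so inverse variance is the natural weight; the floor
guards degenerate blocks). The correction subtracts the fitted polynomial
evaluated at the fitting-time $\bar g_n$ snapshot, so fit and apply form a
consistent pair; applying a model to a different gene set is refused rather
than silently extrapolated.

**Nonlinear transform (NLT).** More plausibly, the bias acts on the
sample's *own* value: $G_{nm} = \alpha_m(g_{nm}) + \epsilon_{nm}$ with
$\alpha_m(g) = \sum_\ell a_{m\ell} g^\ell$. Block averaging gives
$\langle\bar g_n\rangle_K = \sum_\ell a_{m\ell}\langle g_{nm}^\ell\rangle_K$
plus a combined residual — note the predictors are block averages *of
powers*, not powers of block averages. The combined residual has no clear
relation to expression level, so regression is unweighted. The fitted
polynomial is evaluated at every measured value, including beyond the block
centers; no monotonicity constraint is imposed, but a warning is issued if a
fitted transform is non-monotone on a sample's observed range.

**Shift.** Subtracting each sample's mean deviation is the log-scale
equivalent of the multiplicative renormalization that TPM-style methods
perform; it is included as the baseline the other two are compared against,
and is exactly idempotent.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `c` | 0.25 | log-transform offset, raw-scale units |
| filter threshold | 3.0 | minimum mean log2 expression |
| `degree` (L) | 3 | polynomial order of the bias/transform |
| `span` (K) | 50 | genes per regression block |
| `block_size` | 1000 | genes per diagnostic block (`block_profile`) |
| `window` | 800 | genes per variance-profile window |

Degree 3 is where additional terms stop reducing the regression mean squared
error appreciably; results are insensitive to $K$ over a wide range. The
variance-profile window of 800 and the diagnostic block size of 1000 are
display-resolution choices, not inferential ones.

## Numerical decisions

* Regression uses R's QR solver on a centered/scaled basis — for LLT, powers
  of the standardized predictor; for NLT, standardized columns of the raw
  power basis — and coefficients are mapped back to the original basis
  afterwards. Raw log2 values in the 0–15 range raised to the third power
  would otherwise produce a badly conditioned design. Results match
  normal-equation solutions on well-conditioned toy inputs to $10^{-8}$.
* Sorting ties in mean expression are broken by gene id, so all fits are
  invariant under gene and sample relabeling (tested).
* Trailing genes beyond $\lfloor N/K\rfloor$ full blocks are dropped, both
  in the diagnostics and in the fitting designs, rather than folded into a
  short block.
* A singular fitting design names the offending sample in its error.
* The d'Agostino omnibus statistic is computed from the standard 1990
  skewness/kurtosis transformations (requiring at least 8 observations) and
  is cross-checked in the tests against independently computed reference
  values.

## The synthetic-data generator

`generate_synthetic_dataset()` emulates the statistical shape of a
preprocessed cohort, with every draw a pure function of the config seed:

* true per-gene means uniform on $[3, 12]$ log2 units — the post-filter
  range of real cohorts;
* per-gene across-sample sd constant at 0.5 by default (matching the flat
  variance-vs-mean profile of log data; a vector or a function of the mean
  is accepted for mean-linked variability);
* optional equicorrelated gene blocks (correlation $\rho$ within blocks)
  for studies of gene–gene correlation;
* per-sample distortions $g = p_m(G) + \epsilon$, by default gentle random
  cubics with $|p_m(g) - g| \le 0.3$ over the expression range — the
  magnitude of per-sample deviations seen in real data — drawn once per
  sample from a seeded uniform coefficient distribution;
* additive residual noise with sd 0.1.

What the generator does **not** emulate: count-level sampling noise
(negative-binomial dispersion at low expression), heavy-tailed and skewed
per-gene distributions, library-preparation batch structure, and the dense,
biology-driven correlation network of real transcriptomes. Passing tests on
synthetic data therefore demonstrate that the estimators invert the *modeled*
distortion class at realistic noise levels — not that real cohorts contain
no distortions outside that class.

Spiking adds $\log_2(1 + C/100)$ to chosen genes in a chosen subpopulation:
a C-percent enhancement, exact on the raw scale when $c = 0$ and within the
offset bound otherwise. Because the spike is injected into data (real or
synthetic), ground truth is known without specially prepared samples. All
genes are spiked by default but statistics are computed gene by gene,
modeling single-gene tests.

## Evaluation design

* t statistics use the pooled equal-variance form with $n_A + n_B - 2$
  degrees of freedom; with the group sizes used here it is effectively a z
  statistic.
* ROC curves are built per draw by ranking gene statistics — positives from
  the spiked computation, negatives from the matched unspiked computation on
  the same split — then expressed as TPR as a function of FPR by step
  interpolation and averaged across draws (with 10th/90th percentile bands).
  This "average TPR at fixed FPR" construction matches the practical setting
  where a fixed number of top-ranked genes is taken forward. Tied statistics
  are collapsed into a single operating point.
* Multigene tests histogram the per-gene t values (each gene weight $1/N$,
  bin width 0.01 t units), take the k-fold discrete self-convolution with
  the support extended k-fold, renormalize, and sweep a threshold over the
  two sum distributions to trace the ROC.
* Spearman correlations use average ranks for ties; pairs containing a
  constant gene are skipped and counted.
* The full-scale resampling count in the literature of this method family is
  5000 draws; the package accepts any `R`. The test suite uses 100–200 draws
  per ensemble and, for the correction-improvement property, 50 replicate
  experiments of 3000 genes × 120 samples with 128 draws each — sizes chosen
  so the Monte-Carlo error of each mean TPR is well below the effects being
  asserted.

## Known limitations

* Corrections are defined on the log scale only; raw counts are not
  corrected in place.
* The polynomial transform class is global over the expression range; a
  distortion confined to a narrow expression band would be smoothed over.
* NLT invertibility is not enforced; with degree 3 and gentle distortions
  the fitted transforms are monotone in practice, and a warning flags the
  exception.
* With very few samples the consensus profile $\bar g_n$ is itself noisy and
  the distinction between "bias" and "biology" blurs; the deviations-sum-to-
  zero constraint means a single sample's bias is never identifiable in
  isolation, only relative to the cohort.
* Under gentle distortions the improvement in spiked-gene detection is small
  (fractions of a percentage point of TPR at FPR 0.01 on synthetic data, a
  few percent on real cohorts with stronger distortion); the main benefits
  are the variance reduction and the removal of correlation bias.
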