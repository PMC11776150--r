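# scaleleveler

Detection and correction of per-sample, expression-level-dependent scale
distortion in bulk RNA-seq expression matrices.

## The problem

Conventional RNA-seq normalizations (TPM, FPKM, TMM, RLE) rescale each sample
by a single multiplicative factor. On the log2 scale that is one additive
constant per sample — but block averaging of genes sorted by mean expression
reveals smooth, per-sample deviations that *depend on expression level*. No
overall factor can remove them; they inflate between-sample variance, bias
gene–gene correlation estimates, and blunt the sensitivity of two-population
t tests. The package is aimed at analysts working with genes × samples
expression matrices (counts, TPM or FPKM) who want to diagnose and remove
this distortion before downstream inference.

## The model

All analysis is on offset log values `g = log2(x + c)` (default `c = 0.25`,
the mean of small values that round to zero), restricted to genes with mean
log2 expression above 3 (raw mean above 8, where the offset distorts values
by at most `c/x = 1/32`). Writing `g_nm` for the measured level of gene `n`
in sample `m` and `ḡ_n` for its across-sample mean, the package provides
three corrections:

* **shift** — subtract each sample's mean deviation
  `s_m = (1/N) Σ_n (g_nm − ḡ_n)`; a multiplicative renormalization on the
  raw scale.
* **LLT** (local-leveling transform) — model the bias as a per-sample
  polynomial in the gene's mean level, `g_nm = G_nm + β_m(ḡ_n) + ε_nm` with
  `β_m(ḡ) = Σ_ℓ b_mℓ ḡ^ℓ`, fit by weighted least squares on block averages
  `⟨·⟩_K` over K consecutive mean-sorted genes, and subtract:
  `Ĝ_nm = g_nm − β̂_m(ḡ_n)`.
* **NLT** (nonlinear transform) — model a per-sample change of scale,
  `G_nm = α_m(g_nm) + ε_nm` with `α_m(g) = Σ_ℓ a_mℓ g^ℓ`, fit by unweighted
  regression of `⟨ḡ_n⟩_K` on the block averages of the sample's own value
  powers `⟨g_nm^ℓ⟩_K`, and evaluate: `Ĝ_nm = α̂_m(g_nm)`.

Defaults are degree `L = 3` and span `K = 50`. Block averaging is the key
device throughout: it suppresses per-gene noise by `1/√K` while leaving the
smooth per-sample bias intact, so a low-order polynomial becomes estimable.

A spiking/resampling framework quantifies what correction buys: a controlled
C-percent enhancement (`+log2(1 + C/100)`) is injected into all genes of a
random subpopulation, pooled-variance t statistics are computed against the
complement, and complementary CDFs and averaged ROC curves (TPR as a
function of FPR, averaged over draws, with 10th/90th percentile bands) are
compared across correction methods.

## Worked example

```r
library(scaleleveler)

# simulate a distorted cohort with known truth
cfg <- synthetic_config(n_genes = 4000, n_samples = 80, seed = 42)
ds  <- generate_synthetic_dataset(cfg)

# fit and apply the nonlinear transform
fit <- fit_nlt(ds$measured, degree = 3, span = 50)
corrected <- apply_nlt(ds$measured, fit)

median(abs(ds$measured$values - ds$truth$values))  # 0.0737
median(abs(corrected$values  - ds$truth$values))   # 0.0684

# spiked two-population test: mean TPR at FPR = 0.01 over 100 draws
splits <- draw_subpopulations(80, 10, R = 100, seed = 1)
tpr_at_1pct <- function(m) {
  roc_ensemble(
    spiked_runner = function(i) {
      s <- splits[[i]]
      two_population_t(spike(m, spike_design(s, 1:4000, 40)),
                       setdiff(1:80, s), s)
    },
    null_runner = function(i) {
      s <- splits[[i]]
      two_population_t(m, setdiff(1:80, s), s)
    },
    fpr_grid = 0.01, R = 100)$mean_curve[1]
}
tpr_at_1pct(ds$measured)  # 0.670
tpr_at_1pct(corrected)    # 0.673
```

The median per-entry reconstruction error drops from 0.074 to 0.068 log2
units — essentially the floor set by the generator's additive noise
(`noise_sd = 0.1` gives a median absolute residual of about 0.067) — and the
detection rate of 40%-spiked genes at a 1% false positive rate rises from
0.670 to 0.673 for this gentle distortion; gains grow with the distortion
magnitude.

A command-line wrapper is installed at `inst/scripts/scale-leveler` with
subcommands `transform`, `diagnose`, `correct`, `simulate` and `evaluate`;
see the header of that file for usage.

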