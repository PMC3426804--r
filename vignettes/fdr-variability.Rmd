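---
title: "Sources of variability in FDR estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sources of variability in FDR estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bumfdr)
library(dplyr)
```

# The problem

When tens of thousands of genes are tested for differential expression
between two groups, the list of "significant" genes is usually calibrated by
an estimate of the false discovery rate (FDR). Those estimates are built
from the empirical distribution of the per-gene p-values, and they behave as
if the p-values were independent draws. Real expression data are not like
that: genes travel in co-regulated groups, so the effective number of
independent measurements is far smaller than the gene count, and FDR
estimates computed from different subsets of the same samples can disagree
wildly.

`bumfdr` packages a simulation framework for taking that problem apart. It
generates two-group expression data with a known, block-correlated ground
truth, estimates the FDR with a beta-uniform mixture (BUM) model of the
p-values, and records — dataset by dataset — the quantities that expose
where the variability comes from: the BUM parameters, the logical upper
bound on the true-null proportion, the realised false discovery proportion
(FDP), the dispersion of the z-value ensemble, and the spread of the
pairwise-correlation density.

# The data-generating model

`simulate_experiment()` builds a `G × 2N` log2 expression matrix (N normal
and N cancer samples) in stages:

1. **Blocks.** Genes are partitioned into correlated blocks with sizes drawn
   as `1 + Poisson(ξ − 1)`, so the mean block size is exactly `ξ` and
   `ξ = 1` produces fully independent genes. The final block is truncated so
   sizes sum to `G`.
2. **Activity.** A fraction `active_fraction` of blocks is transcriptionally
   active. Inactive blocks contribute zero raw signal in *both* groups —
   activation never switches between groups — so the observed values for
   those genes are pure measurement noise near the detection floor.
3. **Correlation.** Each block gets a correlation magnitude
   `ρ ~ Beta(rho_a, rho_b)` and a negative-sign fraction `θ`: a fraction θ
   of the block's genes carries sign −1, the rest +1, and the within-block
   correlation matrix is the signed one-factor form
   `(1 − ρ)I + ρ s sᵀ`, which is positive semi-definite for any sign
   pattern. Sampling uses the equivalent factor construction
   (`shared block factor × sign + idiosyncratic noise`), which is exact and
   costs O(size) per block rather than a Cholesky factorisation.
4. **Baselines.** Active genes receive baseline log2 means
   `Normal(baseline_mean, baseline_sd²)` and per-gene biological standard
   deviations from a Gamma distribution with mean `gene_sd_mean`.
5. **Differential expression.** A fraction `ψ` of the *active* blocks
   (rounded half up) is flagged differentially expressed. Every gene in a
   flagged block receives an absolute log2 shift
   `|Δ| ~ Gamma(de_shape, de_rate)` and an independent fair-coin direction.
   With the default shape = rate = 10 the mean absolute log2 fold change is
   1 (a two-fold change) with a long right tail.
6. **Noise.** Raw-scale signal `S = 2^X` is observed as
   `Y = S·exp(H) + E` with multiplicative log-noise
   `H ~ Normal(0, mult_sd²)` and additive background
   `E ~ Normal(add_mean, add_sd²)`, clipped below at `floor` before the
   final log2.

Each stage runs on its own RNG sub-stream derived deterministically from the
single configuration seed. This has a useful consequence: changing `ψ` alone
changes *only* the injected shifts — the block layout, baselines and
sample-level noise are untouched, so DE-level comparisons are paired rather
than confounded with layout resampling.

## Defaults, and what they emulate

| parameter | default | meaning |
|---|---|---|
| `mean_block_size` (ξ) | 10 | mean size of co-regulated gene groups |
| `theta_scenario` (θ) | `"tent"` | per-block negative-sign fraction, uniform on (0, 0.5) via `0.5 − |x − 0.5|`, `x ~ U(0,1)` |
| `psi` (ψ) | 0 | fraction of active blocks differentially expressed |
| `active_fraction` | 0.7 | fraction of blocks transcriptionally active |
| `de_shape`, `de_rate` | 10, 10 | `|Δ|` law; mean log2 fold change 1 |
| `rho_a`, `rho_b` | 4, 4 | block correlation magnitude `Beta(4, 4)` — centred at 0.5, covering loosely to strongly correlated blocks |
| `baseline_mean`, `baseline_sd` | 6, 1.5 | log2 baseline means of active genes |
| `gene_sd_mean` | 0.5 | mean per-gene biological log2 sd (Gamma with shape 4) |
| `noise` | `mult_sd = 0.1`, `add_mean = 2`, `add_sd = 1`, `floor = 1` | raw-scale measurement noise |

The noise, baseline, correlation-magnitude and activity defaults are
*emulation defaults*: plausible values for log2-scale two-group microarray
data, chosen once and documented here, not quantities estimated from any
particular dataset. Everything is configurable through
`simulation_config()`.

The generator emulates the features that matter for FDR variability —
clumpy correlation, partial transcriptional activity, gamma-tailed effect
sizes, multiplicative plus additive noise. It deliberately omits
probe-level artifacts, normalisation effects, sample heterogeneity within a
group, and outcome-linked (survival) structure. Conclusions drawn from the
simulation therefore speak to the statistical geometry of correlated
p-values, not to any specific platform's artifact profile.

# The estimation machinery

## Gene-level tests

`gene_ttests()` computes a classical two-sample t-test per gene (pooled
variance by default, Welch by flag), two-sided, oriented cancer − normal.
Genes that are constant in both groups are reported with `t = 0`, `p = 1`
and a `zero_variance` flag rather than dropped: dropping them would thin the
uniform component of the p-value distribution and bias the BUM uniform
weight upward. `t_to_z()` maps each statistic through its own t CDF and the
standard normal quantile function, giving z-values that are standard normal
under the null.

## The BUM model

The p-value density is modelled as

$$f(p) = \lambda + (1 - \lambda)\,\alpha\, p^{\alpha - 1},
  \qquad 0 < p \le 1,\ 0 < \alpha, \lambda < 1,$$

a uniform null component of weight λ plus a Beta(α, 1) component that peaks
at zero. `fit_bum()` maximises the log-likelihood after logit-transforming
both parameters (smooth, unconstrained), from five fixed starting points,
keeping the best converged solution; p-values are floored at `1e-12`
because two-sided t p-values can underflow. Estimates are clamped to
`[1e-8, 1 − 1e-8]`: on pure-null data the uniform weight legitimately runs
to the boundary of the parameter space.

Because the density at `p = 1` is `λ + (1 − λ)α`, that quantity is the
largest uniform component consistent with the fit — the *logical upper
bound* `pi_ub` on the proportion π of true nulls. The model-based FDR of
the rule "call `p ≤ τ` significant" is

$$\widehat{\mathrm{FDR}}(\tau)
  = \frac{\pi_{ub}\,\tau}{\lambda\tau + (1-\lambda)\tau^{\alpha}} \wedge 1,$$

nondecreasing in τ. `cutoff_for_target_fdr()` inverts it by bisection
(tolerance `1e-10`) for the **largest** cutoff meeting the target — the most
permissive threshold that still controls the estimated FDR, which is the
threshold a practitioner would report. The boundary cases are encoded in
the return value: 1 when the target exceeds `pi_ub` (everything passes), 0
when no representable cutoff achieves the target (near-pure-null fits).

## Truth-based metrics

With simulation truth in hand, `fdp_curve()` tabulates true and false
positives on a cutoff grid and reports `FDP = FP / (FP + TP)`, defined as 0
when nothing is called — the convention that makes the FDR the expectation
of the FDP. Calls use the closed threshold `p ≤ τ`. The default grid is 50
log-spaced cutoffs from `1e-6` to 1.

## Dispersion summaries

`estimate_null_width()` estimates the width σ₀ of the central peak of the
z-value ensemble by central matching: counts in bins of width 0.1 on
[−2, 2], bins with ≥ 5 observations kept, quadratic least squares on the
log counts, `σ₀ = (−2c₂)^{−1/2}` from the curvature. The dispersion variate
is `A = (σ₀² − 1)/√2`, the coefficient of the second Hermite term in the
empirical-null expansion: correlation (or an excess of moderate effects)
widens the central peak when `A > 0` and narrows it when `A < 0`. The
z-values of *all* genes enter the estimate — the ensemble, not a known-null
subset, is what one can observe in practice.

`correlation_sd()` reports the standard deviation of the empirical
pairwise-correlation density (`corr.std`) from 50,000 uniformly sampled
gene pairs (exhaustive below that), with zero-variance genes resampled out.
For independent genes the sample correlation has sd `≈ 1/√(n − 1)`, which
provides the calibration check.

# Experiments

`run_grid()` drives a full factorial over sample sizes, block sizes, θ
scenarios and DE levels with per-(configuration, replicate) seeds derived
from a single base seed; each dataset contributes one row of BUM, FDP and
dispersion summaries. Stages fail independently: a degenerate empirical
null on a heavily correlated dataset flags the row and nulls the dispersion
columns without discarding the BUM and FDP records. `run_resampling()`
implements the subsampling protocol: repeated within-group subsamples, a
BUM fit and FDR-10% cutoff per resample, then each resample's *effective*
model-based FDR at the shared median cutoff (plus the true FDP at that
cutoff when truth is known).

## Problem sizes and study conditions

The trend analyses in the test-suite and the acceptance script run at desk
scale: G = 2000 genes, 20 replicates per configuration, N ∈ {10, 25, 100}
as needed, with the factorial enumeration itself checked at the full
4 × 8 × 4 = 128 cells. These sizes give standard errors comfortably below
the effects being asserted while keeping a full run in minutes on one core.

Two study-condition choices deserve explanation:

- **DE-level comparisons run with `active_fraction = 1`.** The nominal
  truth π = 1 − ψ (e.g. 0.9 at ψ = 10%) holds at the gene level only when
  DE blocks are drawn from all blocks; with the default 0.7 the gene-level
  DE fraction is ≈ 0.7ψ and the bookkeeping no longer matches the nominal
  level. The general factorial keeps the 0.7 default, where both active and
  inactive blocks coexist.
- **The dispersion-vs-FDP sign analysis runs at N = 10.** The joint sign
  structure — A and FDP negatively correlated when ψ varies, weakly
  positively correlated within fixed ψ — requires the dispersion variate to
  respond to ψ, which happens when test power is moderate and DE z-values
  land near the central matching window. At N = 25 with these effect sizes
  most DE z-values sit far outside [−2, 2] and A barely moves with ψ; the
  qualitative structure is a power-dependent phenomenon, not a universal
  constant of the model.

# Numerical choices and degenerate inputs

- BUM optimisation: analytic gradients under the logit reparameterisation,
  BFGS, relative tolerance `1e-10`, five deterministic starts. All-equal
  p-values are a degenerate-fit error; fewer than 100 p-values warns.
- FDR inversion: monotone bisection to `1e-10`; any monotone root-finder
  agreeing to that tolerance is equivalent.
- Central matching needs ≥ 3 populated bins and negative curvature;
  constant, bimodal, or centre-depleted z ensembles raise an
  estimation-failure error rather than returning a width.
- FDP at a cutoff with zero positive calls is 0 by convention.
- ψ and θ counts round half up (`round(0.5 · blocks)` selects, never
  drops, the half block).
- TSV serialisation writes doubles at 17 significant digits and re-parses
  them with base R's exact parser, so write-then-read is value-identical.

# Known limitations

- The block model draws independent blocks; overlap between pathways and
  hub-gene structure are not represented.
- The BUM model is the only FDR estimator shipped; it is fast and fits
  these p-value ensembles well, but alternative estimators (q-value-style,
  local FDR) would be needed to show estimator-independence of the
  conclusions.
- The dispersion variate is estimated from all genes' z-values; with very
  strong signal the central window is effectively null-only and A loses
  sensitivity to the DE fraction (see above).
- Survival outcomes, probe-level artifacts and normalisation pipelines are
  out of scope.

# A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  n_genes = 5000, n_per_group = 25, mean_block_size = 10,
  psi = 0.2, active_fraction = 1, seed = 7
)
exp <- simulate_experiment(cfg)
pv  <- t_to_z(gene_ttests(exp))
fit <- fit_bum(pv$p_value)
fit
tau <- cutoff_for_target_fdr(fit, target = 0.10)
fdp_curve(pv$p_value, exp$truth$is_de, c(0.001, 0.01, tau))
dispersion_summary(exp, z_values = pv$z)
```
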