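# bumfdr

Simulation-based analysis of why false discovery rate (FDR) estimates vary
so much between expression datasets — and between subsamples of the *same*
dataset.

When thousands of genes are tested for differential expression, FDR
estimates are computed from the empirical distribution of per-gene
p-values as if those p-values were independent. In real transcriptomic
data genes are correlated in co-regulated blocks, so the effective number
of independent measurements is far smaller than the gene count and the
estimates become unstable. `bumfdr` is for statisticians and computational
biologists who want to quantify that instability: it simulates two-group
log2 expression data with a known block-correlated ground truth, estimates
the FDR with a beta-uniform mixture (BUM) model, and measures how sample
size *N*, mean correlation block size *ξ*, and the true proportion of
differentially expressed blocks *ψ* drive both the magnitude and the
precision of everything downstream.

## The model in brief

**Generator.** Genes fall into blocks of mean size ξ (sizes
`1 + Poisson(ξ − 1)`); a block is transcriptionally active with fraction
`active_fraction`, carries a correlation magnitude ρ ~ Beta(4, 4) and a
fraction θ of negatively correlated genes, realised through the signed
one-factor correlation `(1 − ρ)I + ρssᵀ` (positive semi-definite for any
signs). A fraction ψ of the active blocks is differentially expressed:
each of its genes gets |Δ| ~ Gamma(10, 10) on the log2 scale (mean
fold change 2) with a random direction. Raw signal is observed through
multiplicative and additive noise, `Y = S·exp(H) + E`, floored and
log2-transformed.

**Estimator.** Gene-wise two-sample t-tests give p-values modelled by the
BUM density

    f(p) = λ + (1 − λ) α p^(α−1),   0 < p ≤ 1,  0 < α, λ < 1,

whose value at p = 1 bounds the true-null proportion from above:
π_ub = λ + (1 − λ)α. The model-based FDR of calling `p ≤ τ` is
`π_ub τ / (λτ + (1 − λ)τ^α)`, inverted by bisection to find the cutoff
achieving a target FDR.

**Diagnostics against truth.** The observed false discovery proportion
FDP = FP/(FP + TP) per cutoff; Efron's dispersion variate
`A = (σ₀² − 1)/√2` from the central-matching width σ₀ of the z-value
ensemble; and `corr.std`, the spread of the empirical pairwise-correlation
density. `run_grid()` sweeps factorial designs over (N, ξ, θ, ψ);
`run_resampling()` reproduces the subsample-stability experiment (the
cutoff achieving FDR 10% per subsample, and the effective FDR at the
median cutoff).

## Worked example

```r
library(bumfdr)

cfg <- simulation_config(n_genes = 5000, n_per_group = 25, mean_block_size = 10,
                         psi = 0.2, active_fraction = 1, seed = 7)
exp <- simulate_experiment(cfg)
#> <expression_experiment> 5000 genes x 50 samples (25 per group)
#>   5000 active genes, 977 differentially expressed (psi = 0.2)

pv  <- t_to_z(gene_ttests(exp))
fit <- fit_bum(pv$p_value)
fit
#> <bum_fit> n = 5000 p-values
#>   alpha = 0.0660, lambda = 0.7549, pi upper bound = 0.7711
#>   log-likelihood 12169.14, converged: TRUE

tau <- cutoff_for_target_fdr(fit, 0.10)   # 0.02782
fdp_curve(pv$p_value, exp$truth$is_de, c(0.001, 0.01, tau))
#>      cutoff  tp fp   tn  fn         fdp
#> 1 0.0010000 872  3 4020 105 0.003428571
#> 2 0.0100000 927 39 3984  50 0.040372671
#> 3 0.0278158 948 96 3927  29 0.091954023

dispersion_summary(exp, z_values = pv$z)
#>      sigma0            A  corr_std  n_z n_pairs
#> 1 0.9964292 -0.005040914 0.1727476 5000 50000
```

Reading the output: 977 of 5000 genes (19.5%) truly shift, but the BUM fit
bounds the null proportion at 0.771 — it *overestimates* the DE fraction
(22.9%), the characteristic bias of the upper bound. The cutoff
τ = 0.0278 targets a 10% estimated FDR; against the simulation truth the
realised FDP at that cutoff is 9.2%, so the estimate was honest in this
dataset — the point of the package is to show how much that agreement
fluctuates across replicates, block sizes and sample sizes. The dispersion
variate A ≈ −0.005 says the z-ensemble's central peak is essentially at
its theoretical width here; `corr.std` = 0.173 versus 0.143 for
independent genes at 50 samples reflects the added block correlation.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods; grid results are tidy tibbles ready for dplyr and
ggplot2.

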