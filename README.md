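# wfrecomb

Maximum likelihood inference of the **recombination rate** from a
continuously observed Wright–Fisher diffusion of haplotype frequencies.

## The problem

Recombination rates are usually inferred from a present-day sample by
integrating over unobserved evolutionary histories, which makes the
estimators noisy. This package asks the idealized complementary question:
if the *entire* trajectory of haplotype frequencies were observed, what
would the MLE of the recombination rate look like, and how well can it do?
The answer is an upper bound on the information available to any practical
method, and it is relevant to the growing body of time-series population
genetic data, which can be viewed as a noisy discretization of this object.
The audience is population geneticists and statisticians working on
diffusion-based inference for evolutionary parameters.

## The estimator

For a two-locus model with haplotype frequencies `X_ij(t)` on the simplex,
recombination drift `a_ij = ρ(X_i· X_·j − X_ij)` (no factor 1/2 in `ρ`),
and known mutation drift `c(x)`, the log-likelihood relative to the
completely linked model `ρ₀ = 0` is quadratic,
`log L_T(ρ) = ρY − ½ρ²I_T`, with

```
Y   = ∫₀ᵀ Σ_ij (X_i· X_·j / X_ij) dX̃_ij        (X̃ = X − ∫ c dt)
I_T = ∫₀ᵀ Σ_ij (X_ij − X_i· X_·j)² / X_ij dt    (observed information)
```

so the raw MLE is `ρ̂ = Y / I_T`. The corrected MLE rectifies this to the
parameter space `[0, ∞)` and handles the unusual feature of this problem:
the observed information can **explode in finite time** (at the stopping
time `S` when a haplotype frequency hits 0), whereupon the estimator
converges to the true rate and `ρ` is learned *without error*:

```
ρ̂_MLE = 1{T < S} · max{0, ρ̂_T}  +  1{S ≤ T} · lim_{t↑S} ρ̂_t .
```

A likelihood-ratio test of `ρ₀ = 0` uses `Λ = ρ̂²_MLE I_T` against the
boundary mixture null `½χ²₀ + ½χ²₁` (5% threshold ≈ 2.706, the 90th
percentile of a `χ²₁`), with `Λ = +∞` or `0` on exploded paths according to
the sign of the estimate. The package also provides selection-adjusted and
joint recombination/selection estimators, multi-locus (joint and
shared-rate) estimators, numeric confounder-robustness checks, and an
Euler–Maruyama simulator with a boundary-safe square-root diffusion factor.

## Worked example

```r
library(wfrecomb)

m <- wf_model(rho = 5, theta_A = 5, theta_B = 5)  # diallelic, symmetric mutation
p <- simulate(m, seed = 1, dt = 1e-4, t_end = 1)  # Euler-Maruyama path
fit <- rho_mle(p)
summary(fit)
#> Recombination-rate MLE (corrected): 5.247124
#>   raw estimator: 5.247124
#>   I_T = 0.05848474 over T_eff = 1
#>   curvature-based standard error: 4.135031 (quasi-likelihood; explosion regime excluded)

lrt_recombination(fit)
#> Likelihood-ratio test of rho_0 = 0 (boundary chi-squared mixture null)
#>   Lambda = 1.61022  threshold at level 0.05 = 2.705543
#>   decision: do not reject the no-recombination null
```

At this high mutation rate the path stays in the interior of the simplex,
information accumulates slowly (`I_T ≈ 0.058`), and even a true `ρ = 5`
cannot be distinguished from 0 on a single path of length 1. At a low
mutation rate the picture reverses — a haplotype frequency hits zero, the
information explodes, and the rate is learned exactly:

```r
m1 <- wf_model(rho = 1, theta_A = 1, theta_B = 1)
fit1 <- rho_mle(simulate(m1, seed = 2, dt = 1e-4), convention = "truth_assigned")
fit1
#> Recombination-rate MLE (corrected): 1
#>   raw estimator: 4.751267
#>   information exploded at S = 0.6345 ; convention: truth_assigned
```

A cell of the simulation study (here scaled down to 20 replicates on a
coarser grid):

```r
cell <- run_cell(theta = 1, rho = 1, n_replicates = 20, dt = 1e-4, seed = 1)
cell$summary
#>  theta rho_true     mean variance pct5 median    pct95 freq_zero_error power
#>      1        1 1.682189 1.571117    1      1 4.690742             0.7  0.85
```

`freq_zero_error` is the fraction of replicates whose information exploded
(and so estimated `ρ` exactly); `power` is the rejection rate of `ρ₀ = 0`
at level 5%. `run_table1()` runs the whole `θ ∈ {1, 5}`,
`ρ ∈ {0, 0.1, 1, 2.5, 5, 10, 25}` grid; `run_path_diagnostics()` returns
single-path series of the running estimator and running information.

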