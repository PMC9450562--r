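# spikedyn

Criticality diagnostics for neural population spike rasters: where does
spontaneous activity sit between the asynchronous-irregular regime, the
near-critical "reverberating" regime, and criticality proper?

The package is written for analyses of inferred-spike rasters (neurons ×
time bins with bin width Δt, e.g. from calcium imaging followed by spike
inference), where two practical obstacles dominate: only a subset of the
network is recorded (spatial subsampling) and the sampling is slow relative
to the neural timescale (temporal coarsening). Every estimator here is
paired with simulators that reproduce those obstacles on data with known
ground truth.

## What it computes

**Avalanche scaling.** Avalanches are maximal runs of nonzero population
activity between silent bins; size *S* = total spikes, duration *T* = bins.
Criticality predicts power laws f(S) ~ S^-τ, f(T) ~ T^-α, a conditional
mean ⟨S⟩(T) ~ T^β, and shape collapse s(t,T) ∝ T^γ F(t/T) with the
crackling-noise relation γ = β − 1. Discrete maximum-likelihood power-law
fits (Hurwitz-zeta normalization, KS-minimizing x_min) are compared against
the discrete exponential with a Vuong-normalized likelihood ratio; a power
law is claimed only when the ratio is positive and p ≤ 0.1.

**MR branching-parameter estimation.** The population activity is modelled
as a driven branching process ⟨A_{t+1} | A_t⟩ = m A_t + h. Regression
slopes r_k of A_{t+k} on A_t follow r_k = b·m^k, with spatial subsampling
absorbed entirely into the constant b — so the multistep-regression (MR)
fit of the decay recovers m where the naive one-step slope r_1 = b·m
underestimates. The autocorrelation time is τ = −Δt/ln m. A five-test
battery (H_offset, H_tau, H_lin, H_MR_invalid, H_poisson) screens for
nonstationarity and Poisson activity before any m̂ is reported, and
m̂ = φ^Δt fits convert estimates across sampling timescales
(m̂ = m_true^(Δt/ΔT)).

**Population statistics.** Windowed spike-count covariances give the mean
μ and width σ of the pairwise distribution, the normalized width
Δ = σ/c̄_ii, the distance to the dynamically balanced critical point
λ_max = 1 − 1/(1 + NΔ²), and the participation-ratio dimensionality
N_eff = (Σ λ̃_k²)^-1 from PCA explained-variance ratios.

**Synthetic data.** Driven branching processes, a 4-neighbour periodic
lattice network (per-edge Bernoulli transmission, implied branching ratio
4·p_transmit), binomial spike subsampling, systematic neuron subsampling,
temporal coarsening by summation or skipping, and time-shuffled Poisson
surrogates.

## Worked example

```r
library(spikedyn)

# a reverberating process at a 15 Hz sampling rate, recording-like length
s <- simulate_branching(0.9, 1, 13000, dt = 1/15, seed = 1)
mr <- mr_estimate(s)
print(mr)
#> <mr_result> m_hat = 0.9111, b_hat = 0.9725, tau = 0.716 s, k_max = 109
print(stationarity_battery(mr$r_k, s$dt))
#> <stationarity_report> verdict: accepted_clear
#>   flags: H_offset- H_tau- H_lin- H_MR_invalid- H_poisson-

# throw away 90% of the spikes: the MR estimate survives, r_1 does not
sub <- subsample_spikes_binomial(s, 0.1, seed = 2)
mr_sub <- mr_estimate(sub)
cat(sprintf("after keeping 10%% of spikes: m_hat = %.3f (r_1 alone: %.3f)\n",
            mr_sub$m_hat, mr_sub$r_k[1]))
#> after keeping 10% of spikes: m_hat = 0.908 (r_1 alone: 0.346)
```

The true m is 0.9: the fitted m̂ ≈ 0.91 is recovered both at full sampling
and under 10× spike loss (where the one-step slope collapses to 0.35), the
battery clears the run as stationary, and τ ≈ 0.7 s is the timescale over
which a perturbation persists.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the study-style pipeline on
synthetic data and write tables under `results/`:

1. `01_simulate.R` — branching processes across m ∈ {0, 0.5, 0.9, 0.985,
   0.9999} and the two lattice regimes, with ground-truth manifests.
2. `02_avalanches.R` — avalanche extraction, distribution comparison, β,
   shape collapse, crackling residual.
3. `03_mr_estimation.R` — MR + battery over a temporal-coarsening sweep and
   the φ conversion fit.
4. `04_subsampling.R` — binomial-vs-systematic subsampling sweeps (the
   invariance and its breakdown).
5. `05_popstats.R` — covariance distribution, Δ, λ_max, N_eff.

Run them in order from the repository root after installing the package.

## Acceptance script

`scripts/acceptance.R` regenerates a synthetic spectrum of datasets
(Poisson, subcritical, reverberating, shuffled surrogate) from the seed it
is given, runs the full pipeline on them (avalanches, MR battery,
coarsening sweep, φ fit), prints the report, and writes its JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/criticality-diagnostics.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, the
numerical choices (fit strategy, tie-breaks, degenerate inputs), what the
synthetic worlds do and do not establish, and known limitations.
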