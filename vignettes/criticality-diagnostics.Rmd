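---
title: "Where does population activity sit between asynchrony and criticality?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Where does population activity sit between asynchrony and criticality?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Spontaneous neural population activity can be asynchronous-irregular
(temporally decorrelated, fast-forgetting), critical (long-range
correlations, scale-free avalanches), or somewhere between — a near-critical
"reverberating" regime in which perturbations persist for hundreds of
milliseconds without diverging. `spikedyn` implements the analyses needed to
place a recording on that spectrum, starting from an inferred spike raster
(neurons × time bins, bin width $\Delta t$), together with simulators that
generate ground-truth data for every analysis.

The dynamical backbone is the driven branching process on the
population-summed activity $A_t$:

$$\langle A_{t+1} \mid A_t \rangle = m A_t + h,$$

where $m$ is the branching parameter ($m = 0$ Poisson/asynchronous, $m = 1$
critical, $m \lesssim 1$ reverberating) and $h$ the mean external drive per
bin. The autocorrelation time is $\tau = -\Delta t / \ln m$, which diverges
at criticality. The simulator draws
$A_{t+1} \sim \mathrm{Poisson}(mA_t) + \mathrm{Poisson}(h)$: the model
specifies only conditional means, and Poisson offspring is the minimal
choice with exact analytic means and variances for testing. The subcritical
stationary mean is $h/(1-m)$; simulations discard a 1000-bin burn-in.

## Avalanche scaling analyses

An avalanche is a maximal run of consecutive bins with $A_t > 0$, delimited
by silent bins; its size $S$ is the total spike count and its duration $T$
the bin count. Criticality predicts

$$f(S) \sim S^{-\tau_S}, \quad f(T) \sim T^{-\alpha}, \quad
\langle S \rangle(T) \sim T^{\beta}, \quad s(t, T) \propto T^{\gamma} F(t/T),$$

with the crackling-noise consistency condition $\gamma = \beta - 1$.

Distribution fits use the discrete maximum-likelihood power law
($P(x) = x^{-\alpha}/\zeta(\alpha, x_{\min})$, Hurwitz-zeta normalization,
Euler–Maclaurin evaluation) with $x_{\min}$ selected by Kolmogorov–Smirnov
distance minimization, and a Vuong-normalized likelihood-ratio comparison
against the discrete exponential. The power law is "favored" only when the
ratio is positive *and* $p \le 0.1$ — the reporting convention under which a
heavy tail may be claimed. No installed R package provides this discrete
machinery, so it is implemented here and validated against an inverse-CDF
sampler with known exponent.

Choices worth knowing:

* **Edge-truncated avalanches** (runs touching the first or last bin) are
  extracted and flagged but excluded from fits by default: their sizes are
  censored. A series with *no* silent bin (common at slow sampling rates)
  yields an empty avalanche set plus a warning, not an error.
* **Shape collapse** follows the variance-over-span-squared objective: drop
  $T < 5$ and durations with fewer than 3 avalanches, average profiles per
  duration, rescale time to $[0,1]$, linearly interpolate at 1000 points,
  scale by $T^{-\gamma}$, and minimize (mean pointwise variance across
  durations) / (span of the scaled profiles)$^2$ over $\gamma \in [0,5]$ by
  a 0.1 → 0.01 → 0.001 coarse-to-fine grid.
* Linear interpolation of a curved profile sampled at few points has an
  irreducible error floor: with parabolic profiles and durations as short
  as 5 bins the collapse error bottoms out near $10^{-4}$ and the optimum
  shifts upward by $\approx 0.02$; with durations $\ge 20$ the error falls
  below $10^{-6}$ and $\gamma$ is recovered to the grid step. Tests pin
  both behaviours.

## The MR estimator and its guard rails

Regressing $A_{t+k}$ on $A_t$ for lags $k = 1 \dots k_{\max}$ gives slopes
$r_k$. Under full sampling $r_k = m^k$; under spatial subsampling
$r_k = b\,m^k$ with an unknown but *constant* bias $b$ — so fitting the
exponential decay recovers $m$ even when only a fraction of neurons or
spikes is observed, which is precisely where the naive one-step slope
$r_1 = bm$ fails. The fit is profile least squares: for fixed $m$ the
amplitude(s) are linear, so the search is one-dimensional in $m$ over a
dense grid with local refinement, with ties broken toward the smaller
residual and then the smaller $m$. This replaces the more conventional
multi-start Levenberg–Marquardt: it is deterministic, cannot fail to
converge, and optimizes the identical objective.

`k_max` defaults to $\min(\lceil 10\,\hat\tau/\Delta t\rceil,
\lfloor n/10 \rfloor)$ (floor 20), with $\hat\tau$ from a quick exponential
fit to the first 50 slopes.

Before $\hat m$ is reported, the slope curve is screened:

| flag | fires when | failure mode caught |
|---|---|---|
| `H_offset` | offset model halves the exponential's residual | transient drive increase |
| `H_tau` | $\tau$ of plain vs offset fit differ by > 200% | drive ramp |
| `H_lin` | a straight line beats the exponential | state switches |
| `H_MR_invalid` | one-sided t-test of mean $r_k > 0$ has $p \ge 0.1$ | flat slope curve, fit uninterpretable |
| `H_poisson` | (given `H_MR_invalid`) slope of $r_k$ vs $k$ has $p \ge 0.05$ | genuine Poisson activity, $m = 0$ |

"Residual" is the sum of squared fit residuals throughout — the factor-2
comparison in `H_offset` is only meaningful on that scale. Verdicts:
nonstationarity flags reject; `H_MR_invalid` + `H_poisson` accept with
$m = 0$; `H_MR_invalid` alone is `invalid`. The `lenient` acceptance policy
additionally accepts datasets whose *only* positive flags are the last two,
because short stationary recordings trip them by sampling fluctuation alone.

Two numerical honesty notes, both measured during development. First, a
numerically perfect exponential fit leaves both models at machine-epsilon
residuals where the factor-2 rule becomes a coin flip; residuals below
$10^{-12}\,\lVert r \rVert^2$ therefore count as a perfect exponential fit.
Second, on *long* stationary simulations ($10^5$ bins) `H_offset` falsely
rejects 30–60% of runs: the many pure-noise tail slopes are serially
correlated and a fitted offset absorbs their common shift. This is intrinsic
to the test's definition, weakens at recording-like lengths
($\sim 10^4$ bins), and is why a screened-out recording should be read as
"not interpretable by this battery", not "nonstationary with certainty".

## Timescale conversion

A branching process observed at a coarser bin $\Delta t = n\,\Delta T$ has
effective parameter $\hat m = m_{\mathrm{true}}^{\,n}$; at criticality
$m = 1$ is scale-invariant. Across sampling rates
$\hat m = \phi^{\Delta t}$ with $\phi = m_{\mathrm{true}}^{1/\Delta T}$,
fitted through the origin in log domain for stability, with explicit
outlier exclusion. Two coarsening modes are provided: `skip` keeps the last
bin of each block (classical subsampling), `sum` totals the block (what
slow-indicator spike inference effectively measures). Both drop a trailing
partial block, so `sum`-coarsening commutes exactly with population
summation.

## Covariance, dimensionality, and the balanced critical point

Spike counts are totalled per neuron in contiguous windows (default 2 s, or
a multiple of the recording's own $\tau$; widths floor to whole bins). The
unbiased pairwise covariances $\hat c_{ij}$ give the mean $\mu$ and width
$\sigma$ of the off-diagonal distribution and the normalized width
$\Delta = \sigma / \bar c_{ii}$. Avalanche criticality predicts large $\mu$
with small $\sigma$; the asynchronous/balanced regime the reverse. The
distance to the *dynamically balanced* critical point is
$\lambda_{\max} = 1 - 1/(1 + N\Delta^2)$ with $N$ the full network size
(default 1500) — not the recorded neuron count. $\Delta$ estimated from few
windows is biased; a jackknife-over-subsets corrected value is reported
alongside, clearly labelled as a surrogate for the canonical correction.
Dimensionality is the participation ratio
$N_{\mathrm{eff}} = (\sum_k \tilde\lambda_k^2)^{-1}$ over PCA
explained-variance ratios (per-neuron centering, no scaling); avalanche
criticality implies $N_{\mathrm{eff}} \approx 1$ with uniform loadings.

## What the synthetic worlds do and do not establish

The generators reproduce the mechanisms the analyses are sensitive to —
branching dynamics, spatially clustered propagation (the 4-neighbour
periodic lattice with per-edge Bernoulli transmission, implied branching
ratio $4 p_{\mathrm{transmit}}$), binomial spike loss, systematic neuron
selection, temporal summation vs skipping, and shuffled Poisson surrogates.
They do not emulate calcium-indicator dynamics, spike-inference errors,
cell-type heterogeneity, or real connectivity, so a green test establishes
correctness of the estimators on their generative assumptions, not the
biological conclusions for any particular recording.

Defaults the analysis design leaves open, chosen once:

* Branching drive is set so the stationary mean is $\approx 10$ events/bin
  — the scale at which avalanches are separated by silent bins at
  recording-like rates.
* The lattice subsampling experiment runs two regimes at the 4 ms fine
  timescale, summed ×15 to a 60 ms measurement timescale. The reverberating
  regime ($m^{15} = 0.7972$) uses 0.125 spikes/s per unit: sparse,
  avalanche-like activity, which is where the summation + systematic
  subsampling bias mechanism operates (measured-site spacing exceeds the
  activity diffusion length within one coarse bin once fewer than ~100 of
  2500 sites are kept). The near-critical regime ($m^{15} = 0.9985$) is
  necessarily dense: stationary fluctuations of a branching process scale
  as $\mathrm{sd}(A)/\langle A\rangle = \sqrt{1/(2\langle A\rangle(1-m))}$,
  so at $m = 0.9999$ any population mean below $\sim 5000$ leaves the
  process absorption-dominated and no estimator can see $m$. Density is a
  consequence of the regime, not a free knob.
* Near-critical avalanche simulations use $m = 0.9999$ with $h = 0.001$:
  large avalanches separated by genuine silences.

## Known limitations

* The stationarity battery treats the $k_{\max}$ slopes as independent
  samples in its t-test, as the procedure defines; no dependence correction
  is applied.
* On an exactly flat noise slope curve (genuine Poisson activity) the strict
  `H_lin` comparison is close to a coin flip — a two-parameter line fits
  pure noise better than the two-parameter exponential about half the time —
  so Poisson inputs split between `accepted_poisson` and
  `rejected_nonstationary` rather than all landing on the former. Either
  way no branching parameter is reported, which is the scientifically
  relevant outcome.
* `H_offset`'s false-rejection rate on long stationary series (above) means
  pipeline acceptance rates on simulations should be read per recording
  length.
* The discrete power-law sampler is exact up to $x = 10^6$ and uses a
  continuous-approximation tail beyond (mass $< 10^{-3}$ at the exponents
  used here).
* $\lambda_{\max}$ inherits the small-sample bias of $\Delta$; only the
  labelled jackknife surrogate is provided, not the canonical correction.
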