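---
title: "Modelling metabolite heterogeneity with Poisson mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metabolite heterogeneity with Poisson mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metanoise)
```

## The model

`metanoise` studies how stochastic enzyme expression propagates to
cell-to-cell variability in a metabolite. The model couples two
classical building blocks into one jump process:

* **Catalysis** — reversible Michaelis–Menten kinetics on a constant
  substrate pool of `n_s` molecules: substrate and free enzyme bind at
  rate constant `k_1` to form a complex, which dissociates at `k_m1`,
  converts to product at `k_cat`, or is re-formed from product and free
  enzyme at `k_rev`. The metabolite is consumed by downstream pathways
  at a first-order rate `k_c`.
* **Expression** — the three-stage gene expression model: a single-copy
  promoter switches between inactive and active states (`k_on`,
  `k_off`), transcribes at `k_tx` when active, transcripts are
  translated at `k_tl` and degraded at `k_deg`, and enzyme (free and
  complexed) is diluted by growth at `delta`.

All twelve reactions follow mass action kinetics; `ssa_simulate()`
generates exact sample paths with the Gillespie direct method. The
default parameter preset (`preset_rate_constants("table1")`) places the
system in a physiologically realistic corner: a doubling time of about
46 minutes (`delta` = 2.5e-4 s⁻¹), a handful of mRNAs, on the order of
a hundred enzymes, and on the order of a thousand metabolite molecules.

## Timescale separation and the Poisson Mixture Model

At such parameters the dynamics span three well-separated timescales:

1. substrate binding/unbinding, with rate scale `k_1 n_s + k_m1`
   (thousands per second);
2. catalysis and consumption, with scale
   `max(k_cat, k_rev n_p, k_c)` (order 1–10 per second);
3. enzyme expression and dilution, with scale `delta` and the switching
   rates (1e-4–1e-2 per second).

Because total enzyme `n_etot = n_e + n_c` is conserved by binding and
catalysis, it evolves only on the slow timescale. Conditioned on
`n_etot`, fast binding equilibrates the free/bound split at the
saturation fraction `epsilon = k_1 n_s / (k_1 n_s + k_m1)`, and the
metabolite becomes a linear birth–death process with birth
`k_cat epsilon n_etot` and per-molecule death
`k_rev (1 - epsilon) n_etot + k_c` (`reduced_propensities()`). Its
stationary law is Poisson with

$$\lambda(n_{etot}) = \frac{\lambda_\infty}{1 + K/n_{etot}}, \qquad
\lambda_\infty = \frac{n_s\,k_{cat}\,k_1}{k_{rev}\,k_{-1}}, \qquad
K = k_c\,\frac{k_1 n_s + k_{-1}}{k_{rev}\,k_{-1}},$$

both in molecules per cell, with the identity
$\lambda_\infty/K = \epsilon\, k_{cat}/k_c$ (`effective_kinetics()`,
`kinetic_line()`). For an irreversible reaction (`k_rev = 0`) the
saturating form degenerates; the package represents that case as an
explicit linear regime, $\lambda(n) = k_1 n_s k_{cat}/((k_1 n_s +
k_{-1}) k_c)\, n$, rather than as infinite parameters, because silent
infinities would corrupt every downstream mixture.

Marginalising over the enzyme gives the Poisson Mixture Model (PMM):

$$P(n_p) = \sum_{n_{etot}=0}^{\infty} P(n_{etot})\,
  \mathrm{Poisson}(n_p;\, \lambda(n_{etot})),$$

assembled by `pmm_distribution()` from any enzyme distribution: the
analytic three-stage law (`three_stage_pmf()`), a measured single-cell
histogram (`empirical_pmf()`), or a fitted Gamma distribution
discretised to integer copy numbers (`gamma_discretized_pmf()`). The
`n_etot = 0` term is a point mass at zero — the subpopulation that
carries no enzyme makes no product.

The approximation needs all three gaps to be wide. `timescale_
diagnostics()` reports the two ratios and flags any below a validity
factor (default 10×, configurable); the factor is a package choice, as
only qualitative separation is usually stated for such reductions.

## The three-stage stationary law and its evaluation

With fast mRNA turnover (`k_deg >> delta`) the stationary enzyme
distribution has the closed form

$$P(n) = \frac{\Gamma(\alpha_+ + n)\,\Gamma(\alpha_- + n)\,
  \Gamma(\gamma)}{\Gamma(n+1)\,\Gamma(\alpha_+)\,\Gamma(\alpha_-)\,
  \Gamma(\gamma + n)} \left(\frac{b}{1+b}\right)^{n}
  \left(\frac{1}{1+b}\right)^{\alpha_+}
  {}_2F_1\!\left(\alpha_+ + n, \gamma - \alpha_-; \gamma + n;
  \tfrac{b}{1+b}\right)$$

with `gamma = (k_on + k_off)/delta`, `a = k_tx/delta`,
`b = k_tl/k_deg`, and `alpha_pm` the roots of
$z^2 - (a+\gamma) z + a\,k_{on}/\delta$. The placement of the
*activation* rate in the product of roots matters and is fixed by the
analytic limits: `k_off = 0` must give the negative binomial with shape
`a`, `k_on = 0` a point mass at zero, and fast switching a negative
binomial with shape `a k_on/(k_on+k_off)`. Some published statements of
this solution carry a typo with `k_off` in the product; that variant
fails all three limits and disagrees with the master equation (total
variation ≈ 0.75 on an asymmetric test set, against ≈ 1e-5 for the
form used here). The package asserts the limits in its test suite and
validates the full formula against a finite-state master-equation
solve.

Numerically, the Gamma-function ratio is evaluated with `lgamma` and
the hypergeometric factor by its Gauss series at argument
`b/(1+b) < 1`. Because `alpha_- <= gamma <= alpha_+`, every series
term is non-negative, so plain accumulation (rescaled into log space
when large) is stable to near machine precision; no extended-precision
arithmetic is needed — there is no cancellation to lose digits to.
Non-convergence within the term cap is signalled with the offending
parameters. Degenerate promoters short-circuit the formula: `k_on = 0`
returns the point mass directly and `k_off = 0` the negative binomial,
avoiding 0/0 in the roots.

Distributions are truncated at a configurable tail tolerance (default
1e-8 of total mass) and carry an explicit `tail_mass_bound`, so
downstream consumers can account for the missing tail instead of
silently renormalising it away. The per-mode Poisson windows in the
mixture extend to mean ± 12 standard deviations + 30, which keeps the
per-mode truncation error far below the tail tolerance.

## Oracles

Two independent references validate the analytic machinery:

* `cme_stationary()` solves the truncated chemical master equation on a
  state box (reflecting truncation), either by a sparse LU solve with
  one state pinned (the pinned state is located by a short power
  iteration, because pinning a negligible state overflows the solved
  ratios) or, beyond ~20000 states where the LU fill-in of
  high-dimensional boxes becomes prohibitive, by uniformised power
  iteration with a residual stopping rule. Boundary mass above a
  tolerance aborts the solve with a message to enlarge the caps.
* the SSA itself, which is exact for the full network.

Validation runs use down-scaled parameter sets (`n_s = 30`, copy-number
means below 20, rates within a couple of orders of magnitude) so the
truncated state space stays below ~1e5 states and the chain mixes
within seconds of simulated time.

## Exact simulation at realistic parameters

A single direct-method event costs nanoseconds, but at the nominal
parameters the binding/unbinding pair fires ~1e5 times per second of
simulated time, and stationary histograms need hundreds of cell cycles
(~5e5 s): that is ~1e11 events per parameter set, hours of computation
for a single comparison. The package therefore provides
`compress_timescales()`, which rescales the hierarchy while preserving
the PMM exactly:

* scaling `k_1` and `k_m1` jointly leaves `epsilon`, `lambda_inf` and
  `K` unchanged and only slows the (irrelevantly fast) binding
  equilibration;
* scaling `k_on, k_off, k_tx, k_tl, k_deg, delta` jointly leaves
  `gamma`, `a`, `b` and `k_deg/delta` — and therefore the exact
  stationary enzyme law — unchanged while shortening the cell cycle.

The package's mixture-versus-simulation validation uses binding × 0.25
and expression × 25, which keeps both diagnostic ratios above the 10×
validity factor (binding/catalysis ≈ 100×, catalysis/expression ≈
13×), and simulates 2020 cell cycles (20 discarded as burn-in). The
run length is set by the sampling noise of an occupancy histogram: the
enzyme marginal is known exactly, and its empirical total-variation
distance after T cell cycles is ≈ 0.1 sqrt(200/T), so a 0.05 tolerance
needs on the order of a thousand cycles — a few hundred cycles leave
the comparison noise-floor-limited regardless of model quality.
Residual discrepancy at these settings is ≈ 0.03, part sampling noise,
part the O(1/separation) bias of the quasi-equilibrium reduction,
which shrinks as the binding factor is raised toward 1.

Histograms are accumulated from exact event holding times during the
run (not from the thinned recording grid), so thinning affects storage
only. The simulator uses its own xoshiro256++ generator seeded from the
`seed` argument: trajectories are bit-identical across runs and
platforms and independent of R's RNG state. Default initial state is
all-zero with the promoter off; stationary summaries must not depend on
it (tested), only on the burn-in (default 20 cell cycles) being long
enough.

## Modality rules

Regime maps classify each distribution as unimodal, bimodal or
multimodal:

* **peaks** on a discrete pmf are indices that rise from the previous
  run of equal values and fall to the next; plateaus collapse to their
  leftmost index, and both boundaries can be peaks (the spike at
  `n_p = 0` *is* the no-enzyme mode and must be countable);
* **bimodal** if some pair of peaks has smaller/larger height ratio at
  least 10% and the trough between them at most 10% of the smaller
  height — the scan covers all candidate pairs, not just the two
  tallest, because widely separated minor modes can certify bimodality
  under a dominant spike;
* **multimodal** if, beyond a bimodal pair, an additional peak exceeds
  the absolute height 1e-4 and the trough to a neighbouring peak is at
  most 90% of the smaller of the two neighbouring heights ("its
  height" is read as that smaller neighbour; the trace records the
  thresholds that fired so alternative readings can be compared).

Two practical guards accompany the rules. First, a relative visibility
floor (default 1e-4 of the highest mass) excludes peaks that no
finite-sample histogram could resolve: an analytic mixture evaluates
side-modes of mass 1e-7 and below exactly, and such invisible mode
pairs would otherwise satisfy the (scale-free, hence floorless)
bimodality rule. The floor is relative, so bimodality remains
scale-free; the multimodality rule keeps its absolute threshold by
construction. Second, finite-sample SSA histograms may be smoothed by
a centred moving average (off by default; partial windows at the
boundaries so a genuine boundary mode is attenuated rather than
erased) before classification, because single-bin sampling spikes
otherwise register as spurious peaks. Analytic PMM pmfs are never
smoothed.

Exact-simulation histograms additionally expose fine structure the
mixture does not model: whenever the metabolite drains after the last
enzyme disappears, it transits every copy number on the way down,
leaving a shallow occupancy shelf proportional to `1/(k_c n_p)`
between the producing mode and zero. At affordable run lengths the
shelf is lumpy and its low-`n_p` end can exceed the 1e-4 absolute
threshold, so classifying a raw histogram can return spurious
multimodality. When validating sweep labels against simulation, the
package classifies histograms with a raised visibility floor (2% of
the maximum — roughly the resolution of a plotted histogram), which
removes the shelf while leaving both genuine modes intact.

One consequence of counting the boundary spike deserves note: in the
promoter-switching maps, catalytically-induced bimodality (unimodal
enzyme, bimodal metabolite) does not vanish entirely at small
`lambda_inf` — a weakly expressed enzyme with an appreciable no-enzyme
probability keeps a qualifying zero-spike/producing-mode pair at
`lambda_inf = 300` in a narrow band of fast switching and low activity
(and exact simulation of the full network confirms the bimodal
histogram there). Detectors that ignore boundary bins, or that operate
on coarsely binned histograms in which the single-bin spike at zero is
averaged away, classify those points unimodal; under such detectors
the catalytic region survives only where the non-zero Poisson modes
are mutually separated, which requires large `lambda_inf`. The package
keeps the boundary-counting definition because the zero mode is the
biologically meaningful non-producer subpopulation.

## Parameter sweeps

`switching_sweep()` evaluates the PMM over a grid of promoter
switching timescale (`k_on + k_off`, log-spaced) and promoter activity
(`k_on/(k_on + k_off)`, linear) — these axis definitions are package
choices, recorded in the output metadata. Varying `lambda_inf` down a
column corresponds to increasing `k_cat`, which leaves `K` untouched.
Each point stores both the enzyme and metabolite labels, so
switching-induced (bimodal → bimodal) and catalytically-induced
(unimodal → bimodal) regimes are distinguished, along with the full
rule traces for re-thresholding without re-computation. Wide default
ranges (1e-6–1e-1 s⁻¹ for the timescale) cover slow and fast
switching relative to the nominal dilution rate. `kinetic_sweep()`
fixes the enzyme distribution and maps `(lambda_inf, K)`; a 20 × 20
map evaluates in about a minute on one CPU, which is the point of the
analytic mixture. Per-point failures are recorded with reasons and do
not abort the sweep.

Where only `(lambda_inf, K)` pairs are published for a regime (the
decomposition into five rate constants is not unique), the presets
store the effective pair directly rather than inventing rate
constants; the simulation spot-checks construct a realisation
explicitly and state the constraints used.

## What the presets emulate — and what they do not

The presets describe a single enzymatic reaction under constant
substrate, with first-order consumption standing in for the downstream
pathway and first-order dilution for growth. Passing tests on these
conditions show that the mixture reproduces the exact stationary law
of *this* network across the probed regimes; they do not speak to
product inhibition, allosteric feedback, transcription-factor
regulation of the enzyme, explicit cell division with binomial
partitioning, extrinsic noise, or time-dependent (non-stationary)
behaviour — all outside the model class. The Gamma-distribution input
mimics the common practice of summarising measured single-cell protein
distributions by fitted Gamma laws; real measurement noise,
autofluorescence and gating artefacts are not modelled.

## Known limitations

* The three-stage closed form assumes `k_deg >> delta`; at ratios
  below ~1000 its error becomes visible at the 1e-3 total-variation
  level (the master-equation oracle is exact and can be used instead
  for small systems).
* The quasi-equilibrium reduction biases the mixture when the binding
  scale is within an order of magnitude of `k_rev * n_p` — strongly
  reversible, high-copy regimes need care; the diagnostics flag them.
* Classification inherits the arbitrariness of any threshold rule
  near regime boundaries; the stored rule traces make the decisions
  auditable.
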