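---
title: "Surrogate-transfer global sensitivity analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-transfer global sensitivity analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoreglos)
```

## The problem

Agent-based models (ABMs) of cell populations are stochastic, rule-based and
expensive: a single global sensitivity analysis (GSA) can require thousands of
ensemble simulations. **smoreglos** implements a surrogate-transfer strategy:
a cheap, explicitly formulated ODE surrogate is calibrated to ABM ensembles at
a modest number of sampled ABM parameter vectors, the *uncertainty* of each
surrogate parameter is traced over ABM parameter space as a pair of
confidence hypersurfaces, and any GSA method (Morris screening, eFAST) is then
driven through the surrogate instead of the ABM. The key approximation is

$$f(p_{ABM}) \;\approx\; \int_{\Omega_{SM}(p_{ABM})} \tilde f(p_{SM})\,
d\mu(p_{SM};p_{ABM}),$$

where $\Omega_{SM}(p_{ABM})$ is the hyperrectangle formed by the per-parameter
95% confidence intervals of the surrogate at $p_{ABM}$, $\mu$ is uniform on
that box, and $\tilde f$ is the output metric evaluated on surrogate
trajectories. The global sensitivity of $f$ is then estimated by applying the
chosen GSA method to this box-averaged metric. The estimator is agnostic to
the GSA method.

## The bundled ABM

The test system is a 2D on-lattice birth–death–migration model of an *in
vitro* cell proliferation assay with explicit cell-cycle phases (G1, S, G2,
M). The update rules are a reconstruction built for this package:

* fixed time step $\Delta t = 0.01$ d; each step visits all cells in a fresh
  random order; daughters born in a step are not updated until the next step;
* each cell attempts one phase transition with probability
  $1 - e^{-\rho\,\Delta t}$ using its phase's rate, then one migration step to
  a uniformly chosen empty Moore neighbour with probability
  $1 - e^{-s\,\Delta t}$;
* **contact inhibition acts at the restriction point**: the G1$\to$S
  transition is arrested while more than `T_con` of the 8 Moore neighbours are
  occupied. We deliberately do *not* trap cells in M when crowded: a
  division-blocking formulation accumulates cells in G2/M at confluence,
  which is the opposite of the G1 arrest seen in real contact-inhibited
  monolayers and of the behaviour the surrogate is meant to capture;
* the M$\to$G1 transition always completes; it yields a daughter G1 cell in a
  uniformly chosen empty Moore neighbour only if the parent is not
  contact-inhibited and the division survives a global logistic thinning
  (blocked with probability $N/K_A$). The parent re-enters G1 either way,
  mirroring the surrogate's division-yield factor $(2 - N/K_C)$, which moves
  from 2 (true division) toward 1 (bare transition) as the population
  approaches capacity;
* the lattice is $100\times100$ with reflecting edges; `n_initial = 1000`
  cells (10% confluence, typical seeding for a 3-day proliferation assay) are
  placed at random distinct sites. Seeding much sparser than this cannot
  approach the carrying-capacity plateau within the 3-day observation window
  for realistic cycle times, which would leave the contact-inhibition and
  capacity parameters without any regime in which to act;
* initial phases are drawn 40/30/20/10% for G1/S/G2/M, the composition of an
  asynchronous growing culture. A uniform 25% draw would start the G1/S
  vs G2/M pools exactly at the symmetric-rate equilibrium of the surrogate,
  which erases the transient that identifies the absolute (not just
  relative) transition rates in no-growth regimes;
* recording times are $\{0, 0.5, \dots, 3\}$ days.

Default GSA ranges: transition rates $[0.5, 4]$/day, migration $[0, 50]$/day,
$K_A \in [1000, 8000]$ cells, `T_con` $\in \{1,\dots,7\}$. `T_con` is treated
as continuous for design generation and field interpolation and rounded only
when an actual ABM simulation is launched.

What the generator does *not* emulate: cell death, heterogeneous cycle-time
distributions (phase exit is memoryless), nutrient or oxygen fields, and 3D
growth. Tests passing on this system therefore validate the machinery and
its internal consistency, not the behaviour of any particular laboratory
system.

## Surrogates

Two families are built in:

* the two-pool cell-cycle model
  $\dot N_{1S} = -\lambda_C N_{1S} + \alpha_C\,(2 - N/K_C)\,N_{2M}$,
  $\dot N_{2M} = \lambda_C N_{1S} - \alpha_C N_{2M}$, with
  $N = N_{1S}+N_{2M}$; the total equilibrates at $K_C$;
* single-variable growth laws: exponential ($\lambda$), logistic ($r, K$) and
  von Bertalanffy ($\dot N = \alpha N^{\theta} - \beta N$,
  $\theta = 1 - 1/\nu$, $\nu > 1$, equilibrium $(\alpha/\beta)^{\nu}$),
  used with the stochastic mock growth-curve generator that stands in for an
  expensive external ABM.

Exponential and logistic solutions use closed forms. The cell-cycle and von
Bertalanffy systems are integrated by a fixed-step classical Runge–Kutta
scheme in compiled code (default step 0.01 d; local error $O(h^5)$, and the
suite cross-checks the trajectories against an adaptive reference solver to
$10^{-4}$ relative). The fixed-step choice keeps a single objective
evaluation at a few microseconds, which is what makes profiling over a
hundred thousand re-optimizations practical on one CPU.

## Fitting, profiles, identifiability

Fits minimize the normalized weighted RSS
$\frac{1}{n_{obs}}\sum_{t,v} \left[(SM(t,v) - \bar y(t,v))/SD(t,v)\right]^2$
with per-point ensemble standard deviations as weights, floored at
$\max(1\%\ \text{of the final-time mean total},\ 1\ \text{cell})$. A
well-specified model then fits with RSS near 1. Initial conditions are fixed
to the ensemble mean at the first recording time, so the free parameter
counts are 1 (exponential), 2 (logistic), 3 (von Bertalanffy and cell-cycle).
Optimization is derivative-free: Nelder–Mead on log-transformed parameters
with a quadratic out-of-bounds penalty, restarted from 10 Latin-hypercube
points in the log-bounds box; ties are broken by lowest RSS, then
lexicographically smallest parameter vector. One-parameter models use
golden-section search on the log-interval instead.

Profile likelihoods fix one parameter on a 41-point log grid spanning
$[\hat\theta/100,\ 100\,\hat\theta]$ (clipped to the search bounds; the
best-fit value itself is inserted into the grid so the profile always
contains its minimum) and re-optimize the remaining parameters, warm-started
outward from the optimum. The 95% bounds are the outermost crossings of
$RSS^* + \Delta$ with $\Delta = RSS^*\,\chi^2_{0.95}(1)/n_{obs}$ — the
likelihood-ratio threshold for Gaussian errors under this normalized
objective (with unit-variance weights it reduces to the classic
un-normalized $\Delta RSS = 3.84$). The $RSS^*$ factor makes the rule
invariant to an overall rescaling of the weights, behaving like a variance
estimated from the residuals; the suite's linear-Gaussian calibration
experiment uses $n = 100$ observations and a profile grid fine enough to
resolve the interval (the crossing is located by chords, which bias inward
on grids much coarser than the interval itself), where the empirical
coverage of the 95% interval sits within a few points of nominal.

Each surrogate parameter at each ABM vector receives the identifiability
index: 2 if both 95% bounds are finite and inside the biologically relevant
range (rates $(0, 100]$/day, capacities $(0, 10^6]$ cells), 1 if exactly one
is, 0 otherwise; a profile whose total variation is below $\Delta/10$ is
classified flat. On this generator two honest limitations surface: at ABM
vectors whose dynamics equilibrate within the first 0.5-day recording
interval, the fast direction $\lambda_C + \alpha_C$ is unconstrained from
above (index 1), and strongly arrest-dominated corners are misspecified for
the two-pool model. Both reduce the index-2 frequency below the ideal 100%
at extreme corners of the default ranges; interior vectors are uniformly
index 2.

## Model selection

Candidates are compared by the Gaussian-error criterion
$AIC = n_{obs}\ln(RSS_{unnorm}/n_{obs}) + 2k$ per ABM vector (the
small-sample correction is available but off by default), with relative
log-likelihoods $(AIC_{alt} - AIC_{ref})/2$ and per-point winners (ties to
the fewer-parameter model). The documented selection heuristic filters
candidates to those whose parameters are index-2 at 80% or more of ABM
vectors and takes the best AIC win fraction among them; if the filter
empties it falls back to the win fraction alone, with a warning, because a
flexible but sloppy surrogate (the von Bertalanffy failure mode) transfers
its parameter uncertainty into nonsensical sensitivity estimates.

## Hypersurfaces and the transfer estimator

Unbounded or out-of-range confidence bounds are clipped to the relevant
range (flagged, since clipping widens the sampled box to the full biological
range on the unidentified side). The clipped lower and upper bounds of each
surrogate parameter are interpolated over ABM parameter space: multilinearly
when the sampled vectors form a full rectangular grid (the default design),
otherwise by an inverse-distance-weighted interpolant (power 4, exact at
nodes, continuous, positive weights — so shrinking every sampled interval
shrinks every queried box). No extrapolation: queries outside the sampled
domain are errors. Integer ABM parameters are interpolated on the real line.

`surrogate_metric()` turns a field into a metric function: at $p_{ABM}$ it
draws `n_mc` uniform samples from the queried box (seeded deterministically
from the base seed and the point's printed coordinates, so repeated
evaluation is stable within a design), solves the surrogate, applies the
metric to the total-count trajectory and averages. The standard error of
this box mean scales as $1/\sqrt{n_{mc}}$; the default `n_mc = 100` keeps it
well below the between-parameter differences screened for.

## GSA engines

*Morris/MOAT.* Standard trajectories on an even-level grid
($\Delta = p/(2(p-1))$, default $p = 4$, $r = 30$), every parameter
perturbed exactly once per trajectory in random order with random sign.
Elementary effects are computed in normalized units, so $\mu^*$ is the
metric change over a full parameter range; $\mu$, $\mu^*$, $\sigma$ are
reported. For additive metrics the effects are exact and degenerate
($\sigma = 0$), which the suite asserts to machine precision.

*eFAST.* Each parameter in turn is driven at
$\omega_{max} = \lfloor (N_s - 1)/(2M)\rfloor$ (all $M$ harmonics below the
Nyquist limit of the $N_s$-point curve; 8 for the default $N_s = 65$,
$M = 4$) while complementary parameters cycle through the low frequencies
$1..\max(1, \lfloor\omega_{max}/(2M)\rfloor)$, with random phases per
resampling ($N_r = 4$) and the arcsine-of-sine sawtooth transform onto the
unit cell. $S_i$ sums spectral power at the drive frequency and its
harmonics; $S_{Ti}$ is one minus the low-frequency complement share
($k \le \omega_{max}/2$). Spectra are pooled over resamplings before the
ratios are formed, which suppresses the upward bias a fluctuating per-curve
variance denominator induces when several complementary parameters share a
frequency. Two estimator floors remain inherent at these design sizes: a
null parameter shows $S_i \approx 0.02$ (even harmonics of complementary
parameters collide with multiples of $\omega_{max}$), and main effects carry
a few points of phase-to-phase variability. No dummy parameter is used.

## Numerical choices and degenerate inputs

* SD floor as above; zero-SD points therefore never divide by zero.
* `rss = 0` maps to $AIC = -\infty$ with a warning.
* Zero-variance eFAST outputs yield zero indices with a warning.
* Profile grid points whose re-optimization fails are flagged and linearly
  interpolated over; a profile with more than 20% failures is invalid.
* Crossed interpolated bounds (possible only through floating-point
  degeneracy; linear interpolation preserves ordering) are swapped with a
  warning at query time.
* All randomness flows from explicit integer seeds; replicate $i$ of an
  ensemble uses `base_seed + i - 1`, and per-point seeds inside metric
  closures are derived from the printed coordinates, keeping every derived
  seed below $2^{31}$.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run entirely on one CPU at desk
scale: identifiability is mapped on the 128 corners of the 7-parameter box
plus 20 Latin-hypercube interior vectors with 6-replicate ensembles;
the end-to-end Morris comparison builds the field from those corners and
repeats direct (r = 10 trajectories, 5 replicates per point) versus
surrogate-transfer screening for ten seeds; the profile-coverage experiment
uses 1000 linear-Gaussian replications; growth-law recovery uses 50 seeded
mock ensembles. These sizes were chosen as the smallest at which the
qualitative conclusions are stable.

## Known limitations

* The ABM update rules are a plausible reconstruction, not a replica of any
  published lattice model; absolute sensitivity values depend on them.
* Under the default ranges a slow-cycling culture (rates near 0.5/day)
  cannot approach its capacity within 3 days from any admissible seeding
  density, so the final-count metric retains genuine sensitivity to the
  transition rates in that sub-saturated region; capacity-dominated
  behaviour concentrates where rates are fast.
* The identifiability index depends on the relevant-range convention;
  clipped boxes inflate the transfer estimator's spread at poorly
  identified vectors.
* eFAST at $N_s = 65$ has the estimator floors noted above; they shrink
  with $N_s$ and $N_r$, not with model quality.
* The hyperrectangle ignores correlations between surrogate parameters
  (it is an axis-aligned box by construction); strongly correlated
  surrogate posteriors are over-covered.
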