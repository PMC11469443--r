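---
title: "Smoothed stochastic simulation of gene expression: models, gradients and design"
author: "diffGillespie"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothed stochastic simulation of gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diffGillespie)
```

## The problem

Stochastic gene expression is naturally modelled as a continuous-time Markov
jump process: a reaction network with state vector $x$ (molecule counts and
promoter-state indicators), stoichiometric matrix $S$, and propensities
$r_i(x)$. The Gillespie direct method samples it exactly — draw a waiting
time $\tau = -\ln(u)/R$ from the pooled rate $R = \sum_i r_i$, pick the
reaction $i'$ as the smallest index whose cumulative propensity fraction
exceeds a second uniform draw $u'$, and apply the stoichiometry row — but
both the index choice and the state update are step functions of the kinetic
parameters $\theta$, so nothing downstream of a simulation can be
differentiated. This package implements a smoothed variant in which

$$ i' = 1 + \sum_{i=1}^{N-1} \sigma\!\left(\frac{u' - q_i}{a}\right),
\qquad q_i = \frac{1}{R}\sum_{j \le i} r_j, $$

with $\sigma$ the logistic function, and the one-hot update is replaced by
Gaussian weights $w_i = \exp(-(i'-i)^2/b)$ on every stoichiometry row. For
fixed noise draws the whole trajectory is then a smooth function of
$\theta$, which enables gradient-based parameter estimation and circuit
design; the exact simulator ships alongside and is the ground truth for
every accuracy claim.

A note on the selection: the smoothed index uses **cumulative** propensity
fractions. The bare single-reaction fractions do not reduce to the direct
method in the sharp limit; the cumulative form does, and that limit
equivalence is tested.

## Hyperparameters and their defaults

* `1/a = 200` (sigmoid steepness of the selection) and `1/b = 20` (Gaussian
  width of the update), the package defaults, are the conventional operating
  point: sharp enough that the long-horizon mRNA distribution of the
  two-state benchmark differs from the exact one by a
  divergence-to-entropy ratio of only about 0.003, wide enough that
  gradients remain finite. `sweepSmoothing()` reproduces the sweep that
  motivates this choice.
* `rateFloor = 1e-10` is added to $R$ inside divisions; a raw total rate
  below it marks the state absorbing and the state is held to the horizon.
* `maxSteps = 1e6` caps events per trajectory; overruns are flagged on the
  batch and warn when they affect more than 1% of trajectories.

## Numerical choices that required decisions

**Two-sided indicator clamp.** Real-valued updates can undershoot zero, so
species are clamped with a smooth softplus (sharpness $10^3$). Promoter
indicator species additionally get an upper clamp at one: near cumulative
ties (a zero-propensity reaction sandwiched between live ones) the soft
index transits through the dead reaction and deposits weight on it, and
with only a lower clamp this manufactures indicator mass without bound (we
observed the free-promoter indicator growing past 1.7 within ten time
units, and mRNA diverging tenfold). A single promoter copy's state
occupancies are bounded in $[0,1]$ by construction, so the two-sided clamp
restores the physics while keeping gradients alive.

**Three horizon statistics.** The raw *final* state includes the update of
the step that crosses the horizon, which overstates counts by a fraction of
one event — consistent with the systematic moment overestimation this class
of smoothed simulators is known for. The *snapshot* state (the state whose
dwell interval covers $T$, exactly how the exact simulator defines its
state at $T$) is the unbiased statistics surface and the default for all
moments. The *readout* state linearly interpolates the snapshot toward the
post-crossing state in time; unlike the other two it is a continuous
function of $\theta$ even where a trajectory's step count changes, so it is
the surface on which finite-difference gradient checks are meaningful.

**Loss moments are straight-through.** Distribution metrics round the
real-valued abundances to integer bins. The fitting losses do the same for
their *values* (mean and standard deviation of the rounded snapshot), while
*gradients* flow through the smooth unrounded surrogate. Without rounding,
partial-weight selection events near boundary zones smear low-copy counts
inward and leave fitted moments one to two standard errors away from their
targets; with it the recovered moments are statistically indistinguishable
from the exact targets.

## Gradients: what is exact, what explodes, and what we ship

The pathwise (common-random-numbers) derivative propagated through every
smooth operation is implemented exactly in compiled code as forward-mode
sensitivities, and `gradientMode = "full"` exposes it. On short chains it
agrees with central finite differences to $10^{-6}$; that agreement is part
of the test suite.

Over long horizons at the default smoothing the *map itself* is chaotic:
the selection kernel $\sigma'(\cdot)/a$ has spikes of height $1/(4a) = 50$,
and whenever a trajectory's accumulated state sensitivity passes through
one, it is amplified. Measured on the two-state benchmark over a horizon of
10, per-trajectory sensitivities grow by $e^{18}$ and the ensemble mean
gradient is dominated by a handful of astronomically large trajectories.
This is a property of the method at these hyperparameters, not of any
implementation — and no finite difference step sits inside the linear
regime of those tail trajectories, so ensemble-level agreement between the
exact pathwise gradient and finite differences is unobtainable there.

The production estimator used by the fitting losses therefore truncates the
chain in *time*: sensitivities accumulate only over a trailing window (2
time units by default, `gradWindow`), with an elasticity guard
(`jacobianClip`) bounding $|\partial x_s/\partial \log\theta_p|$ by ten
times the species magnitude. The truncation rescales each
parameter-statistic sensitivity by a positive factor; since the
moment-matching losses settle where the residual-weighted gradient
vanishes, and the statistic-by-parameter Jacobian is square and
nonsingular for the fits we run, the optimizer's fixed point — residuals
equal to zero — is unchanged. What the truncation costs is the descent
*path*, not the destination.

## Fitting protocol

The single-condition loss is the squared moment gap
$L(\theta) = (\langle\hat m\rangle - \langle m\rangle)^2 +
(\hat\sigma_m - \sigma_m)^2$; the multi-condition variant shares the
transcription and degradation rates across a repressor titration with one
binding rate per condition and $\sigma$-targets $\sqrt{f_i\langle
m\rangle_i}$. Time is measured in units of the repressor unbinding rate
(`koffR = 1`).

* Simulation horizon 10 with 2000 trajectories per evaluation, the
  conventional fitting setting. Because 10 can be shorter than the mRNA
  relaxation time $1/\gamma$, each batch is warm-started at the measured
  stationary law: promoter indicators at their stationary fractions
  (real-valued states make this possible) and mRNA dispersed over
  stratified gamma quantiles matched to the target mean and standard
  deviation. The warm start is data-derived and parameter-independent, so
  it contributes no gradient terms.
* ADAM in log-parameter space (positivity for free), learning rate 0.15
  decaying linearly to a tenth, 300–500 iterations, fresh noise seed per
  iteration with matched noise inside each evaluation. The returned
  estimate is the tail-averaged iterate (geometric mean over the last ~40%
  of the run), which sits closer to the optimum than the best single
  iterate under per-iteration noise. The degenerate three-parameter fit
  multi-starts over a few degradation-rate initializations and keeps the
  restart with the best refreshed-seed loss.
* Confidence intervals follow the conventional printed curvature recipe
  exactly: $\delta\theta_i = (\partial^2 L/\partial\theta_i^2)^{-1}$
  estimated from $\pm5\%$ matched-seed perturbations, interval
  $[\hat\theta_i - \delta\theta_i,\ \hat\theta_i + 1.96\,\delta\theta_i]$.
  Note the asymmetry and the fact that $\delta$ is a bare inverse curvature
  (not its square root), so its units are not those of $\theta$; a
  dimensionally standard half-width $1.96\sqrt{2/\mathrm{curvature}}$ is
  reported alongside, and coverage claims should be based on the latter.

## Synthetic benchmark data

`generateSynthetic()` defines the study conditions for every recovery
claim: `konR`, `r`, `gamma` drawn uniformly in $[0.1, 10]$ with
`koffR = 1` (20 sets by convention), and per-set targets computed by
**exact** Gillespie ensembles of 2000 trajectories, never by the smoothed
simulator. The exact horizon scales as $\max(20, 20/\gamma)$ so every set
is fully relaxed. The generator emulates population-snapshot moment data of
the kind single-molecule FISH produces; it does not emulate measurement
noise, cell-to-cell parameter heterogeneity, partial-labeling artifacts or
extrinsic noise, so passing recovery tests demonstrate correctness of the
inference machinery on an idealized data-generating process, not robustness
to real experimental nuisance structure.

## The four-state design problem

The nonequilibrium promoter has four states (OFF/ON chromatin state crossed
with activator bound/unbound), concentration-dependent binding
($[c]\,k_b$, modified by $\eta_{ba}$ in ON), unbinding ($k_u$, modified by
$\eta_{ua}$), and switching ($k_a, k_i$, modified by $\eta_{ab},
\eta_{ib}$ when bound). Mean production is read off the ON occupancies,
$\langle\bar r\rangle = r(\pi_2 + \pi_3)$; mRNA is never simulated in the
design pipeline. The thermodynamic budget is the drive
$\Delta\mu = \ln(\eta_{ab}\eta_{ua}/\eta_{ib}\eta_{ba})$, the cycle flux
$J = \pi_0 k_b [c] - \pi_1 k_u$, and the dissipated power $\Phi = J\Delta\mu$
(reported at the response midpoint concentration).

Design fits the seven free parameters (log space, ADAM) to a target
dose-response on ten log-spaced concentrations in $[10^{-2}, 10^2]$, with
$k_b = 0.02$ and $r$ fixed. Two engines drive the loss: the default
`"exact"` engine evaluates occupancies by the $4\times4$ null-space solve
with analytic gradients (cheap and noise-free; the reported curves always
come from it), and the `"dga"` engine uses 600 smoothed simulations per
concentration with pathwise occupancy gradients — the two agree to a
gradient cosine above 0.99 in the tests.

Because the response constrains only rate ratios, the design optimum is a
degenerate manifold; a small $\Delta\mu^2$ penalty (weight $3\times10^{-4}$)
selects its least-dissipative point. That tie-break is what makes the
thermodynamic comparison meaningful: the shipped `"shallow"` reference
target (logistic in $\log_{10}[c]$, slope 2.3 per decade — effective Hill
coefficient about one) is then realized essentially at equilibrium
($\Phi \approx 10^{-7}$), while the `"sharp"` target (slope 3.5, effective
Hill about 1.5) exceeds the single-site equilibrium bound and forces a
driven cycle with orders of magnitude more dissipation. A first version of
the shallow target (slope 1 per decade) taught us the converse lesson:
responses *wider* than Hill-1 also demand a driven cycle, with negative
drive, and dissipated more than the sharp target — sub-Hill flatness is as
nonequilibrium as super-Hill sharpness.

## Known limitations

* Tails: the smoothed simulator underweights rare large excursions; no
  tail correction is attempted, and distribution claims are about bulk
  statistics.
* Occupancy leak: soft selection leaves an absolute bias of up to a few
  percent in rarely-visited promoter states, independent of simulation
  length, so occupancy comparisons against the exact steady state are
  bias-limited, not noise-limited.
* Exact ensemble-level agreement between pathwise gradients and finite
  differences is limited to short chains or tame smoothing; see the
  gradients section.
* Problem sizes used throughout the documentation and tests — 2000
  trajectories, horizons of 10 (fitting) and $10^4$ (distribution
  benchmarks), 600 design simulations per concentration, 10-20 synthetic
  sets — are the package's standard operating points and match the
  conventions of the underlying benchmark.
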