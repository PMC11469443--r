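# diffGillespie

Differentiable Gillespie simulation of stochastic gene expression in R.

Chemical reaction networks — here, gene promoters switching between
transcriptional states while mRNA is produced and degraded — are exactly
simulated by the Gillespie direct method, but the method's discrete choices
(which reaction fires, how the state jumps) make every simulated statistic
a non-differentiable function of the kinetic parameters. This package
implements a smoothed variant of the algorithm in which the reaction index
is selected through sigmoids over cumulative propensity fractions,

&nbsp;&nbsp;&nbsp;&nbsp;*i′ = 1 + Σᵢ σ((u′ − qᵢ)/a)*,&nbsp;&nbsp;
*qᵢ = Σ_{j≤i} r_j / R*,

and the state update blends stoichiometry rows with Gaussian weights
*wᵢ = exp(−(i′−i)²/b)*. For fixed noise draws the whole trajectory is then
smooth in the parameters, and the package propagates exact forward-mode
pathwise sensitivities alongside every batch of trajectories. On top of
this core it provides:

* the exact direct-method simulator as ground truth, with distribution
  metrics (entropy, Kullback–Leibler and Jensen–Shannon divergences, the
  divergence-to-entropy accuracy ratio) to quantify the smoothing error;
* built-in two-state (telegraph) and four-state nonequilibrium promoter
  models with analytic and master-equation oracles;
* gradient-based parameter estimation with ADAM in log space: single- and
  multi-condition moment-matching losses, curvature confidence intervals,
  loss landscapes, a synthetic-data benchmark generator;
* gradient-based design of four-state promoter dose-response curves, with
  the thermodynamic budget (drive Δμ, cycle flux J, dissipated power
  Φ = JΔμ) of each designed circuit.

## Worked example

Simulate the classic repressed two-state promoter (`konR = 0.5`,
`koffR = 1`, `r = 10`, `gamma = 1`) with both simulators and compare:

```r
library(diffGillespie)

net    <- twoStatePromoter(konR = 0.5, koffR = 1, r = 10, gamma = 1)
params <- c(konR = 0.5, koffR = 1, r = 10, gamma = 1)

twoStateMeanFano(0.5, 1, 10, 1)
#>     mean     fano       sd
#> 6.666667 2.333333 3.944053

exact <- ensembleFinalStates(net, params, T = 1000, nTraj = 2000, seed = 1)
mean(exact[, "m"])                      # exact stationary mean, MC estimate
#> [1] 6.7145

dga <- simulateDGA(net, params, T = 1000, nTraj = 2000, seed = 2)
mean(snapshotStates(dga)[, "m"])        # smoothed simulator, state at T
#> [1] 7.138744

jsdOverEntropy(empiricalPDF(snapshotStates(dga)[, "m"]),
               empiricalPDF(exact[, "m"]))
#> [1] 0.001706083
```

The smoothed distribution sits within a divergence-to-entropy ratio of a
few thousandths of the exact one — the headline accuracy of the method — while
being differentiable: requesting `gradients = TRUE` attaches the Jacobian
of every final state and occupancy with respect to the kinetic parameters,
which is what the fitting and design routines consume.

Fitting parameters to measured moments:

```r
targets <- c(mean = 6.667, sd = 3.944)            # e.g. from FISH data
fit <- fitTwoState(targets, gamma = 1, seed = 1)  # estimates konR and r
fit@thetaHat
#>      konR          r      gamma
#> 0.7341047 10.8282734  1.0000000
```

The recovered parameters reproduce the target moments to within
Monte-Carlo error (see the confidence intervals in `fit@ci`). Designing a
sharp dose-response with the four-state promoter:

```r
design <- designFit(referenceTarget("sharp"), seed = 1)
design@sharpness; design@drive; design@powerMid
#> [1] 0.2944
#> [1] 1.732
#> [1] 0.00696
```

A command-line entry point over the same functionality ships in
`inst/cli/dga-cli.R` with YAML configurations (examples in
`inst/extdata/`).

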