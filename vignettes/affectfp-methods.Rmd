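---
title: "Bounded gradient-drift diffusion models of affect: methods and design"
author: "affectfp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded gradient-drift diffusion models of affect: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectfp)
```

## The model

`affectfp` fits continuous-time stochastic models of bivariate affect
dynamics to experience-sampling (ESM) time series. The state
$\mathbf{y}(t) = (y_1, y_2)$ holds the momentary positive- and
negative-affect levels, each scaled to $[0, 1]$. Its evolution is a
gradient diffusion on a free-energy surface $F(\mathbf{y})$:

$$\mathrm{d}y_i = -D\,\partial_i F(\mathbf{y})\,\mathrm{d}t
  + \sqrt{2D}\,\mathrm{d}W_i, \qquad i = 1, 2,$$

with uncorrelated Wiener processes $W_i$ and a diffusion constant $D$
(units 1/hour) that scales drift and noise together — it is a pure
time-scaling parameter.

Two surfaces are implemented:

* **Affective Ising Model (AIM).**
  $$F(\mathbf{y}) = \sum_{i=1}^{2}\Big[-\Lambda_i y_i^2 + \Theta_i y_i
    + N_i\big(y_i\ln y_i + (1-y_i)\ln(1-y_i)\big)\Big]
    + \Lambda_{12}\, y_1 y_2.$$
  $\Lambda_i \ge 0$ are self-excitation weights, $\Theta_i \ge 0$
  thresholds, $N_i \ge 0$ entropy weights whose logarithmic terms
  diverge at the boundary and keep the state inside the unit square, and
  $\Lambda_{12}$ couples the two dimensions (positive values: mutual
  inhibition). The interaction is implemented as the product
  $\Lambda_{12} y_1 y_2$, the form consistent with the mutual-inhibition
  reading (large $y_2$ raises the energy cost of large $y_1$ when
  $\Lambda_{12} > 0$).
* **Bounded Ornstein–Uhlenbeck.**
  $F(\mathbf{y}) = \tfrac12 (\mathbf{y}-\mu)^\top A (\mathbf{y}-\mu)$
  with $\mu$ in the open unit square and $A$ positive definite. This
  parameterisation was chosen deliberately: the interior dynamics are
  exactly OU with drift $-DA(\mathbf{y}-\mu)$, so the Gaussian
  transition moments are known in closed form and serve as an oracle for
  the numerical solver. For the isotropic case $A = a I$ the conditional
  mean reverts at rate $Da$ and the per-dimension transition variance is
  $(1 - e^{-2DaT})/a$ (stationary variance $1/a$, the Boltzmann variance
  of $e^{-F}$).

The conditional density $p(t, \mathbf{y})$ of the state given an earlier
observation obeys the Fokker–Planck equation with a delta initial
condition and no-flux boundary conditions on the unit square; its
long-time limit is the Boltzmann distribution $e^{-F}/Z$.

## The lattice propagator

There is no closed form for the AIM's transition densities, so the
likelihood is built from a numerical solver. The affect space is divided
into $n \times n$ cells of width $\delta = 1/n$ whose centers sit at
$\big(\tfrac{2m+1}{2}\delta, \tfrac{2k+1}{2}\delta\big)$ — pushed half a
cell off the boundary, where the free-energy gradient is singular. Each
update redistributes cell masses by a Metropolis–Hastings random-walk
rule: a state in a cell proposes to stay or to move to one of its four
neighbors with probability $1/5$ each, and an uphill move to a neighbor
is accepted with probability $\min\{1, e^{F_{\text{cell}} -
F_{\text{neighbor}}}\}$. Summing acceptance-weighted in- and out-fluxes
gives a deterministic linear update of the mass field that conserves
total mass exactly, keeps at least $1/5$ of every cell's mass in place,
and has the discrete Boltzmann field as its detailed-balance invariant.

Boundaries are handled by a ghost layer: one extra cell on every side
with infinite free energy, so the acceptance of any move into it is
exactly zero (computed as $e^{-\max(0, \Delta F)}$, which avoids
arithmetic on infinities) — the discrete no-flux condition.

Matching the update's displacement variance ($2\delta^2/5$ per dimension
per step on a locally flat surface) with the diffusion law
$\langle \Delta y^2 \rangle = 2D\,\Delta t$ fixes the time step:

$$\Delta t = \frac{\delta^2}{5D}.$$

Space and time resolution are therefore entwined; a finer grid buys
accuracy at quadratically more updates per unit time. Propagation over an
interval $\tau$ applies $k = \max(1, \operatorname{round}(\tau/\Delta
t))$ updates. Rounding to the nearest integer keeps the effective
elapsed time closest to the requested one; the one-step floor prevents
distinct observations from being treated as simultaneous. The default
grid is $30 \times 30$ ($\delta \approx 0.033$), enough resolution for
slider self-reports; `grid_n` is exposed for users who need more.

## The likelihood

Ratings are affinely rescaled from the instrument range (e.g. 0–100
sliders) to $[0,1]$, averaging multiple positive/negative items first
when present. The likelihood of a parameter set given a series is the
product of conditional transition densities between consecutive valid
observations; the package minimises its negative logarithm. Each pair
contributes $-\ln p(\mathbf{x}_{j+1} \mid \mathbf{x}_j, \tau_j)$, read
off the propagated field as cell mass divided by $\delta^2$ at the cell
containing $\mathbf{x}_{j+1}$ (no interpolation — the same resolution
convention as the delta initial condition). Design choices:

* **Missed beeps** are skipped and the gap bridged from the previous to
  the next valid observation.
* **Nights**: by default (`night_mode = "skip_pairs"`, used for all fits
  in this package's studies) the overnight transition is not
  evaluated; the first observation of a day, and of the whole series,
  only conditions. Alternatively `"stationary_restart"` evaluates
  first-of-day points under the Boltzmann density, as does
  `initial_mode = "stationary"` for the first point of the series.
* **density_floor** ($10^{-300}$): zero-mass target cells would give an
  infinite objective; flooring keeps it finite so the global optimizer
  can rank rather than reject such members.
* **step_budget**: one evaluation's total number of lattice updates is
  capped (configurable; fits here use a few times $10^5$). Members whose
  small $\Delta t$ would demand enormous numbers of updates score
  `Inf`. This guards runtime against near-stationary candidates and
  never binds at the optimum in the studies below.
* Per parameter set, the tabulated surface, the kernel and (when
  needed) the stationary field are built once and shared across all
  pairs.

Time is measured in hours throughout; $D$ is per hour. Unit conversions
happen only at I/O boundaries.

## The trajectory oracle

An independent Euler–Maruyama simulator provides Monte-Carlo reference
densities: trajectories follow
$\mathbf{y} \leftarrow \mathbf{y} - D \nabla F\,\mathrm{d}t +
\sqrt{2D\,\mathrm{d}t}\,\xi$ and endpoint histograms (no kernel
smoothing) approximate the conditional density. Near the boundary the
diverging gradient can overshoot; the simulator clamps each coordinate
into $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ after
every step. Clamping was preferred over reflection because under a
diverging *inward* drift a reflected step distorts the process near the
wall more than a clamp, and the reference step size is small anyway: the
oracle's $\mathrm{d}t$ is tied to the lattice step of the finest grid it
is compared against (grid 240 by convention, grid 120 in the scaled
cross-validation study). The oracle uses its own xoshiro256++ generator
seeded explicitly, since it consumes billions of Gaussian draws.

## Global optimization

The negative log-likelihood can be multimodal, so it is minimised by
differential evolution (rand/1/bin): donor $= a + w\,(b - c)$ from three
distinct other agents, binomial crossover at rate CR with one guaranteed
mutant coordinate, and greedy parent–child selection. Defaults follow
common practice for this estimator: NP = 50, CR = 0.6, 1000 generations;
the differential weight $w$ is not dictated by that practice and
defaults to 0.7. Infeasible child coordinates are clipped to the
feasible region ($D$ floored at $10^{-8}$ to keep $\Delta t$ finite).

Initial populations are drawn from configurable priors: exponentials for
the nonnegative parameters (default means 10 for $\Lambda$ and
$\Theta$, 5 for $N$), a symmetric two-sided exponential for
$\Lambda_{12}$ (scale 10) — nonnegative support matching the
constraints, with tails heavy enough for a global search. The initial
$D$ is exponential with mean $25\,\delta^2 / (5\bar\tau)$, where
$\bar\tau$ is the mean evaluated inter-observation interval, so the
expected number of lattice updates per pair in the first generation is
25. This calibration deliberately favours dynamical over near-stationary
solutions early on, because stationary solutions are strong local
attractors; if the data prefer them, $D$ drifts there later at a higher
step cost.

## The synthetic ESM generator

The generator emulates a standard smartphone ESM protocol: ten beeps per
day placed by stratified random sampling in a 10:00–22:00 window (the
720-minute window is split into ten equal strata and one time drawn
uniformly in each, giving a mean within-day gap of 72 minutes), each
beep answered with probability 0.87. Series are simulated at lattice
resolution: the first answered beep of a day is drawn from the Boltzmann
field, each later one from the propagated conditional field given the
previous observation and the true interval, with uniform jitter inside
the sampled cell (the lattice does not resolve sub-cell placement).
Nights carry no simulated dynamics — each day restarts from
stationarity, consistent with the `skip_pairs` likelihood used to fit
such data.

What this emulates — and what it does not: the generator produces data
whose statistical structure is exactly the one the estimator assumes
(same lattice, same conditional densities). Passing recovery tests
therefore demonstrates the correctness of the estimation machinery, not
that real affect dynamics follow the AIM; real series add measurement
noise, Likert discretisation, overnight dynamics and day-level
nonstationarity that are out of scope here.

Recovery experiments follow the two-condition design: a base-size series
(default seven days, about 61 answered beeps — the scale of a typical
one-week ESM study) and an enlarged data set drawing `multiplier` points
from every conditional density along the same chain (100 reproduces the
full-scale design; scaled runs here use 5). Fitting the enlarged set
evaluates all draws against the same propagated conditional per slot, so
its cost stays close to the base fit.

## Solver cross-validation

`convergenceStudy()` reproduces the structure of the accuracy analysis:
for random fitted-like AIM parameter sets and a random initial condition,
the lattice conditional fields at several grid sizes are compared with
the trajectory oracle's histograms after horizons $t\,(1/30)^2/(5D)$ with
$t \in \{5, 50, 100, 500\}$ (exactly $t$ updates on the default grid).
All fields are rebinned to a common $30\times30$ grid — coarse-to-fine
splits mass equally, fine-to-coarse sums blocks, both mass-preserving —
and differences are taken in $L^2$ and $L^\infty$ on cell masses
(masses, not densities, so the comparison is resolution-independent
after rebinning). Initial conditions are drawn uniformly over the unit
square rather than on any lattice's cell centers: a grid-aligned start
would sit exactly on one resolution's cell while landing half a cell off
on finer ones, biasing short-horizon comparisons toward the aligned
grid. Expected behaviour, asserted in the tests: the median
$L^2$ difference shrinks as the grid refines and is smaller at long
horizons, where the conditional approaches the stationary field.

## Study sizes and numerical tolerances

The test suite runs scaled versions of the full-scale designs, chosen
once as a balance of statistical resolution and desk-scale runtime:

* Cross-validation: 5 random parameter sets, grids $\{15, 30, 60,
  120\}$, $10^5$ trajectories (the full design uses $10^7$ and adds grid
  240; at $10^5$ the Monte-Carlo noise floor is estimated empirically
  with a second independent histogram instead).
* Recovery: one 600-observation dominance fit at NP = 20, 200
  generations; ten seeded 7-day recoveries at NP = 12, 60 generations,
  multiplier 5.
* Tolerances: lattice invariants are asserted near machine precision
  (mass conservation $10^{-12}$ over $10^4$ updates, Boltzmann
  invariance $10^{-14}$ per cell); Monte-Carlo comparisons use 3–5
  standard errors; the OU closed-form comparison allows 2%, which
  covers the $O(\delta)$ lattice discretisation bias at $n = 120$.

All computations are double precision. An optional renormalisation of
propagated fields was considered and rejected: conservation already
holds to $10^{-12}$ without it.

## A short example

```{r example, eval = FALSE}
truth <- aimParameters(lambda1 = 4, lambda2 = 3, lambda12 = 2,
                       theta1 = 2, theta2 = 3, n1 = 2, n2 = 2, D = 0.005)
set.seed(1)
sched <- esmSchedule(scheduleConfig(days = 7))
series <- simulateSeries(truth, sched, buildGrid(30))
negLogLikelihood(truth, series)
fit <- fitModel(series, "aim",
                deConfig(NP = 20, generations = 100, seed = 1),
                likelihoodOptions(step_budget = 2e5))
paramVector(fit@params)
```

## Known limitations

* Likelihoods are evaluated at cell resolution; sub-cell structure in
  very low-variability series needs a finer grid (at quadratic step
  cost).
* Single-person fits only: no hierarchical pooling across participants,
  no measurement-error convolution, no state-space filtering.
* The optimizer reports a point estimate and its trace; no standard
  errors or confidence intervals.
* Overnight dynamics are neither simulated nor evaluated under the
  default protocol.
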