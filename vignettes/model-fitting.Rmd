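---
title: "Fitting delay-coupled phase-oscillator whole-brain models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting delay-coupled phase-oscillator whole-brain models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

kurafit simulates resting-state brain activity as a network of `N` Kuramoto
phase oscillators, one per brain region:

$$\dot\theta_i(t) = 2\pi f_i
  + \sum_{j=1}^{N} k_{ij}\,\sin\!\big(\theta_j(t-\tau_{ij}) - \theta_i(t)\big)
  + \sigma\,\eta_i(t), \qquad \eta_i \sim U[-1,1].$$

Pairwise couplings and delays come from the structural connectome: with
`SC` the streamline-count matrix and `PL` the mean streamline path lengths,

$$k_{ij} = \frac{\mathrm{SC}_{ij}}{\langle \mathrm{SC}\rangle}\frac{C}{N},
\qquad
\tau_{ij} = \frac{\mathrm{PL}_{ij}}{\langle \mathrm{PL}\rangle}\,\tau,$$

where $\langle\cdot\rangle$ averages all off-diagonal entries (zeros
included). The three free parameters are the global coupling $C$
(dimensionless), the global delay $\tau$ (seconds) and the noise intensity
$\sigma$ (dimensionless). Simulated BOLD is $\sin\theta_i(t)$ downsampled to
the repetition time, and simulated functional connectivity (simFC) is the
Pearson correlation matrix of those signals. The model fit of a parameter
point is the Pearson correlation between the strictly upper triangles of
simFC and the subject's empirical FC; the unit diagonal is excluded because
it carries no information and would inflate the correlation.

The assumptions are the usual ones for this model class: regional dynamics
reduce to a phase; amplitude effects and hemodynamics are ignored (no
Balloon–Windkessel convolution); structural streamline counts are
proportional to effective coupling and streamline lengths to conduction
delay; and the BOLD correlation structure is stationary over the simulated
window.

# Numerical scheme

The delay SDE is integrated with the stochastic Heun (predictor–corrector)
scheme at `dt = 0.06` s. Choices the equation itself does not pin down:

* **Noise discretization.** The increment is $\sigma\sqrt{dt}\,u$ with
  $u \sim U[-1,1]$, added once per step and identical in predictor and
  corrector (Euler–Maruyama-consistent; the variance of the phase grows as
  $\sigma^2 dt/3$ per step, the $1/3$ being the variance of $U[-1,1]$).
  This fixes the scale on which $\sigma$ is interpreted.
* **Delay discretization.** $d_{ij} = \mathrm{round}(\tau_{ij}/dt)$,
  nearest-integer, no interpolation; the discretization error is at most
  `dt/2` per pair.
* **Initial history.** The history for $t \le 0$ is frozen at the initial
  phases (uniform on $[0, 2\pi)$ from the seed, overridable). After the
  discarded transient this choice is immaterial for stationary FC.
* **Downsampling.** Samples sit at $t = m\,\mathrm{TR}$; the first retained
  sample is the smallest $m\,\mathrm{TR} \ge$ transient. At the full-scale
  settings (4000 s, 500 s transient, TR 0.72 s) this retains 4861 samples.
* **Phase storage.** Phases are kept unwrapped; all couplings enter through
  sines of differences, which are wrap-invariant.
* **Reproducibility.** The integrator carries its own splitmix64 stream
  seeded from the run seed, so trajectories are bitwise reproducible
  regardless of R's RNG state. Noise is drawn region-major within each
  step. The inner loop expands $\sin(\theta_j^{delayed}-\theta_i)$ via
  sin/cos ring buffers, so each step costs one sin/cos pair per region per
  stage plus multiply–adds per connection.

# The goal function and its randomness

`goal_function()` simulates FC at a parameter point and correlates it with
the empirical FC. Each evaluation draws a fresh noise seed from a
counter-based seed policy by default, making $F$ a stochastic objective, as
it is when fitting real data. A fixed-seed policy freezes the noise
realization, which makes $F$ deterministic and gives the exact closure used
in tests: a subject whose "empirical" FC was generated at $(C^*, \tau^*,
\sigma^*)$ with seed $s$ returns $F = 1$ exactly when re-evaluated there
with the same seed. In two-dimensional fits $\sigma$ is held at 0.3.

# Baseline grid and optimizers

The grid-search baseline uses 64 equidistant couplings on $[0, 0.945]$
crossed with 48 equidistant delays on $[0, 94]$ s (3072 nodes, $\sigma =
0.3$) in two dimensions, and $48 \times 22 \times 81 = 85536$ nodes on
$[0, 0.94] \times [0, 48] \times [0, 2]$ in three. The three-dimensional
delay axis should be denser at small delays, where the optima concentrate;
we use the quadratic rule $\tau_m = 48\,(m/21)^2$, which is strictly
increasing with nondecreasing gaps. The
five best nodes are retained as the reference points of the cost function.

All four optimizers maximize $F$ over the box $[0,1] \times [0,100]$
($\times\,[0,2]$ in 3Dim), working internally in normalized unit-box
coordinates (the coordinate system in which all solution distances are
measured) and stopping after at most 80 iterations:

* **Nelder–Mead** (`lambda = Dim + 1`): Lagarias coefficients (reflection
  1, expansion 2, contraction 0.5, shrink 0.5); initial simplex at a random
  interior point plus 0.05 axis steps; candidates projected onto the box;
  extra stop when the longest simplex edge drops below 0.01 (normalized).
* **Particle swarm** (`lambda = 60`): constriction-type update with
  inertia 0.7298 and cognitive/social weights 1.49618; clamped positions
  with the violating velocity component zeroed; stops early after 50
  consecutive iterations without strict improvement of the global best.
* **CMA-ES** (`lambda = 24`, 12 parents): log-rank recombination weights,
  cumulative step-size adaptation, rank-one plus rank-$\mu$ covariance
  update, initial step 0.3; out-of-box samples are projected and the
  projected points are used in the updates; same 50-iteration stall rule;
  covariance repaired by eigenvalue flooring if it degenerates.
* **Bayesian optimization** (initial Latin hypercube of 5 points in 2Dim,
  10 in 3Dim): Matérn-5/2 Gaussian process with an observation-noise term,
  hyperparameters refit each iteration by marginal-likelihood ascent
  (warm-started from the previous iteration, falling back to it on a
  degenerate fit), expected improvement maximized by multi-start L-BFGS-B
  over the box; the iteration cap is the only stopping rule, and the 80
  acquisition iterations exclude the initial design.

The velocity coefficients, simplex tolerance, initial CMA-ES step and GP
kernel are configuration with standard literature defaults, not quantities
fixed by the benchmark protocol; `optimizer_config()` exposes them all.
Stall detection uses strict improvement (no tolerance), the most literal
reading of "no improvement during 50 consecutive iterations". Maximization
is implemented by minimizing $-F$ where a scheme is natively a minimizer.

# Benchmarking machinery

`run_replicates()` executes a method `R_max` times from distinct child
seeds and records the fit vector, the optimal points (normalized), and the
per-run count of goal evaluations. That count is the default *time proxy*:
core-hours are irreproducible across machines, every goal evaluation costs
the same simulation, and the cost-function normalization cancels any common
scale, so evaluation counts order methods exactly as machine time would.

The *success probability* at $R$ runs is estimated per subject by drawing
$R$ of the available fits without replacement (500 resamples) and scoring a
success when the best draw reaches 95% of that subject's grid-search fit,
then averaging over subjects. Drawing without replacement matches the
finite set of distinct runs and admits the exact hypergeometric oracle
$1 - \binom{R_{max}-m}{R}/\binom{R_{max}}{R}$ against which the estimator
is tested. The smallest $R$ whose probability reaches a level (50%, 80%)
feeds the time component; a method that never reaches the level is charged
its full `R_max` runs and flagged.

The per-subject, per-method cost is the product of five components: one
minus the best fit; the population standard deviation (divisor $R_{max}$)
of the fits; the time for the runs-to-80%; the mean pairwise distance
between the solutions (divisor $\binom{R_{max}}{2}$, the 105 pairs of the
15-run protocol); and the mean distance of each solution to the nearest of
the five grid points. Each component is normalized by its maximum over all
subjects and methods before multiplying. The fifth term has two readings in
its source material (nearest grid point in the printed product, average
over grid points in the prose); the product form is the default and
`cost_components(dist_rule = "mean")` selects the prose variant. The method
with the smallest cost is recommended for the subject (ties broken by the
smaller time component, then lexicographically, logged), and the method
with most recommendations wins the cohort.

# The synthetic cohort

Real connectome-plus-fMRI cohorts cannot be redistributed, so the package
generates subjects with the statistical structure the pipeline assumes:

* **Path lengths** from uniformly random 3-D region coordinates, Euclidean
  distances rescaled affinely into `length_range` (default 20–160,
  streamline-length-like units): symmetric with triangle-like structure by
  construction.
* **Streamline counts**: log-normal pair magnitudes damped by
  $\exp(-\mathrm{PL}_{ij}/\lambda)$ with $\lambda$ half the length-range
  span, and the top `round(density * N(N-1)/2)` pairs kept. This
  reproduces heavy-tailed, distance-dependent weights; the default density
  0.35 is in the range of parcellated tractography SC matrices.
* **BOLD sessions**: unit sinusoids at region-specific natural frequencies
  with random phases plus (optionally FC-correlated) Gaussian noise, four
  sessions of 1200 volumes at TR 0.72 s, the multi-session resting-state
  structure the empirical-feature extractors expect.
* **Empirical features**: natural frequencies are the maximal raw
  periodogram peaks of the detrended, z-scored, session-concatenated
  signals restricted to 0.01–0.1 Hz (spectral resolution $1/(T\cdot
  \mathrm{TR})$; the periodogram is the simplest reproducible estimator,
  and whether to taper or average is an open choice we resolve by not
  doing either); empirical FC is the Pearson correlation of the
  per-session detrended, z-scored, then concatenated series.
* **Ground-truth subjects**: the simulator run at known $(C^*, \tau^*,
  \sigma^*)$ supplies the subject's "empirical" FC, giving
  parameter-recovery fixtures with a known optimum.

What the generator does *not* emulate: hemodynamic filtering and
measurement noise spectra of real BOLD, head-motion artifacts, the
log-normal-plus-topology structure of real tractography beyond distance
decay, and inter-subject correlations. Passing tests therefore demonstrate
that the machinery is correct and that planted parameters are recoverable
under the model's own assumptions — not that the model fits real brains.

# The desk-scale benchmark study

`run_benchmark_study()` runs the full pipeline at a size a single CPU
handles: 8 subjects with `N = 20` regions, a 16 x 12 two-dimensional grid
over the default ranges, and 5 replicates of each optimizer, with 80 s of
simulated time per evaluation of which the first 22 s are discarded (81
retained TR samples). The goal runs in
fixed-seed mode so that each subject's surface is deterministic and equals
1 at the planted truth; truths are drawn from $C^* \in [0.3, 0.7]$,
$\tau^* \in [5, 40]$ s, $\sigma^* = 0.3$. These sizes are the package's
choice of a representative desk-scale configuration; all of them are
arguments.

# Known limitations

* The fit surface of this model is nearly degenerate along ridges in $C$
  (and, at weak coupling, in $\tau$): parameter points one or two coarse
  grid cells apart can differ in fit by less than the FC sampling error of
  a short series. Recovering an *off-grid* truth to within one cell of a
  16 x 12 grid is therefore not guaranteed even noise-free; planted
  on-grid truths are recovered exactly in fixed-seed mode, which is what
  the recovery tests assert. Continuous optimizers are not limited by grid
  granularity, which is visible in the benchmark study where they reach
  the exact truth while the grid reports the best node only.
* Success-probability estimates with 500 resamples carry Monte-Carlo error
  of a few percent; the hypergeometric closed form is exact and preferred
  for analysis.
* The GP surrogate refits hyperparameters by a few warm-started ascent
  steps per iteration rather than to convergence; on smooth objectives the
  effect is negligible, but pathological objectives may need
  `optimizer_config()` adjustments.
* Delays longer than the simulated window are well-defined (the delayed
  input stays at the constant pre-history) but dynamically degenerate;
  desk-scale fits over the full delay box inherit this.
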