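---
title: "Inferring phage-bacteria infection networks from community time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring phage-bacteria infection networks from community time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phagenet` estimates who infects whom — and how efficiently — in a
virus–bacteria community, from nothing but time series of type-resolved
densities. This vignette is the package's account of the science: the model
and its assumptions, the estimator, the conventions and defaults, and what
the in silico evaluation does and does not demonstrate.

## The community model

The dynamics of `N_h` host types and `N_v` virus types follow a generalized
Lotka–Volterra system,

$$\dot h_i = r_i h_i\Big(1 - \sum_{i'} a_{ii'} h_{i'}/K\Big)
            - h_i \sum_j M_{ij}\,\varphi_{ij} v_j, \qquad
  \dot v_j = v_j \sum_i \beta_{ij}\varphi_{ij} M_{ij} h_i - m_j v_j,$$

with logistic host growth against a shared carrying capacity, mass-action
infection, instantaneous lysis (no latent period, no lysogeny), and
first-order viral decay. The binary matrix $M$ switches interactions on and
off; $\varphi_{ij}$ (adsorption rate) and $\beta_{ij}$ (burst size) set their
strength. Every term carries the focal density as a factor, so zero densities
are never driven negative and the extinct state is a fixed point.

**Units.** All rates are per *hour* and densities per ml. The default
sampling ranges — adsorption $10^{-8}$–$10^{-7}$ ml/(virus·h), burst sizes
10–50, host equilibria $10^3$–$10^4$ cells/ml, virus equilibria
$10^6$–$10^7$ virions/ml, $K = 100 \times \max_i H^*_i$ — then imply host
growth rates of order 0.01–1 h⁻¹ (bacterial doubling on hour timescales) and
adsorption constants in the experimentally measured range. We note these
identical numerical ranges are sometimes quoted with per-day units; under a
per-day reading a 96-hour experiment covers only a few percent of the
system's natural oscillation period, the host trajectories are numerically
polynomial of degree ~5, and the regression below is rank-deficient at
machine precision — no network can then be recovered at any solver
tolerance. The per-hour reading is both the biologically standard one and
the one under which the method's documented performance is achievable.

**Competition matrix.** The model never pins down $a_{ii'}$; the package
default is $a_{ii'} = 1$ for all pairs (a single shared carrying capacity).
With the default ranges this keeps the feasibility denominator
$1 - \sum_{i'} a_{ii'}H^*_{i'}/K \ge 0.9$, so the logistic term is a mild
correction and host dynamics are dominated by viral predation. Arbitrary
non-negative matrices are accepted.

## Feasible parameter sets

Rather than screening random parameters for coexistence, the generator
*constructs* it: draw $\varphi$, $\beta$, $H^*$, $V^*$ from their ranges,
then solve the steady-state equations for the remaining rates,

$$m_j = \sum_i M_{ij}\beta_{ij}\varphi_{ij}H^*_i, \qquad
  r_i = \frac{\sum_j M_{ij}\varphi_{ij}V^*_j}{1-\sum_{i'}a_{ii'}H^*_{i'}/K},$$

so that $(H^*, V^*)$ is an exact coexistence equilibrium (`ode_rhs()` at the
equilibrium is numerically zero, relative to the natural rate scale, to
better than $10^{-10}$; the suite asserts $10^{-12}$ for the headline
configuration). No admissibility screening beyond positivity is applied —
local stability is neither required nor asserted, and the perturbed
trajectories are used as-is.

**Rate granularity.** $\varphi_{ij}$ and $\beta_{ij}$ are drawn
independently per host–virus pair by default (`granularity = "pair"`). This
is an identifiability requirement, not a taste: with per-virus rates
broadcast down the columns (`granularity = "virus"`, also available), any
two hosts sharing an infection-matrix row have *identical* per-capita loss
terms and — because the feasibility solve then assigns them identical growth
rates — exactly proportional trajectories for all time. The regression
design is then exactly singular, and matrices with duplicated rows (every
modular matrix with blocks of two or more hosts, for instance) are
unreconstructable in principle. Per-pair draws from the same ranges leave
the effective rates $\varphi\beta$ in the same window
($10^{-7}$–$5\times10^{-6}$) and restore identifiability.

## Infection-matrix ensembles and NODF

Culture-based surveys find infection networks ranging from modular to
nested; the evaluation therefore runs over ensembles spanning that spectrum.
Nestedness is measured by NODF normalized to $[0,1]$: over every unordered
pair of rows (and of columns), a pair with equal degrees contributes 0, and
an unequal pair contributes the fraction of the sparser line's interactions
overlapped by the denser line. The strict decreasing-fill rule has a
consequence worth stating: NODF $= 1$ requires strictly decreasing row *and*
column degrees, which in a $10\times10$ matrix needs at least
$10+9+\dots+1 = 55$ interactions. An ensemble that conserves the default
modular fill of 20 interactions therefore tops out at the NODF of
`max_nested_matrix(10, 10, 20)`, which is $17/45 \approx 0.378$ — the
spectrum is still traversed in full, just against its own ceiling.

The generator walks between the modular and maximally nested endpoints by
single-interaction moves that never decrease NODF, never empty a row or
column, and conserve fill, with random tie-breaking. Mechanically the
trajectory is built *downhill* — random donors from the nested endpoint,
each step taking the smallest available strict NODF decrease — and then
reversed, with the modular matrix prepended. The downhill construction is
used because a purely uphill chain provably strands: accept-if-non-decreasing
hill climbing from the modular start reaches a strict local maximum at NODF
$\approx 0.307$ (10×10, fill 20) from which no single non-decreasing move
escapes, even after tens of thousands of accepted plateau moves. The
reversed descent yields a fine, monotone, reproducible sequence ending
exactly at the ceiling.

## The estimator

Dividing the virus equations by $v_j$ linearizes them in the unknowns. With
densities sampled every $\Delta t$, the discrete log-derivative
$W_{jn} = (\ln v_j(t_{n+1})-\ln v_j(t_n))/\Delta t$ satisfies
$W \approx (\tilde M^\top\,|-m)\,(H;\mathbf 1)$, where
$\tilde M_{ij} = M_{ij}\varphi_{ij}\beta_{ij}$ is the quantitative network
and the ones row carries the decay rates. The constrained least-squares
problem ($\tilde M \ge 0$, $m \ge 0$) separates across virus rows into
$N_v$ independent non-negative least-squares problems of dimension
$N_h + 1$.

**Host-pairing convention.** The centred log-difference is a second-order
accurate estimate of $\mathrm d\ln v/\mathrm dt$ at the interval *midpoint*.
The package therefore pairs it with midpoint host densities (the average of
the two endpoints) by default. Pairing with the left endpoint
(`hosts = "left"`, provided for comparison) leaves a first-order bias that
floors the reconstruction error at a few times $10^{-2}$ in the headline
regime, versus a few times $10^{-4}$ for the midpoint convention — the
difference between a visibly imperfect and an essentially exact noiseless
reconstruction at 6-minute sampling.

**The constraint set.** The decay-rate constraint is implemented as the
closed condition $m \ge 0$ (a strict inequality has no attained minimizer);
positivity of the recovered decay rates is checked by the consumer, not the
solver. The solver is a Lawson–Hanson active-set method written in the
package, run on column-equilibrated designs (columns scaled to unit norm;
host columns are $O(10^3)$, the intercept is 1, coefficients are
$O(10^{-6})$, so equilibration is what keeps the active-set tests
meaningful). A generous iteration budget matters here: near $\delta = 0$ the
designs are deliberately, catastrophically ill-conditioned, and off-the-shelf
routines with a small fixed iteration cap abort on exactly the cases the
evaluation is designed to probe. The test suite cross-checks the solver
against brute-force enumeration of all active sets on small problems, and
against an independent NNLS implementation on well-conditioned ones. No
regularization is applied anywhere (a plain least-squares objective); the
condition number of the equilibrated design is reported with every fit and a
warning is raised beyond $10^{12}$, or when the column count cannot
determine the coefficients at all.

## Experiment designs and their defaults

* **Perturbation size** `delta` (default 0.5): each population starts at
  $x^*(1\pm\delta)$, the sign independent per population and seed-controlled.
  $\delta$ is the lever controlling trajectory variability, hence regression
  conditioning: at $\delta=0$ all host columns equal the equilibrium and the
  reconstruction is degenerate (the package warns); error falls as $\delta$
  grows. The headline value 0.5 is a package choice — absolute error levels
  quoted anywhere in this documentation depend on it.
* **Sampling** (defaults $\Delta t = 0.1$ h, $T = 96$ h): a design is
  reported by its number of usable regression columns, $T/\Delta t$ (961 grid
  points give 960 columns). At a fixed budget of columns there is an interior
  optimal interval: too-fine sampling of a short window leaves the
  trajectories nowhere to go (conditioning), too-coarse sampling breaks the
  discretization (bias). With the default dynamics the optimum for budgets of
  100–400 measurements sits near $\Delta t \approx 0.2$ h on the grid
  $\{0.0125, 0.05, 0.2, 0.8, 3.2, 12.8\}$ h used by the evaluation.
* **Multi-experiment designs**: several short experiments differing only in
  their initial conditions, concatenated column-wise, probe state space far
  more effectively than one long experiment of the same total size. The
  evaluation splits a fixed 960-column budget across $p = 1\ldots20$
  experiments; the error drops steeply to $p\approx5$ and is essentially flat
  past $p\approx12$ at the scaled ensemble size, with the minimum in the
  upper teens.
* **Measurement noise**: additive zero-mean Gaussian noise per series with
  variance $P_{\text{signal}}/10^{\text{SNR}_{\text{dB}}/10}$ (so 10 dB means
  noise power at 10% of signal power), applied to hosts and viruses by
  default (`targets = "viruses"` restricts it). Non-positive noisy values are
  clipped to $10^{-6}\times$ the series' smallest noiseless value to keep
  logarithms finite; the floor is configurable and recorded. Noise is applied
  to densities, before any logarithm.

**Pairing across grids.** Every sweep reuses one per-matrix pool of
initial-condition seeds at all grid points — the same replicate experiments
evaluated under every design, with only the injected noise redrawn. Grid
effects are therefore not confounded with initial-condition resampling,
which matters at the evaluation's scale: the package's standard ensemble
runs use 20 matrices (and 8–10 for the design-surface and noise protocols),
sizes chosen to keep a full evaluation in minutes on one CPU while leaving
every qualitative trend resolvable. All sub-seeds derive from one master
seed via a documented counter scheme, so every sweep is bit-reproducible.

## What the in silico evaluation shows — and what it cannot

The simulator generates data from exactly the model the estimator assumes,
with noiseless or Gaussian-corrupted measurements on a regular grid. Passing
tests therefore demonstrate: correctness of the regression assembly and the
constrained solver (including exact recovery from analytic derivatives, the
method's $\Delta t \to 0$ consistency limit); the conditioning phenomenology
(equilibrium degeneracy, the multi-experiment advantage, the interior optimal
sampling interval); and graceful degradation with noise.

They cannot demonstrate robustness to what real communities add: model
misspecification (latent periods, lysogeny, saturating adsorption, host
refuges, evolution of resistance or host range during the experiment),
demographic stochasticity, multiplicative or correlated measurement error,
irregular sampling, or abundance estimation biases from sequencing pipelines.
The reconstruction functions accept irregular time grids, but the simulator
never emits them. Inference of the host-side parameters ($r$, $a$, $K$) from
the host equations is likewise out of scope.

## Numerical choices, degenerate inputs, edge cases

* Integration: deSolve's Dormand–Prince `ode45`, `rtol = 1e-8`, absolute
  tolerance $10^{-8}$ per type relative to its equilibrium scale; sampled
  densities must come back strictly positive or the simulation errors
  (deep perturbations can collapse a population to the solver's floor —
  $\delta \ge 1$ is rejected outright).
* The sampling grid is constructed arithmetically as $(0{:}n)\Delta t$, so
  written and re-read series compare bit-exactly (all text writers format at
  17 significant digits).
* $\delta = 0$ and other degenerate designs return a result with a
  conditioning warning rather than an error: the degenerate point is part of
  the evaluation domain.
* Ties in the ensemble rewiring are broken uniformly at random under the
  call's seed; reruns with one seed are `identical()`.
* Zero log-derivative rows recover the zero network exactly (zero is
  feasible and attains zero residual).
* An all-zero reference network is rejected when scoring (the normalized
  error is undefined), as are matrices with an empty row or column anywhere
  a feasible community is required.

## Known limitations

The fill-conserving ensemble cannot reach NODF values above its
fill-determined ceiling, so "maximally nested" means maximal *at that fill*
(a full staircase needs 55 interactions in a 10×10 matrix). Fill-20 ensemble
matrices with many degree-1 hosts are close to non-identifiable from any
single experiment — reconstructions there are only as good as the
multi-experiment design used. At the scaled 20-matrix ensemble size the
location of the multi-experiment optimum is resolved only to within a few
experiments (the flat tail of the curve); the qualitative orderings are
stable. And the estimator's absolute error figures are conditional on the
package's conventions documented above — midpoint pairing, per-pair rates,
per-hour units, $\delta = 0.5$ — each of which is a flag away from its
alternative.
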