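# phagenet

Infer quantitative phage–bacteria infection networks from community
time-series data.

## The problem

In a microbial community with many bacterial host types and many phage
(virus) types, the *infection network* — which virus infects which host, and
how efficiently — governs the community's dynamics. The gold-standard plaque
assay establishes infections pair by pair and does not scale to environmental
communities, most of whose members cannot be cultured. `phagenet` implements
an alternative: estimate the whole network at once from time series of host
and virus densities, the kind of data that quantitative metagenomic pipelines
increasingly provide.

## The model and the estimator

Community dynamics follow a multi-host, multi-virus generalized
Lotka–Volterra model. With hosts `h_i` (cells/ml), viruses `v_j`
(virions/ml), growth rates `r_i`, competition coefficients `a_ii'`, a shared
carrying capacity `K`, adsorption rates `φ_ij`, burst sizes `β_ij`, decay
rates `m_j` and a binary infection matrix `M`:

    dh_i/dt = r_i h_i (1 − Σ_i' a_ii' h_i' / K) − h_i Σ_j M_ij φ_ij v_j
    dv_j/dt = v_j Σ_i β_ij φ_ij M_ij h_i − m_j v_j

Dividing the virus equation by `v_j` makes it *linear* in the unknowns: the
per-capita virus growth rate equals `Σ_i M̃_ij h_i − m_j`, where
`M̃_ij = M_ij φ_ij β_ij` is the **quantitative infection network** — the
effective infection rate of each host–virus pair. Given densities sampled at
`t_0, t_1, …`, the discrete log-derivatives

    W[j, n] = (ln v_j(t_{n+1}) − ln v_j(t_n)) / Δt

stack into the matrix equation `W ≈ (M̃ᵀ | −m) (H; 1)`, and the network is
recovered by non-negative least squares, solved per virus row with a
Lawson–Hanson active-set method:

    min ‖W − (M̃ᵀ | −m)(H; 1)‖²_F   subject to  M̃ ≥ 0, m ≥ 0.

Reconstruction quality is scored by the normalized Frobenius error
`Error_rec = ‖M̃ − M̃_rec‖_F / ‖M̃‖_F`.

The package also provides everything needed to study the estimator *in
silico*: ensembles of binary infection matrices spanning a spectrum of
nestedness (the NODF metric), feasibility-based parameter generation (growth
and decay rates solved from target coexistence equilibria), an ODE simulator
with equilibrium-perturbed initial conditions and Gaussian measurement noise
at a prescribed SNR, and evaluation sweeps over perturbation size, experiment
count, sampling design and noise level.

## Worked example

Ten hosts, ten viruses, twenty interactions; a feasible parameter set; a
96-hour experiment sampled every 6 minutes, started 50% away from
equilibrium:

```r
library(phagenet)

M      <- modular_matrix(10, 10, 5)            # who infects whom (binary)
params <- feasible_parameters(M, seed = 1)     # Table-style ranges + steady-state solve
ts     <- simulate_community(params, M,
            experiment_design(delta = 0.5, dt = 0.1, T = 96), seed = 2)
fit    <- fit_infection_network(ts, truth = quantitative_network(M, params))
summary(fit)
```

```
Quantitative infection network fit (10 hosts x 10 viruses)
Regression: 960 columns, 1 experiment(s), hosts at midpoint
Objective (residual sum of squares): 2.03814e-08
Design condition number: 79.6
Interactions above 1% of max: 20
Effective rates: 7.06e-13 - 3.14e-06 ml/(cell h)
Decay rates: 0.00314 - 0.0261 1/h
Reconstruction error vs truth: 0.001191
```

The fit recovers the network to a 0.1% normalized error; thresholding at 1%
of the largest entry identifies exactly the 20 true interactions
(`identical(support_matrix(fit), M + 0)` is `TRUE`), and the inferred decay
rates match the truth to the printed precision:

```r
round(rbind(true = params$m[1:5], recovered = fit$m[1:5]), 4)
#             [,1]   [,2]   [,3]   [,4]   [,5]
# true      0.0073 0.0078 0.0126 0.0068 0.0189
# recovered 0.0073 0.0078 0.0126 0.0068 0.0189
```

Several shorter experiments that differ only in their initial conditions can
be combined at the same total measurement budget
(`fit_infection_network(list(ts1, ts2, ...))`); see `sweep_experiment_count()`
for why that is usually the better design.

A thin command-line interface covering ensemble generation, parameter
drawing, simulation, reconstruction and the sweeps is installed at
`system.file("cli", "phagenet.R", package = "phagenet")`.

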