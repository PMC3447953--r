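# scnsim

Simulation of seasonal network plasticity in the suprachiasmatic nucleus
(SCN), the mammalian master circadian clock.

## The scientific problem

The SCN adapts its collective output to day length: the phase distribution of
single-neuron electrical activity is narrow in winter and broad in summer,
which shortens or lengthens the behavioral activity window — yet the
individual neurons fire the same way in both seasons. `scnsim` implements and
analyzes a network-level mechanism for this adaptation: the **fraction of
long-range cell-to-cell connections** (δ) is the seasonal dial. Dense
long-range wiring (winter) synchronizes the population and narrows the
activity phase; sparse wiring (summer) fragments the network into communities
and broadens it.

The package is for computational chronobiologists and network scientists who
want to simulate heterogeneous coupled circadian oscillators on structured
graphs and reproduce the seasonal analyses end to end.

## The model in brief

Each of N cells (default 600, one third ventrolateral) is a spiking
amplitude–phase oscillator

    dr/dt  = λ r (A − r)
    dφ/dt  = ω₀ (1 + ν (1 + cos φ)/2)²,   ω₀ = π(2+ν) / (τ (1+ν)^{3/2})

with log-normal A and λ across cells, τ ~ N(24 h, 3 h), and ν = 2 so the
activity peak lasts ~4.7 h per cycle (nonrhythmic cells: A = 0). A Goodwin
gene-circuit backend is included as well. Dorsomedial cells couple on a
random geometric graph (mean degree 6); long-range links are Bernoulli draws
with probability δ between regions and δ/10 within. Coupling is local mean
field, (g/kᵢ) Σⱼ Wᵢⱼ xⱼ; a 24 h square-wave light input of width σ_L
(photoperiod) drives the ventrolateral cells only. Analyses: mean-field width
w and amplitude h, correlation matrices ρ̄, peak-phase spreads, PRCs and
adjoint iPRCs, Arnold-tongue entrainment maps, efficiency/clustering (C·E
small-world product), and near-zero singular values of the local-mean-field
Laplacian L = I − D⁻¹W. See `vignettes/scn-network-model.Rmd` for the full
account.

## Worked example

```r
library(scnsim)

net_w <- build_network(winter_config(seed = 1))   # delta = 0.01,  ~900 long links
net_s <- build_network(summer_config(seed = 1))   # delta = 0.005, ~450 long links
pop   <- sample_poincare_population(600, f_nonrhythmic = 1/3, seed = 2)
sim   <- sim_config(seed = 3, dt_out = 0.25)      # g = 0.2/h, 40 cycles

run_w <- simulate_network(net_w, pop, light_schedule(width = 8),  sim)
run_s <- simulate_network(net_s, pop, light_schedule(width = 16), sim)

activity_width_height(mean_field(run_w))
#> <activity_shape> w = 6.07 +/- 0.11 h, h = 13.3 +/- 0.013 (25 cycles)
activity_width_height(mean_field(run_s))
#> <activity_shape> w = 7.63 +/- 0.13 h, h = 9.47 +/- 0.074 (25 cycles)

correlation_matrix(run_w)$rho_bar   #> 0.855
correlation_matrix(run_s)$rho_bar   #> 0.538

near_zero_singular_count(net_w)$n_near_zero   #> 1  (one synchronized block)
near_zero_singular_count(net_s)$n_near_zero   #> 2  (communities -> broad phase)
```

Reading: the winter network's mean electrical activity is **narrow and tall**
(w ≈ 6 h, h ≈ 13) with strong pairwise synchrony (ρ̄ ≈ 0.86), while the same
cells on the summer network produce a **broader, flatter** mean field
(w ≈ 7.6 h, h ≈ 9.5) with weaker synchrony — seasonal adaptation from wiring alone. The
near-zero singular values of the graph Laplacian flag the summer communities
responsible for the broadened phase distribution.

A command-line interface wraps the same functions:

```sh
inst/cli/scnsim build-net --N 600 --delta 0.01 --out out/
inst/cli/scnsim season-scan --N 150 --delta-grid 0.005,0.01,0.02 --out out/
```

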