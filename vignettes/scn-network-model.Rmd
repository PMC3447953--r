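---
title: "Modeling seasonal plasticity of the SCN network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling seasonal plasticity of the SCN network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnsim)
```

## The model

The suprachiasmatic nucleus (SCN), the mammalian master circadian clock, adapts
its collective electrical output to day length: the distribution of single-cell
activity phases is narrow in winter and broad in summer, while the individual
neurons themselves do not change. `scnsim` implements a network-level
explanation of that adaptation: the *fraction of long-range cell-to-cell
connections* acts as the seasonal control parameter.

### Cells

Each neuron is a two-dimensional amplitude--phase (Poincare) oscillator,

$$\dot r = \lambda\, r (A - r), \qquad
  \dot\varphi = \omega_0 \left(1 + \nu\,\tfrac{1 + \cos\varphi}{2}\right)^2,$$

integrated in Cartesian coordinates $(x, y) = (r\cos\varphi, r\sin\varphi)$;
the activity coordinate is $x$. The radial relaxation rate $\lambda$ and the
relative amplitude $A$ are log-normal across the population (log-scale SDs 0.4
and 0.5, as fitted to dissociated single SCN cells); nonrhythmic cells have
$A = 0$ and are damped. The phase velocity is non-uniform: fast around the
activity maximum ($\varphi = 0$), slow around the trough. The squared
raised-cosine modulation used here was chosen because it is smooth, strictly
positive for every $\nu \ge 0$, and admits a closed-form offset

$$\omega_0 = \frac{\pi\,(2 + \nu)}{\tau\,(1 + \nu)^{3/2}}$$

that makes the rotation period *exactly* $\tau$ for every modulation strength.
At $\nu = 0$ the cell is an ordinary sinusoidal oscillator (activity above its
half peak-to-trough level for 12 h per cycle); at the default $\nu = 2$ the
activity peak occupies about 4.7 h of a 24 h cycle, matching the 4--5 h
electrical-activity peak of real SCN neurons. Intrinsic periods are Gaussian,
$\tau \sim \mathcal N(24\,\mathrm h, 3\,\mathrm h)$ (truncated at 6 h), so most
periods fall in the observed 18--30 h range.

A four-variable Goodwin gene circuit (`goodwin_params()`) is available as a
biochemically grounded alternative backend: clock-gene mRNA $u$, clock protein
$p$, transcriptional inhibitor $z$, and a neuropeptide $V$ that mediates
coupling. Constants follow the published Gonze et al. parameterization.
Dorsomedial cells use Hill coefficient $n = 4$ (self-sustained); ventrolateral
cells use a reduced Hill coefficient, which damps the oscillation. We chose
$n = 3$ for the damped class: with $n = 2$ no value of the clock-gene
degradation rate $v_2$ reaches a 24 h inherent period (the linearized ringing
period bottoms out near 26.6 h), whereas $n = 3$ crosses 24 h, so the
documented recalibration of $v_2$ per region is actually attainable. The
calibrated rates (`goodwin_v2_defaults()`: $v_2^{VL} = 0.560$,
$v_2^{DM} = 0.351$ nM/h) are produced by the included one-dimensional root
search `calibrate_goodwin_v2()`. For damped cells the inherent period is
defined as the linearized ringing period $2\pi/\mathrm{Im}\,\lambda_{\max}$ at
the stable equilibrium; peak-based estimates on decaying transients proved too
discontinuous to calibrate against. Cell heterogeneity enters through a rate
scaling factor $s \sim \mathcal N(1.0, 0.05)$ dividing all production and
degradation rates.

### Network

Cells live in the unit square. One third are ventrolateral (VL, "core"):
light-receiving, nonrhythmic, mutually unconnected, placed uniformly in the
band $y < 1/3$. The rest are dorsomedial (DM, "shell"): rhythmic, placed
above, and short-range coupled as a random geometric graph with radius
$r = \sqrt{k_{\text{mean}} / (\pi \rho)}$, $\rho$ the DM density, so the mean
degree away from boundaries is $k_{\text{mean}}$ (default 6; hard boundaries,
so the realized mean degree undershoots slightly at the edges). Long-range
connections are Bernoulli draws per unordered pair: probability $\delta$
between regions and $\delta/10$ within a region. The defaults
$\delta = 0.005$ (summer) and $\delta = 0.01$ (winter) at $N = 600$ give about
450 and 900 long-range connections; $\delta$ scales as $1/N$, so the expected
counts are size-independent. All coupling is bidirectional; edges carry
weights (default 1) so that synaptic weakening can be emulated without
changing the topology (`scale_edge_weights()`). "Long-range" membership is
defined by the construction stage, not by a distance threshold.

### Coupling, light, and integration

Coupling is local mean field: cell $i$ receives
$(g / k_i) \sum_j W_{ij} x_j$ and $(g / k_i) \sum_j W_{ij} y_j$ added to
$\dot x_i$ and $\dot y_i$ (a switch restricts coupling to $x$ only for
sensitivity checks; both-coordinate coupling is the default since the coupling
terms are added to the full Cartesian system). Light is a 24 h square wave of
width $\sigma_L$ (the photoperiod) and amplitude $b$, added to $\dot x_i$ of
VL cells only. In the Goodwin backend, the neighbour neurotransmitter mean
field $F_i = (1/k_i) \sum_j W_{ij} V_j$ feeds transcription through
$v_c F / (K_c + F)$, and light (printed amplitude 0.01) adds to $\dot u_i$.

Integration uses `deSolve` (`lsoda`, adaptive, stiff-safe) with tolerances
$10^{-6}$, initial conditions $x \sim \mathcal N(1, 0.2)$,
$y \sim \mathcal N(0, 0.2)$, 40 forcing cycles with the first 15 flagged as
transient, and output sampled every 0.1 h (0.25 h in the heavier scripted
runs; a test verifies that halving the tolerances moves post-transient
mean-field peaks by less than $10^{-3}$ and that statistics computed from
cycle 16 versus cycle 21 onward differ by under 2%).

### Calibrated couplings

The two global forcing constants are calibrated once, and then frozen:

* **Coupling strength** `g`: chosen on a coarse grid as the value that
  reproduces the reported coupled regime — synchronization of the
  heterogeneous population together with an approximately ten-fold expansion
  of single-cell activity amplitudes relative to uncoupled cells. At
  $g = 0.05$ the expansion is only ~2-fold and the population barely
  synchronizes ($\bar\rho \approx 0.18$); at $g = 0.2$ the expansion is
  ~10-fold with $\bar\rho \approx 0.8$. Default: $g = 0.2\,\mathrm h^{-1}$.
* **Light amplitude** `b`: the coupled network is rigid and needs a much
  stronger zeitgeber than a single cell; $b = 0.6$ is the smallest probed
  value that entrains *both* seasonal topologies over 40 cycles at the default
  $g$. Default: $b = 0.6$.

### Analyses

* `mean_field()`: population-mean activity, shifted so its minimum is zero.
* `activity_width_height()`: per cycle, amplitude $h = \max - \min$ and width
  $w$ = total time above $\min + h/2$ (split super-threshold intervals are
  summed, which keeps $w$ meaningful for bimodal peaks). Both are invariant
  to constant shifts.
* `correlation_matrix()`: Pearson correlations of every cell pair on every
  25th recorded sample; $\bar\rho$ averages the *signed* off-diagonal values
  (zero-variance cells are excluded and reported).
* `peak_phase_distribution()`: per-cell circular-median peak time relative to
  lights-on or the mean-field maximum; the scalar spread is the angular
  deviation $\sqrt{2 (1 - R)}$, which is bounded and equals $\sqrt 2$ rad for
  a uniform distribution (the conventional circular SD
  $\sqrt{-2 \ln R}$ diverges there). Peaks are local maxima with a half-cycle
  refractory window and parabolic sub-grid refinement.
* `measure_prc()`: finite (4 h pulse) phase response curves, anchored at
  CT0 = mean-field maximum under prior 24 h entrainment; control and pulsed
  runs share the identical pre-pulse state. `compute_iprc()`: adjoint
  infinitesimal PRCs (backward integration of the variational system with
  normalization $z \cdot f = 1$), cross-checked in the tests against a
  closed form and against finite-difference shifts.
* `is_entrained()` / `entrainment_region()`: explicit, auditable criterion —
  mean-field inter-peak interval within 0.1 h of the forcing period *and*
  secular peak drift below 0.05 h per cycle over the last 10 cycles.
  Arnold-tongue scans force with photoperiod $T_{\text{ext}}/2$, one network
  realization per condition.
* `efficiency()`, `clustering_coefficient()`, `small_world_scan()`: structural
  metrics on the unweighted pattern (weights affect dynamics, not topology);
  the product $C \cdot E$ locates the small-world optimum.
* `laplacian()` / `near_zero_singular_count()`: local-mean-field Laplacian
  $L_{ij} = \delta_{ij} - W_{ij}/k_i$ (weighted, so weight-reduction
  experiments shift the spectrum; generally non-symmetric, hence singular
  values). Disconnected cells are pruned first; the count of singular values
  below $10^{-6}$ includes the trivial zero of each connected component, so a
  single synchronized network scores 1 and every extra near-zero value flags
  a community that fails to synchronize.

## What the generator emulates — and what it does not

The synthetic populations reproduce the statistical structure of the modelled
SCN: log-normal amplitude/relaxation heterogeneity, Gaussian periods,
one-third nonrhythmic light-receiving cells, geometric short-range coupling
and Bernoulli long-range wiring. They do **not** emulate anatomical 3-D
geometry, directed or delayed synapses, stochastic single-cell gene
expression, or the bimodal phase distributions seen in very long photoperiods.
Passing tests therefore demonstrate the internal consistency of the network
mechanism, not a fit to recordings of real SCN tissue.

## Numerical choices and degenerate inputs

Seeds: one root seed per experiment is split by `scn_subseed()` into
independent streams (placement, long-range wiring, population, initial
conditions), so each stage is reproducible in isolation. Degree-0 cells
receive no coupling (no division by zero) and are pruned from spectra.
Flat mean fields make the width undefined; this is flagged rather than
silently zeroed. Peakless cells are excluded from phase distributions with a
reported count. Problem sizes in the tests are deliberately modest (networks
of 20--150 cells, 14--30 cycles) with the full 600-cell, 40-cycle
configuration reserved for the scripted acceptance runs; the seasonal
orderings are robust at these sizes because the $1/N$ scaling of $\delta$
keeps the expected long-range count fixed.

## Known limitations

* The entrainment criterion is a pragmatic surrogate; near tongue borders the
  classification depends on its tolerances.
* The network PRC pairs control and pulsed mean-field peaks by index; for
  pulses that create or destroy a peak the matched pairing can wrap by a full
  cycle (mitigated by reporting shifts modulo 24 h in $(-12, 12]$).
* Analytic entrainment borders and phase-reduction variance formulas are out
  of scope; the spectral prediction (more near-zero singular values, broader
  phase distribution) is validated empirically as a rank correlation.
* With strong weight rescaling the structural metrics (unweighted by design)
  and the dynamics (weighted) intentionally diverge.

## A worked example

```{r example, eval = FALSE}
net_w <- build_network(winter_config(seed = 1))
net_s <- build_network(summer_config(seed = 1))
pop <- sample_poincare_population(600, f_nonrhythmic = 1/3, seed = 2)
sim <- sim_config(seed = 3, dt_out = 0.25)

run_w <- simulate_network(net_w, pop, light_schedule(width = 8), sim)
run_s <- simulate_network(net_s, pop, light_schedule(width = 16), sim)

activity_width_height(mean_field(run_w))  # narrow, tall winter mean field
activity_width_height(mean_field(run_s))  # broad, flat summer mean field
correlation_matrix(run_w)$rho_bar         # > rho_bar of the summer run
near_zero_singular_count(net_s)$n_near_zero  # > 1: summer communities
```
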