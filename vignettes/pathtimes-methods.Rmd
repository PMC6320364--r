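---
title: "Path-time methods: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-time methods: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pathtimes)
```

This vignette is the package's own account of the science it implements:
the stochastic model, the first-passage theory, the estimators, the
numerical schemes with their accuracy, and the choices made where the
design was genuinely open. Everything quantitative stated here is computed
by the test suite or by `scripts/acceptance.R`; nothing is quoted from
elsewhere.

## Model and units

The dynamical model is one-dimensional overdamped Langevin motion

$$\gamma(x)\,\dot x(t) = f_\mathrm{ext}(t) - \frac{\partial U}{\partial x}(x)
  + \sqrt{2 k_BT \gamma(x)}\,\xi(t),$$

with white noise $\langle\xi(t)\xi(t')\rangle = \delta(t-t')$ and friction
tied to the diffusion profile by Einstein–Stokes, $\gamma(x) = k_BT/D(x)$.
Positions are in micrometres, times in seconds, forces in femtoNewtons, and
energies in units of $k_BT$; the single constant is `units()$kBT = 4.11`
fN µm (about 298 K). Every energy/force conversion goes through this object,
which keeps unit errors structurally impossible rather than merely unlikely.

Landscapes come in four variants (`potential_*()`): the bistable asymmetric
quartic $U/k_BT = \tfrac a4 x^4 + \tfrac b2 x^2 + cx$, usually built from
physical parameters through `quartic_from_barrier(dU1, dU2, L)`
($a = 64\,\Delta U_1/L^4$, $b = -aL^2/4$, $c = 2\,\Delta U_2/L$); a constant
tilt; a mixture of Gaussian wells (our stand-in for optical point/line
traps — the experimental trap profile is not parametric, and Gaussian wells
are a choice, not a claim); and a natural-cubic-spline interpolation of
tabulated values, with extrapolation forbidden. Forces are analytic
derivatives, not finite differences.

### Telegraph forcing

The external force is a dichotomous process
$f_\mathrm{ext}(t) = \mathrm{offset} + f_0\,\mathcal T(t)$,
$\mathcal T = \pm 1$, with exponential dwells. Two rate conventions coexist
in the literature; we define $\alpha$ *by the autocovariance*
$\langle f_\mathrm{ext}(t+\Delta t)f_\mathrm{ext}(t)\rangle - \mathrm{offset}^2
\propto e^{-\alpha\Delta t}$, which fixes the per-direction switching rate
at $\alpha/2$ and the mean dwell per level at $2/\alpha$ (a decorrelation
time of 2 s means $\alpha = 0.5\,\mathrm{s^{-1}}$ and 4 s dwells). The
`offset` field expresses feedback protocols that alternate between two
unequal force levels; `offset = 0` recovers the symmetric telegraph.
`fit_decorrelation_rate()` checks the realized process by least squares on
the log-autocovariance, with a block-resampled standard error (a naive
regression SE would ignore the serial correlation of the signal).

## Simulator

`simulate_overdamped()` integrates with Euler–Maruyama,

$$x_{k+1} = x_k + \Big[\frac{f_\mathrm{tot}(x_k, t_k)\,D(x_k)}{k_BT}
 + D'(x_k)\Big]\,\Delta t + \sqrt{2 D(x_k)\Delta t}\; \eta_k ,$$

in compiled code, drawing from R's RNG so that a seed makes runs
bit-identical. The $D'(x)$ term is the kinetic-convention (isothermal)
spurious drift: with it, the simulator's stationary law matches the
Fokker–Planck current $j = (f/\gamma)\rho - D(x)\partial_x\rho$ used by the
theory module, so both halves of the package solve the *same* model even
for spatially varying $D$ (for constant $D$, the paper regime of every
shipped analysis, the conventions coincide). Reflecting channel ends are
applied by folding.

Numerical choices:

* **Time step.** Default $\Delta t = 10^{-3}$ s, far below the fastest
  deterministic relaxation at the parameter scales used here (well
  curvatures of order $10^2\,k_BT/\mu m^2$ give relaxation times of order
  $10^{-1}$ s at $D = 0.15\,\mu m^2/s$). A weak-convergence test (halving
  $\Delta t$) is part of the suite.
* **Crossing times.** Exit and transition times are linearly interpolated
  between the last interior and first exterior sample, removing the
  $O(\Delta t)$ part of the discretization bias.
* **Sampling bias of path times.** A subtler $O(\sqrt{D\,\Delta t})$ bias
  remains: grazing excursions across a boundary that return within one step
  are invisible, which effectively widens the interval and lengthens
  transition paths. Measured on free diffusion across 1 µm it is $\approx
  4.8\%$ of the mean at $\Delta t = 10^{-3}$ s and $\approx 1\%$ at
  $2.5\times10^{-4}$ s; analyses that compare *means* against closed forms
  therefore use $\Delta t = 2.5\times10^{-4}$ s, while direction-symmetry
  comparisons, where the bias cancels between directions, use
  $5\times10^{-4}$–$10^{-3}$ s.
* **Censoring.** Protocol repeats that never exit within `t_max` are
  reported as censored and excluded from time statistics, mirroring the
  discarding of incident-contaminated experimental repeats; their count is
  always visible.

Long event-collection runs (`run_transition_protocol()`,
`asymmetry_sweep()`) never store trajectories: the compiled core streams
only boundary-crossing events, in resumable chunks of one continuous
realization, so memory stays flat while millions of steps integrate per
second.

## First-passage theory

All interval theory treats both boundaries as absorbing,
$\rho(x_L, t) = \rho(x_R, t) = 0$.

**Quadrature stack.** With $u = U/k_BT$ and weights $e^{\pm u}/D$, the mean
first-passage time solves $(D\tau')' - u' D \tau' = -1$; integrating
factors give a closed two-pass prefix-sum solution (`mfpt_profile()`,
$O(N)$). Splitting probabilities use
$P_\to(x_0) \propto \int_{x_L}^{x_0} e^{u}/D$; the $1/D$ weight is required
for consistency with the kinetic convention above and is invisible for
constant $D$. The mean transition-path time (`mean_transition_time()`) is
the standard double quadrature with $e^{u}/D$ inner integrals and
$e^{-u}$ outer weight, evaluated with cumulative trapezoids; for $U = 0$ it
reduces exactly to $L^2/6D$, and it is invariant under $U \to U + c$ and
under force reversal — both asserted in tests.

A note on the current at an absorbing boundary: a transition-path density
normalization that is sometimes written as
$j = \partial_x(U\rho) - D\partial_x\rho$ is dimensionally inconsistent; we
implement the consistent form $j = (f/\gamma)\rho - D\partial_x\rho$
throughout, which agrees with the exit-problem current.

**Fokker–Planck solver.** `exit_time_density()` evolves
$\partial_t\rho = -\partial_x j$ with a conservative finite-volume
discretization (fluxes at half-nodes, central differencing; cell Péclet
numbers stay far below 2 at the default $N = 513$ nodes) and
Crank–Nicolson stepping with a Thomas solve per step. The initial
condition is a grid delta at the node nearest $x_0$. Because
Crank–Nicolson is not L-stable, a delta would excite non-decaying
odd–even ringing; the first 10 steps are therefore fully implicit
(Rannacher smoothing). Steps are graded: $\Delta t_0 = 0.2 h^2/D$,
growing by 3% per step to a cap of one five-hundredth of the diffusion
time, and the horizon extends automatically until the surviving
probability falls below `mass_tol` (scaled by the smaller splitting
probability, so rare-direction densities keep full relative accuracy).
Boundary effluxes use second-order one-sided differences. Against the
spectral-series solution for free diffusion the density is accurate to
$\sim 10^{-5}$ in sup-norm; first moments agree with the quadrature stack
to better than 1%.

**Transition-path densities.** `transition_time_density()` launches the
solver from $x_0 = x_L + \varepsilon$ at $\varepsilon = 4h$ and $2h$,
normalizes each flux by the splitting probability at its own start, checks
that the first moment moves by less than 1% between the two levels
(otherwise it raises a convergence error), and Richardson-extrapolates
$2\rho_{2h} - \rho_{4h}$; tiny negative values from the extrapolation are
clipped at zero. Forward and backward densities agree pointwise to
$\sim 2\times10^{-4}$ relative on the asymmetric quartic — the equilibrium
symmetry as an exact property of the theory stack.

## Events and statistics

Transition paths use the last-crossing convention: an L→R event spans from
the final up-crossing of $x_L$ to the first subsequent crossing of $x_R$
with no intermediate return. Operationally, all interpolated crossings of
both boundaries are merged in time order and adjacent (L, R) pairs are
kept — a formulation that is exactly equivalent, vectorizes, and is shared
between trajectory analysis and the streaming simulator.

`ks_two_sample()` wraps the two-sided two-sample KS statistic with the
asymptotic Kolmogorov p-value at effective size $n_1 n_2/(n_1+n_2)$
(sample sizes here are $10^2$–$10^3$; tests validate the statistic against
full enumeration at tiny $n$ and the p-value against permutation).
`band_halfwidth(s)` inverts the Kolmogorov tail for ECDF confidence bands.
The working significance for symmetry verdicts is a parameter: interactive
use may follow the strict 0.5 convention (demanding better-than-coin-flip
similarity), while every automated test in this package uses 0.05, since a
0.5 threshold rejects half of all true-null comparisons by construction.
For the same reason, single KS verdicts on symmetric configurations are
always aggregated as "not rejected in at least 8 of 10 independent seeds".

## Inference

`fit_drift_diffusion()` implements the Gaussian displacement law by exact
per-bin moment matching — the maximum-likelihood solution, without
nonlinear-fit fragility: $\hat D = s^2/2\Delta t$ from the step variance
and $\hat f = \bar{\Delta x}\, k_BT/(\hat D \Delta t)$ with the friction
eliminated by Einstein–Stokes. Steps are assigned to the bin of their
*starting* position (the Itô-consistent left-point rule); bins with fewer
than 50 steps are flagged, not estimated; the default spatial bin width
where one must be chosen is 0.1 µm, and 0.05 µm is used when a potential
will be reconstructed by integration (trapezoid and binning bias both
shrink quadratically with bin width; 0.26 kBT sup-norm error on a
5000 s simulated double well, versus 0.33 kBT at 0.1 µm).
`force_from_exit_counts()` inverts the constant-force splitting formula,
$\hat f = (2k_BT/L)\,\mathrm{logit}(n_\to/n)$, with a continuity-corrected
Wilson interval mapped through the same monotone transform — the
conservative Wilson variant, chosen because its exact coverage stays at or
above the nominal level instead of oscillating around it. At the shipped
study conditions the information bound on $\hat f$ from $10^5$ steps at
80 Hz is about 0.43 fN (13% of a 3.3 fN force): displacement-mean force
estimates at that data size are fluctuation-limited, and coverage counts
over 100 Monte-Carlo repeats of a 95% interval fluctuate binomially about
their expectation — both worth remembering when reading single-run
recovery numbers.

## Non-equilibrium diagnostics

`occupancy_2d()` histograms $(x, f_\mathrm{tot})$ with
$f_\mathrm{tot} = f_\mathrm{ext} - dU/dx$. `coarse_current_2d()` counts net
crossings between adjacent bins (antisymmetric edge currents, diagonal
moves counted and reported but not assigned) and summarizes them as
oriented plaquette circulations. The signed circulation — zero in
expectation under detailed balance — changes sign *exactly* under time
reversal of the trajectory, which the package exposes through
`time_reverse()` as an assumption-free null; its absolute value serves as
the nonnegative score, and significance comes from a standard error over
contiguous trajectory blocks (default 10), since bin-to-bin moves are
serially correlated. At the driven study conditions the z-score is ~30–60;
equilibrium runs sit within $|z| < 3$.

`asymmetry_sweep()` reports directional transition-path means, SEMs,
counts, and KS p-values per telegraph rate $\alpha$. At the bistable
benchmark (barrier 5 kBT, asymmetry 2 kBT, wells 1 µm apart, $f_0 = 82$ fN,
$D = 0.15\,\mu m^2/s$), slow switching ($\alpha = 0.5$) yields clearly
different directional distributions, and fast switching ($\alpha = 50$)
restores symmetry — the driving averages into an effectively white force.

### The synthetic hairpin

The hairpin emulation is deliberately topological: a 1D extension
coordinate in a symmetric 5 kBT double well (span 1 µm, $D = 0.15$),
driven between two force levels. It reproduces the *structure* of a
feedback-driven two-state folder — four metastable doublet states
(F±, U±), split pathways, and direction-dependent corner-to-corner path
times that include the intermediate-state dwells — not any calibrated
hairpin's kinetics. Real force-spectroscopy data differ in ways this
generator does not emulate: nm-scale extensions and pN forces, handle and
linker compliance, instrument noise and drift, and a sequence-dependent
free-energy landscape; conclusions that pass here are statements about the
mechanism, not about any particular molecule.

The default levels $(+30, -18)$ fN were set by a regime argument, once:
the doublet cycle requires (i) both tilted landscapes to remain bistable
(tilts below the $\approx 63$ fN spinodal of the default well), (ii)
dwells per force level ($2/\alpha = 4$ s) longer than intra-well
relaxation, and (iii) the *adiabatic* driving condition — barrier crossing
under favourable tilt faster than a force dwell, under unfavourable tilt
much slower — so that unfolding locks to high-force phases and folding to
low-force phases. Weaker levels (e.g. amplitude ~12 fN) fail condition
(iii): both crossings then outlast the dwell, path times become dominated
by symmetric waiting for switches, and the doublet asymmetry washes out;
this failure mode was observed directly and motivated the shipped
defaults. The nonzero level midpoint (+6 fN) makes the two phases'
effective landscapes inequivalent, which is what renders the two
corner-to-corner directions statistically distinguishable
(KS $p$ between $10^{-3}$ and $10^{-14}$ at 400–800 events per direction
across seeds). Equal levels degenerate to a constant force — an
equilibrium two-state system whose directional path times are symmetric.

`classify_hairpin_states()` labels samples by extension threshold (with a
0.1 µm transit buffer against threshold flicker) and force level;
`doublet_transition_times()` measures corner-to-corner spans from the last
exit of one corner state to the first entry into the diagonal one, so
intermediate dwells count toward the path time, by design.

## Problem sizes and reproducibility

The shipped analyses choose sizes that make every statistical verdict
well-powered on a single CPU: 2000–3000 repeats for exit protocols,
500–1000 events per direction for path-time comparisons (collected at
$\Delta t$ matched to the bias analysis above), $10^5$ steps for
drift-diffusion recovery, 3000 s runs for current diagnostics, and 25000 s
for the hairpin doublet statistics. One user-facing seed drives
everything; `child_seed()` expands it counter-style so adding an analysis
stage never perturbs an earlier random stream. `scripts/acceptance.R`
re-derives all headline numbers from scratch under a single `--seed`.

## Known limitations

* Strictly one-dimensional state: no 2D/3D landscapes, no hydrodynamic
  coupling or wall-drag model of $D(x)$ (a measured profile can be supplied
  as data).
* Overdamped only; no inertial corrections.
* The Fokker–Planck module handles static potentials; driven cases are
  delegated to simulation.
* Path-time statistics inherit the $O(\sqrt{D\Delta t})$ sampling bias
  discussed above; at experimental frame rates this is part of the
  measurement, and analyses of real data should treat the recorded rate as
  the resolution limit it is.
* No entropy-production estimation from path-time asymmetry: asymmetry
  witnesses broken detailed balance, but its absence proves nothing, so the
  package deliberately reports diagnostics, not entropy rates.
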