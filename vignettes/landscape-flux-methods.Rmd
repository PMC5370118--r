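---
title: "Methods: landscape and flux analysis of the basal ganglia motor circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape and flux analysis of the basal ganglia motor circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`bgflux` implements a firing-rate model of the basal ganglia-thalamo-cortical
motor circuit with seven populations: motor cortex (1), striatal D1 neurons of
the direct pathway (2), striatal D2 neurons of the indirect pathway (3), the
GPi/SNr output complex (4), GPe (5), motor thalamus (6) and STN (7). Each
population is a single Hopfield-type rate unit,

$$C_i \frac{dx_i}{dt} = I_i - \frac{x_i}{R_i}
  + \sum_j \pm\, T_{ij}\, f(x_j) \;(\pm D_{\mathrm{input}}),$$

where $f(x) = x^n / (s^n + x^n)$ is a Hill response with threshold $s = 2$
and exponent $n = 2$, $T_{ij} \ge 0$ is the strength of the connection from
population $j$ to $i$ with the sign fixed by the wiring (cortex and STN
excite, striatum, GPe and GPi inhibit), $R_i = 1.67$, and
$\tau = R_i C_i = 6$ ms so that every population relaxes with the same leak
rate. Dopamine enters as a constant drive $+D_{\mathrm{input}}$ on the D1
population and $-D_{\mathrm{input}}$ on the D2 population, the standard
account of D1/D2 receptor modulation. The published strength $T_{1,7}$
appears in no equation of the model; it is stored for completeness and only
enters the cortex equation when `include_T17 = TRUE`.

Activities are dimensionless and not clamped at zero: the equations are
integrated exactly as written, and a trajectory that dips below $-s/10$
triggers a validity warning because the even Hill exponent makes $f$
symmetric there and the regime physiologically meaningless.

## Deterministic structure

With the default parameters the circuit is mono-stable at high dopamine
(`D_input = 1.4`, the "normal" state with active cortex and thalamus) and at
very low dopamine (`D_input = 0.6`, the akinetic state), and goes through two
supercritical Hopf bifurcations in between: for `D_input` roughly in
(0.66, 1.13) the only attractor is a limit cycle at beta-band frequency
(17-22 Hz at $\tau = 6$ ms), the model's analogue of Parkinsonian
oscillations. `scan_dopamine()` tabulates the regime per level;
`hopf_point()` refines each bifurcation by bisection on the leading
eigenvalue real part of the interior fixed point, continued by Newton
iteration — two sign changes in a one-dimensional parameter need no
continuation software.

Limit cycles are detected from successive maxima of the cortex coordinate
(the reference signal throughout). Two numerical choices matter here:

* **Amplitude threshold** (`amplitude_tol = 1e-3`): distinguishes sustained
  cycles from damped ringing; no criterion is stated in the source material,
  so the threshold is an explicit, configurable convention.
* **Adaptive transient**: near a Hopf point, ringing decays arbitrarily
  slowly (critical slowing), so a fixed transient misclassifies slowly
  decaying transients as cycles. `detect_limit_cycle()` therefore extends
  the transient (doubling, continuing from the last state, up to `max_time`)
  while the envelope still shrinks by more than 1% per window, and reports
  "no cycle" if the envelope either drops below the threshold or is still
  shrinking at the budget.

Integration uses an adaptive Dormand-Prince 5(4) scheme implemented in C++
(no ODE-solver package is assumed), with defaults `atol = 1e-9`,
`rtol = 1e-7`; the same stepper drives the deterministic system, the moment
closure, and a Hopf normal-form toy used by the tests as an analytic oracle
(radius $\sqrt\mu$, period $2\pi/\omega$).

## Stochastic dynamics and the moment closure

Fluctuations are modelled as additive Gaussian white noise with
autocorrelation $2 D \delta(t - t')$, identical on all seven coordinates;
the default diffusion coefficient `D_diff = 0.01` is a deliberate choice (the
source states only that it is small): it keeps the Gaussian closure accurate
while giving non-degenerate probability grids at the circuit's activity
scale (~0-5).

The steady-state distribution is obtained by the self-consistent mean-field
route: the joint probability is factorised into per-population marginals,
and means and variances evolve by the moment equations
$\dot u = F(u)$, $\dot\sigma = \sigma A^T + A \sigma + 2D$ with
$A_{ij} = \partial F_i / \partial x_j$, retaining only the diagonal of
$\sigma$. Because no population couples to itself through the Hill response,
$A_{ii} = -1/\tau$ exactly, so every retained variance relaxes to
$D\,\tau$ ($= 0.06$ by default) regardless of state — a structural property
of this closure worth knowing when interpreting the landscapes:

* **Known limitation.** The diagonal closure discards coupling-amplified
  fluctuations. At the `D_input = 1.4` fixed point the full Lyapunov
  equation gives true stationary variances of 0.27-0.77 depending on the
  population — 5-13 times the closure value. The Langevin-histogram
  landscapes are correspondingly broader than the mean-field ones; the
  package's oracle tests compare the two at the localisation scale each
  estimator actually supports, and compare variances only in the uncoupled
  (all $T = 0$) limit where the closure is exact.

In a mono-stable regime the converged snapshot defines
$P(x_a, x_b) = N(x_a; u_a, \sigma_a)\, N(x_b; u_b, \sigma_b)$ on the
projection grid. In an oscillatory regime the moments are periodic, and the
steady state is the uniform time average of (by default) 200 evenly phased
snapshots over exactly one period, renormalised; doubling the snapshot count
changes the grid by less than $10^{-4}$ in total variation. The default
projection is (cortex, thalamus), with (GPi, STN) as the replicate; the grid
auto-ranges to the attractor projection padded by four noise standard
deviations, at 200 x 200 cells.

One property of the period average worth noting: each snapshot is centred
exactly on the deterministic orbit, but the *mixture* ridge crest is pulled
toward slow arcs (where many snapshots accumulate), by up to about one noise
standard deviation $\sqrt{D\tau}$ at the fastest arcs. The ridge follows the
cycle at the noise scale, not at arbitrary grid precision.

## Landscape, flux, and the stability metrics

The non-equilibrium potential is $U = -\ln P_{ss}$, with a probability floor
of $10^{-12}$ of the grid maximum before the logarithm so $U$ is finite
everywhere. The steady-state flux is
$J = F P - D \nabla P$ (central differences, one-sided at boundaries, zero on
floored cells), and the driving force decomposes as
$F = J_{ss}/P_{ss} - D \nabla U$. On a grid this identity holds up to
discretization error; `decomposition_residual()` evaluates it on every cell
whose finite-difference stencil stays above the floor (the clamp would
otherwise inject an artificial crease into $\nabla U$). The maximum residual
sits on the boundary stencils and halves when the spacing halves (first
order); the interior residual is second order.

Because the landscape lives on a 2-D projection while the drift is 7-D, the
five off-projection coordinates must be closed to evaluate $F$ on the grid.
The default (`closure = "conditional"`) sets them, per cell, to their
probability-weighted conditional means across the phase snapshots; a
`"nearest"` orbit-point closure is available behind the same switch. Both
are approximations, made explicit rather than implicit.

Scalar metrics, per condition:

* **Barrier height** $U_{max} - U_{min}$, with $U_{max}$ the maximum over
  grid cells strictly inside the projected cycle polygon (ray-casting
  point-in-polygon test) and $U_{min}$ the minimum of $U$ bilinearly
  interpolated along the cycle polyline. The ring interior is defined by the
  deterministic cycle, not by thresholding $U$ — unambiguous for
  banana-shaped rings.
* **Average flux** $J_{Average} = \oint |J|\,dl / \oint dl$: the arc-length
  mean of the flux magnitude along the ring (a signed tangential variant is
  available via `signed = TRUE`).
* **Entropy production rate** $\sum_{cells} J\!\cdot\!J / (D P) \times$
  cell area, the standard non-equilibrium dissipation functional,
  nonnegative and zero only in detailed balance. The exact published form
  lives in supplementary material not available here; the standard form is
  implemented and labelled as such.

Across the oscillatory block the barrier and the average flux rise and then
fall (oscillations are weak near both Hopf points and most robust
mid-block), the period falls monotonically with dopamine, and the entropy
production rate co-varies with the flux — more coherent pathological
oscillations cost more energy.

## Sensitivity and DBS protocols

`sensitivity_scan()` perturbs one connection at a time over a percent grid
(default the eight labelled pathway arrows, ±50% in 10% steps) and rebuilds
the metrics through the full pipeline; the baseline is computed once and
reused bit-for-bit at 0%. Strengthening the indirect-pathway projection
striatum→GPe (T53) pushes the circuit into (more stable) oscillation;
strengthening the direct-pathway projection striatum→GPi (T42) suppresses
it — the direct/indirect asymmetry that makes direct-pathway activation a
plausible symptomatic therapy.

Deep brain stimulation is modelled as constant (DC) input, not pulsatile
stimulation. `dbs_direct_inhibition()` adds a nonpositive offset inside the
target's input bracket; `dbs_decoupled()` additionally multiplies every
coupling term *sourced* at the target by an efferent gain ≥ 1, so somatic
inhibition and axonal output activation are decoupled, as the
electrophysiology suggests. Design choices:

* **Baseline dopamine for DBS, `D_input = 1.10`.** The source does not print
  the level its DBS experiments use; the shapes it reports constrain it.
  Inhibiting GPe acts like further dopamine depletion (indirect-pathway
  disinhibition), so its flux can only rise before falling if the baseline
  sits on the upper (mild-depletion) side of the oscillatory block; at
  mid-block baselines the STN curve shows a genuine sub-1% initial flux rise
  that contradicts the reported monotone decrease. Just below the upper Hopf
  point, all three reported shapes hold: GPi and STN inhibition suppress the
  flux monotonically, GPe inhibition first amplifies then suppresses it, and
  decoupled protocols suppress it on all three targets.
* **Stimulation grids.** Direct inhibition: offsets 0 to −1.2 in steps of
  0.15. Decoupled: offsets to −2.4 with gains to 1.4. Deeper decoupled
  stimulation drives activities strongly negative, where the even Hill
  exponent re-excites the circuit — an unphysiological regime the default
  grid deliberately stops short of.
* "Decrease of neural activity in the stimulated target" is measured as the
  drop of the target's attractor-mean activity (cycle average, or stable
  fixed-point value) relative to baseline.

## The Langevin oracle

`simulate_langevin()` is a brute-force Euler-Maruyama simulator
($x \leftarrow x + F\,dt + \sqrt{2 D\,dt}\,\xi$, default `dt = 0.01` ms,
reproducible under `set.seed()`), kept deliberately independent of the
mean-field pipeline so it can validate it: `empirical_landscape()` bins
post-burn-in samples (default burn-in: ten times the slowest linear
relaxation time at the attractor) into the same grid/potential containers.
What a green oracle test establishes — and what it does not:

* the mean-field and empirical basins/rings coincide in location (minima
  within one cell at the estimators' localisation scale; the empirical
  0.5-nat ridge band covers ≥ 90% of the mean-field band at `D_input = 0.8`),
* uncoupled moments are exact (mean $I R$, variance $D\tau$),
* but the empirical band is systematically wider than the closure's (see the
  closure limitation above), and at `D_diff = 0.01` the noise genuinely
  lengthens the mean rotation period by ~10% relative to the deterministic
  cycle (lingering near the ring's slow basins). The deterministic/stochastic
  period cross-check is therefore run at `D_diff = 0.001`, where the
  spectral peak matches the ODE period within the (phase-diffusion
  broadened) spectral resolution.

## Reproducibility

Every experiment of the study's figure set ships as a flat key/value config
under `inst/configs/` (schema version 1); `run_experiment()` executes a
config into a bundle of tables, grids and a provenance record (config hash,
package version, wall clock), `export_results()` writes CSV tables,
plain-text grids and JSON sidecars, and `inst/cli/bgflux.R` is a thin shell
entry point with distinct exit codes for config errors, numerical failures
and partial completion. All perturbation scans are pure functions of
(parameters, protocol, seed). Test-suite simulations are scaled down
(shorter Langevin runs, 50-150 cell grids where the default is 200) to keep
the default run inside a few minutes; the acceptance checks state their
comparison scales inline.

```{r example}
library(bgflux)
p <- bg_params(D_input = 0.8)
L <- bg_landscape(p)          # classify, close moments, build U and J
summary(L)
plot(L)                       # potential contours, flux arrows, cycle
```
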