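---
title: "Tethered particle motion with reversibly binding tethers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tethered particle motion with reversibly binding tethers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`retether` simulates the confined Brownian motion of a micron-scale particle —
a coccal bacterium is the motivating case — that adheres to a flat substratum
through many elastic tethers (cell-surface appendages, EPS strands), each of
which binds reversibly: a tether detaches when its elastic force exceeds an
adhesion-force threshold, and re-attaches whenever its anchor comes back
within reach of the surface. The package also implements the track statistics
of bacterial vibration spectroscopy (vibration amplitude, position-maps,
positional autocorrelation, mean-squared displacement and its confinement
exponent) and the retract-curve metrics of bacterial-probe AFM, so that
simulated and experimental data flow through one pipeline.

The central question the model addresses: how can adhesion be irreversible as
a whole while every individual bond is reversible? In the simulation, tethers
detach and successively re-attach, but essentially never all at once — the
particle stays surface-bound while its confinement cage slowly reorganises,
producing nanoscale displacement without escape.

## The model

The particle is a rigid sphere of radius $a$ (diameter default 1.0 µm) with
$n$ anchors fixed on its surface (default 256, placed by a Fibonacci spiral
lattice, the standard deterministic quasi-uniform construction). The
substratum is the plane $z = 0$; the sphere centre obeys $z \ge a$
(reflection). Anchor $i$ sits at $\mathbf{c} + a\,\mathbf{u}_i$ where
$\mathbf{c}$ is the centre; rotation is neglected, so the
$\mathbf{u}_i$ are constant (vibration amplitude is a centre-of-mass
observable and tethers are short relative to $a$; rotational compliance is a
second-order correction).

A bound tether connects its anchor tip to a fixed attachment point on the
plane and acts as a pull-only Hookean spring of rest length $L_0$ and spring
constant $k$:
$$\mathbf{F}_i = -k \,\max(0,\, d_i - L_0)\, \hat{\mathbf{e}}_i,$$
with $d_i$ the tip-to-attachment distance and $\hat{\mathbf{e}}_i$ the unit
vector from attachment toward tip. Polymeric tethers buckle rather than
support compression, hence pull-only; a two-sided spring is available behind
`allow_compression` for comparison.

Binding kinetics are threshold-based and deterministic:

* **detachment** — a bound tether whose elastic force strictly exceeds the
  tether adhesion force $F_{adh}$ is released (set $F_{adh} = \infty$ to
  inhibit detachment entirely);
* **attachment** — an unbound tether whose anchor tip is within $L_0$ of the
  plane binds at the perpendicular projection of its tip (so it starts
  slack). An optional per-step attachment probability (default 1) is exposed,
  but no rate parameter is fitted.

Per timestep the order is: particle update, then detachments, then
attachments, each pass in ascending tether index. A tether released while its
tip is still within reach re-binds in the same pass at its current
projection; this "re-centering" of attachment points is the mechanism by
which the confinement cage migrates and the particle displaces nanoscopically
without ever being free.

The centre moves by overdamped Langevin dynamics (Euler–Maruyama):
$$\Delta \mathbf{r} = \frac{\sum_i \mathbf{F}_i}{\gamma}\,\Delta t
  + \boldsymbol{\xi}, \qquad
  \boldsymbol{\xi} \sim \mathcal{N}\!\left(0,\; \tfrac{2 k_B T}{\gamma}\Delta t
  \cdot I\right),$$
with gravity and buoyancy neglected (sub-piconewton for a density-matched
micron sphere). An inertial integrator — the exact constant-force Langevin
update with the full position–velocity covariance — is available behind
`integrator = "inertial"` for fidelity checks; the momentum relaxation time
of a micron particle in water (~5×10⁻⁸ s) is far below every observable
timescale, so it reproduces overdamped statistics.

### Effective drag

$\gamma = 6\pi\eta a \times f_{drag}$. The bulk Stokes factor
($f_{drag} = 1$) describes a sphere far from boundaries; an *adhering*
particle moves much more slowly — lubrication in the thin fluid gap and
internal friction of the polymeric tethers add dissipation that bulk
viscosity does not capture. Experimentally, adhering bacteria tracked at
60 Hz show positional autocorrelation half-times of 0.02–0.4 s; a bare-drag
sphere confined to a ~33 nm cage would decorrelate in ~2.5 ms, i.e. within a
single frame, and would produce qualitatively wrong autocorrelation and MSD
curves. The shipped default $f_{drag} = 150$ was calibrated once so that the
permanently-bound control reproduces that observed autocorrelation scale
(~0.2 s half-time), and is frozen. Free-particle validity checks
(Stokes–Einstein diffusion, MSD exponent 1) set `effective_drag_factor = 1`,
where $\gamma = 6\pi\eta a$ holds exactly. Faxén/lubrication corrections as
explicit functions of gap height are out of scope; the constant factor is the
simplest model consistent with the tracking observations.

## Parameters and shipped defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `particle_diameter` | 1.0e-6 | m | coccal bacterium |
| `particle_mass` | density-matched | kg | only used by the inertial integrator |
| `temperature` | 298 | K | room temperature |
| `fluid_viscosity` | 1.0e-3 | Pa s | water |
| `effective_drag_factor` | 150 | — | calibrated to tracked autocorrelation times (above) |
| `n_tethers_total` | 256 | — | anchors quasi-uniform on the sphere |
| `n_tethers_initial_bound` | 12 | — | initial binding tethers |
| `tether_rest_length` | 130e-9 | m | calibrated once so the non-detachable control vibrates at the 33 nm level; the scale of long fibrils/EPS strands |
| `tether_spring_constant` | 1.2e-5 | N/m | bacterial tether stiffness from vibration spectroscopy |
| `tether_adhesion_force` | 3e-13 | N | midpoint of `default_force_sweep()`; see below |
| `timestep` | 1e-5 | s | stability and rate convergence (below) |
| `duration`, `frame_rate` | 33 s, 60 Hz | | the tracking-experiment convention; 1980 frames |

Geometry calibration: with the sphere resting on the plane, anchors whose
tips lie within $L_0$ of the surface can bind. At the defaults ~33 anchors
satisfy this; the 12 closest-to-surface start bound (ties broken by index).
$L_0$ and the diameter were the two calibration knobs, fixed once against the
33 nm vibration amplitude of the detachment-inhibited control and then
frozen. $L_0$ mainly sets the lateral slack
$\sqrt{L_0^2 - h_i^2}$ of each bound tether and hence the cage size.

The adhesion-force sweep `default_force_sweep()` = (1, 2, 3, 4, 6)×10⁻¹³ N
spans the crossover from frequent Brownian-driven detachment (amplitudes
several times the static level; the particle nevertheless remains
surface-bound) to zero detachments within 33 s. The scale is physical: a
tether thermally stretched by one standard deviation carries
$k\sqrt{k_BT/k} \approx 2\times10^{-13}$ N. The midpoint, 3×10⁻¹³ N, is the
default adhesion force for "dynamic tether" runs.

## Track statistics

All statistics consume a plain table `time_s, x_nm, y_nm` at uniform frame
spacing — simulated or experimental.

* **Vibration amplitude** — mean of the per-axis *population* standard
  deviations about the track mean (the two agree for circular maps). A fixed
  marker amplitude is subtracted linearly and the result floored at zero;
  quadrature subtraction is available (uncorrelated noise adds in variance),
  but linear subtraction is the reporting convention followed here.
* **Positional autocorrelation** —
  $R(h) = \sum_{n=0}^{N-h-1} x(n)x(n+h) / \sum_{n=0}^{N-1} x(n)^2$ on the
  mean-centred x-coordinate (the y-axis is available for anisotropy checks).
  This biased estimator satisfies $R(0)=1$, $|R(h)|\le 1$. The
  autocorrelation time is the lag at which $R$ first falls to 0.5 (linear
  interpolation; $\infty$ if never).
* **MSD** — $\mathrm{MSD}(i) = \frac 1M \sum_{k=1}^{M}
  |\mathbf{r}(j_k + i) - \mathbf{r}(j_k)|^2$ over 2D positions with $M = 10$
  starting frames spaced 100 frames apart and $N = 1000$ lags (16 s at
  60 Hz); ensembles average MSD curves pointwise across particles. This is
  the lag-resolved reading of the double-normalised MSD definition used in
  vibration spectroscopy — the only reading that yields MSD as a function of
  time.
* **Confinement exponent** — $\mathrm{MSD}(t) = A t^{\alpha}$ fitted by OLS
  on $(\log t, \log \mathrm{MSD})$ inside a lag window. Log-log OLS weighs
  decades evenly, the standard in single-particle tracking. Both reporting
  windows are supported: $t > 1$ s (per-strain convention) and $t > 5$ s
  (long-time confinement); the window is always recorded in the fit object.
  $\alpha = 1$ is free diffusion, $\alpha = 0$ full confinement,
  $0 < \alpha \ll 1$ confined displacement with slow escape.

## AFM retract-curve metrics

Attractive forces are stored negative; metrics are reported as positive
magnitudes. The baseline and noise SD come from the far-separation tail of
the retract segment (median and scaled MAD — robust; the procedure an
instrument would otherwise leave unstated). Metrics: **adhesion force** (most
negative baseline-subtracted retract force), **adhesion peaks** (local minima
below 3×noise with topographic prominence ≥ 3×noise, after a light 5-sample
boxcar — without smoothing, a thousand-sample curve statistically yields
single-sample 3σ excursions somewhere), **rupture length** (separation where
the force last returns to within 3×noise of baseline after the final peak),
and **adhesion energy** (trapezoidal area of the sub-baseline retract well
from contact to the rupture length, in J and $k_BT$). `synth_fd_curve()`
generates multi-tether sawtooth curves with a ground-truth ledger (per-tether
rupture positions, analytic $\sum \frac12 k\,\Delta x^2$ energy) for
round-trip testing. Worm-like-chain fitting of individual peaks and thermal
cantilever calibration are out of scope.

## Numerical choices

* **Timestep** 1e-5 s: the stiffest composite (≈30 taut tethers) gives
  $k_{tot}\Delta t/\gamma \approx 0.03$, far inside Euler–Maruyama stability,
  and detachment counts are insensitive to doubling $\Delta t$ (asserted in
  the test suite).
* **Frame sampling**: frames at the integration step nearest each multiple of
  the frame interval; frame count $\lfloor \mathrm{duration} \times
  \mathrm{frame\ rate}\rfloor$ (so 33 s at 60 Hz → 1980 frames; the 2000-image
  convention at 60 Hz is internally inconsistent and the floor rule is used).
* **Boundary conventions**: detachment requires *strictly* exceeding
  $F_{adh}$; the wall reflects ($z \to 2a - z$); a tether exactly at
  $d = L_0$ is slack.
* **Reproducibility**: one seeded RNG per simulation (R's stream, consumed
  identically by the compiled and the reference R path); identical
  (config, seed) gives byte-identical trajectories.
* **Degenerate inputs**: zero-variance tracks are a data error for
  autocorrelation; `fit_power_law` refuses windows with fewer than 3 lags or
  non-positive MSD; curves without adhesion peaks report rupture length 0
  with a warning.

## What the synthetic track generator emulates

`generate_track()` produces white-noise, confined (exact discrete
Ornstein–Uhlenbeck), free-diffusion and drift tracks with 5 nm Gaussian
measurement noise by default (the spatial resolution of the tracking
experiments emulated). These fixtures carry the *statistical* structure the
estimators assume — stationary confinement with a single relaxation time,
or scale-free diffusion — but not the mechanistic features of real tracks
(heterogeneous per-tether relaxation spectrum, cage migration events,
anisotropic maps, drift from stage creep). Passing tests on these fixtures
validates the estimators, not the biology; the simulator itself is the
bridge to mechanism.

## Known limitations

* The fitted "initial" MSD exponent at 60 Hz sampling does not reach 1 for
  realistically calibrated drag: with positional relaxation of a few tenths
  of a second, the log-log slope over the first half second is already bent
  to ≈ 0.7 (and ≈ 0.8 over the first 0.1 s), because the fast modes
  contributed by taut tethers decorrelate within a frame or two. A truly
  diffusive initial window is resolvable only at sub-frame sampling. This is
  a property of confined dynamics sampled at 60 Hz, not of the integrator.
* At the default 33 s window the long-time exponent for dynamically binding
  tethers is heavy-tailed across runs (a window either catches a late cage
  migration or it does not); ensemble averaging over 6 particles leaves
  visible run-set-to-run-set spread. Longer observation or larger ensembles
  stabilise it.
* Rotation, hydrodynamic wall corrections as functions of gap height, DLVO
  surface forces, EPS production dynamics and motile propulsion are excluded
  by design.

## Problem sizes used by the test suite

The suite exercises full-scale study conditions where they are the point
(33 s / 60 Hz runs, ensembles of 6–7 particles, the five-force sweep with six
seeds per force) and small configurations elsewhere (2 s structural runs, a
200 s pre-tensioned equipartition run at 500 Hz sampling with
`effective_drag_factor = 1`). The complete suite runs in a few minutes on one
CPU.

```{r example}
library(retether)

# non-detachable control: the 33 nm amplitude level
traj <- simulate_tpm(sim_config(seed = 1, tether_adhesion_force = Inf))
vibration_amplitude(traj)

# dynamic tethers at the default adhesion force: confined displacement
trajs <- lapply(1:6, function(s) simulate_tpm(sim_config(seed = s)))
fit_power_law(msd_ensemble(trajs), t_min = 5)
```
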