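---
title: "Centralized oscillator–satellite networks for marker trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centralized oscillator–satellite networks for marker trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocapnet)
```

## The model

Human movement recorded by optical motion capture is strongly rhythmic:
most marker coordinates are superpositions of a few periodic components
(gait cadence, arm swing, a slower whole-body mode). `mocapnet` models a
set of marker trajectories with a *centralized network*: a small number
`n` of oscillator **centers** with states $q_i(t)$ drive a large number
$N_m$ of **satellite** units, and each output channel (one marker
coordinate) is a weighted sum of the satellite responses,

$$x_k(t) = \sum_{j=1}^{N_m} W_{kj}\,\Phi_j(q(t)).$$

There are no satellite–satellite connections; the architecture is a
star around the centers, which is what makes learning tractable: the
only nonlinear parameters are the $n$ center frequencies, and for fixed
frequencies the weights $W$ solve an ordinary linear least-squares
problem.

Centers come in two flavours:

* **harmonic**: $\ddot q_i + \omega_i^2 q_i = 0$, evaluated in closed
  form as $q_i(t) = \sin(\omega_i t)$. The initial condition
  $q_i(0) = 0$, $p_i(0) = p_0$ pins the phase at the time origin; we set
  $p_0 = \omega_i$ so the amplitude is exactly 1. Neither choice loses
  generality — amplitude is absorbed by $W$, and the phase convention is
  part of the model class (see *Limitations*).
* **nonlinear**: $\ddot q_i + z_c f(q_i) = 0$ with $f(q) = \sin q$
  (pendulum) or $f(q) = aq - bq^3$ (Duffing). These make the frequency a
  continuous function of a single control parameter $z_c$, which is what
  the switching module manipulates. The orbit energy
  $E = p^2/2 + F(q, z_c)$ is conserved and serves as an integration
  diagnostic; `oscillation_frequency()` measures $\omega(z_c, p_0)$
  numerically.

Satellite bases (`basis_config()`): Gaussian radial units
$\exp(-b^2|q-\bar q^{(j)}|^2/2)$ (the workhorse; local, so sharp motion
transitions stay local in the fit), a cosine family
$\cos(b_j \langle q,u\rangle)$ with $b_j = (j-1)\pi/x_0$ — the cosine
series on $[-x_0, x_0]$, whose first member is the constant term so
channel offsets are representable — and scalar monomials $q^{j-1}$ for
$n = 1$. Because every cosine unit is an even function of the projected
state, the cosine family can only represent even functions of $q$; data
with odd symmetry in $q$ (e.g. a channel equal to $q$ itself) are
outside its span, which is why the radial family is the default.

## Fitting

Given frames $t_1 \dots t_K$ and a candidate frequency vector $\omega$,
the fit is: evaluate the centers, place the radial centers *on the
center trajectory* at $N_m$ equally spaced frames, set the sharpness to
the reciprocal median nearest-neighbour distance of those centers,
build the $K \times N_m$ design, and solve for the weights. Quality is
scored per marker $k$ by the **integral relative accuracy**: with
per-axis squared errors $\epsilon_X^2 = \sum_m (X_k(t_m) -
\hat x_k(t_m))^2$ normalized by the raw second moments
$\sum_m X_k(t_m)^2$,

$$\epsilon_{r,k}^2(\omega) = \tfrac13\left(\epsilon_{r,X}^2 +
\epsilon_{r,Y}^2 + \epsilon_{r,Z}^2\right),$$

reported both squared (`eps_r2`) and as the root (`eps_r`). The
denominators are deliberately uncentered — a large constant offset
makes relative errors look smaller — so the reports also carry the
absolute error (mean per-frame Euclidean distance, in input units).

The frequencies themselves come from minimizing
$\epsilon_{r,k}^2(\omega)$: exhaustively over a uniform Hz grid for
$n \le 2$ (all non-decreasing tuples; ties resolve to the
lexicographically smallest), or by seeded uniform random search for
$n \ge 3$. The default grid, 0.05–5 Hz in 0.01 Hz steps, covers the
slow trunk modes (~0.3 Hz) and faster limb modes (~0.7 Hz and up)
typical of whole-body motion at the grid's resolution. A key practical
property is *transfer*: frequencies learned from one marker serve every
marker driven by the same centers after a cheap weight-only refit
(`transfer_fit()`), so the expensive search runs once per motion, not
once per marker.

Complex motions are handled piecewise (`fit_segmented()`): frame
boundaries are an *input* (segmenting algorithms are out of scope),
segments are `[T_i, T_{i+1})` with the last closed, and each segment is
fit independently with its own time origin. No continuity is enforced
across seams; the seam report measures the predicted inter-frame jump
instead, so smoothness is observed, not imposed.

Model size is chosen by the small-sample corrected Akaike criterion,
$AICc = n\ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)$, with $k$ counting every
fitted weight plus the searched frequencies and $n = 3K$ residuals per
marker (`model_scan()` tabulates centers × satellites and returns the
minimizer).

## The switching module

To store several motions in one network, a separate distar subsystem
selects which parameter set $(\omega(z), W(z))$ the generating network
plays. One hub $z$ and $m$ satellites $\tilde w_i$ evolve as

$$\dot{\tilde w}_i = \sigma(\tilde b_i z - \tilde h_i) -
\kappa^{-1}\tilde w_i,\qquad
\dot z = \sigma\!\left(\kappa^{-1}\textstyle\sum_j \tilde a_j \tilde w_j
- h\right) - \xi\bar\lambda z,$$

with the decay term outside the hub sigmoid — that placement is what
lets the control parameter $\xi$ tilt the decay line and prune rest
points. After the fast satellites equilibrate
($\tilde w_i \to \kappa\sigma(\tilde b_i z - \tilde h_i)$), the hub sees
a sigmoid of a *staircase* in $z$ crossed by the line $\xi\bar\lambda z$:
plateau crossings are stable rest points, rising-edge crossings are
unstable. `construct_switch(m, beta, kappa)` builds this concretely —
sharp satellite sigmoids (gain 50) stepping at $z = i - 1 + \beta/2$,
equal hub gains with a centered hub threshold so plateau heights are
nearly linear in the step index — and then *calibrates numerically*: it
scans $\xi$, verifies with `find_rest_points()` (dense scalar scan,
bisection, finite-difference Jacobian of the full system) that exactly
$m$ stable hyperbolic points lie in the prescribed intervals
$(j-1+\beta,\ j+\beta)$, and also finds a larger $\xi$ at which exactly
one stable point survives. The multistability claim is thus verified
computationally on every constructed module rather than assumed.

`motion_library()` + `run_global_model()` close the loop: each stable
hub value anchors a stored motion; a schedule of $\xi$ pulses moves the
hub between basins (small $\xi$ drives it up, large $\xi$ resets it
down), and after each settling the generating network plays the nearest
anchor's motion. Transitions are instantaneous re-parameterizations —
no blending is attempted — and the oscillators never feed back on the
switch.

## The synthetic generator

All quantitative claims are exercised on synthetic ground truth
(`synth_spec()` → `generate_model()` → `generate_trajectory()`): the
generator *is* the model class — harmonic centers at known frequencies,
radial centers placed on the true center trajectory, i.i.d. standard
normal weights rescaled so every channel has unit amplitude
$(\max-\min)/2 = 1$ — sampled at 120 Hz for 10 s (K = 1200) by default,
with optional i.i.d. Gaussian observation noise scaled to each
channel's amplitude, and optional segment plans with independent
frequency vectors per segment. Defaults mirror the scale of real
capture sessions (multi-second segments at 120 Hz, sub-Hz to ~1.5 Hz
rhythmic content). Everything is bit-reproducible from the seed, and
the generator restores the caller's RNG state.

What the generator does *not* emulate — and therefore what passing
recovery tests do not show about real data: skeletal constraints and
inter-marker correlation, soft-tissue artefact, gaps/occlusions,
non-stationary frequency drift within a segment, and non-Gaussian
noise. Recovery results here certify the estimation machinery, not
biomechanical realism.

## Numerical choices

* Weights: SVD minimum-norm solution at `ridge = 0` (rank cutoff
  $10^{-12}$ of the leading singular value, so rank-deficient designs
  are deterministic); during frequency searches a tiny relative ridge,
  $10^{-10}$ of the mean Gram diagonal, stabilizes nearly collinear
  radial columns without visible bias.
* The search loop (design build + solve per candidate, ~2·10⁴
  candidates for a two-center grid) runs in compiled code; the R
  functions are the reference path and the test suite asserts the two
  agree. Search ties within a $10^{-12}$ relative band resolve to the
  lexicographically smallest frequency tuple; reported frequency
  vectors are sorted ascending (center permutation symmetry).
* Integration: adaptive Dormand–Prince 4(5) (`deSolve::ode45`) with
  `rtol = 1e-9`, `atol = 1e-12` for center trajectories; energy drift
  over ten pendulum periods stays below $10^{-6}$ relative. Period
  detection uses `lsodar`'s built-in root finding on $q = 0$ with
  $p > 0$, which locates the return time to integrator precision and is
  independent of any output sampling grid (we chose this over
  interpolating a fixed grid for exactly that invariance).
* Rest points: reduced scalar scan on 4000 grid points over
  $(-0.5, m+1.5)$, bisection refinement to $10^{-13}$, forward
  differences with step $10^{-7}$ of state scale for the Jacobian,
  hyperbolicity asserted as $|\mathrm{Re}\,\lambda| > 10^{-6}$.
* Frequencies are rad/s internally; user-facing values are Hz
  (`hz()`/`rad_s()`).

## Design choices that were genuinely open

* **Phase pinning.** The basis sees only the center positions $q$, not
  the momenta, and $q(0) = 0$ at the fit's time origin. A generic shift
  of the time origin therefore changes which time functions are
  representable (for $n = 1$, an odd-in-$q$ target sampled off-phase has
  no exact representation), so fits are only invariant to time shifts
  by whole common periods — the test suite asserts exactly that, not
  generic-shift invariance, and `fit_segmented()` restarts the phase at
  every segment.
* **Center placement.** Radial centers sit on the actual center
  trajectory at equispaced frames (deduplicated), which guarantees
  every radial unit is active somewhere on the data and makes fits
  deterministic. The cost: a trajectory that revisits states (one
  center, whole periods) yields near-duplicate centers and a very
  sharp default bandwidth; explicit `centers`/`b` overrides exist for
  such cases.
* **Intercept.** The radial design appends a constant column by
  default (switchable): the Gaussian units decay to zero far from
  their centers, so channel offsets would otherwise contaminate every
  weight.
* **AICc bookkeeping.** $k$ counts all fitted weights plus the $n$
  searched frequencies. One can argue satellites should count once
  across channels; we count per channel, which penalizes satellite
  count more strongly and is stated explicitly so scans are
  comparable.
* **Problem sizes in the checks.** The acceptance computations use the
  generator defaults (K = 1200, $N_m$ = 25–30, 20 seeded replicates for
  the stochastic claims, grid 0.05–2 Hz × 0.01 Hz), chosen as the
  smallest sizes at which the studied effects are unambiguous.

## Limitations

* Centers are uncoupled; synchronization phenomena between oscillators
  are out of scope, as are stochastic center dynamics.
* Segment boundaries must be supplied; no automatic segmentation.
* The cosine basis is limited to even functions of the projected state
  (see above); the monomial basis to scalar centers.
* Missing markers are not imputed — readers reject files with gaps.
* Relative accuracies inherit the offset sensitivity of their
  uncentered denominators; compare `abs_err` across coordinate frames.
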