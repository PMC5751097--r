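# mocapnet

Centralized oscillator–satellite networks for motion-capture marker
trajectories.

## The problem

Optical motion capture produces long 3-D trajectories for dozens of
markers, yet the underlying movement is low-dimensional and rhythmic.
`mocapnet` is for researchers in movement science, animation, and
robotics who want a *compact, generative* representation of such data:
a network with a few oscillator **centers** driving many **satellite**
units, in the spirit of central pattern generators. Each output channel
(marker coordinate) is

```
x_k(t) = Σ_j W_kj Φ_j(q(t)),      q_i(t) = sin(ω_i t)  (harmonic centers)
```

where the Φ_j are Gaussian radial basis functions of the center-state
vector (cosine and monomial families are also available). Learning
splits into a hard-but-tiny part — the n center frequencies ω, found by
exhaustive grid search for n ≤ 2 or seeded random search for n ≥ 3,
minimizing the per-marker *integral relative accuracy*

```
ε²_{r,k}(ω) = ( ε²_{r,X} + ε²_{r,Y} + ε²_{r,Z} ) / 3,
ε²_{r,X} = Σ_m (X_k(t_m) − x_k(t_m))² / Σ_m X_k(t_m)²
```

— and an easy-but-large part, the weights W, which are plain linear
least squares. Frequencies learned on one marker transfer to all
markers of the same motion by a weight-only refit. Segmented motions
are fit piecewise with per-segment frequencies; model size (centers ×
satellites) is selected by small-sample-corrected AIC. A multistable
*switching module* — one hub, m satellites, sigmoid interactions —
stores m motions as stable rest points of an ODE and toggles the
generating network between them via a single control parameter.

## Worked example

```r
library(mocapnet)

# synthetic ground truth: 2 centers at 0.5 / 1.3 Hz, 25 satellites,
# 2 markers, 10 s at 120 Hz
spec <- synth_spec(n = 2, freqs_hz = c(0.5, 1.3), n_m = 25,
                   markers = 2, seed = 42)
g <- synth_motion(spec)
g$trajectory
#> <marker_trajectory> 2 markers, 1200 frames @ 120 Hz (9.99 s), units: unit

# exhaustive frequency search on one marker
fit <- search_frequencies(g$trajectory, "marker1", n = 2,
                          search = search_grid(0.05, 2, 0.01), n_m = 25)
fit
#> <fit_result> marker marker1: f* = 0.5/1.3 Hz, eps_r = 5.013e-10 (19306 candidates)

# transfer the learned frequencies to every marker (weight-only refit)
model <- transfer_fit(fit, g$trajectory)
model$report[, c("marker", "eps_r", "abs_err")]
#>    marker        eps_r      abs_err
#> 1 marker1 5.012524e-10 1.204087e-10
#> 2 marker2 4.744546e-10 8.788577e-11
```

The search recovers both generating frequencies exactly (to the grid
step) and the relative error `eps_r` is at numerical-noise level, as it
must be for data generated by the model class itself; `abs_err` is the
mean per-frame Euclidean error in input units. A switching module with
three stored motions:

```r
sw <- construct_switch(m = 3, beta = 0.5, kappa = 0.05)
find_rest_points(sw$module)
#> <rest_point_report> xi = 0.261092: 5 rest point(s), 3 stable
#>   stable points:
#>      z  max_re  residual
#>  1.030 -0.2609 5.551e-17
#>  1.915 -0.2611 1.110e-16
#>  2.800 -0.2611 1.110e-16
```

Exactly three stable hyperbolic rest points, one per unit interval
(j − ½, j + ½) — each can anchor a stored motion via `motion_library()`
and `run_global_model()`.

A command-line interface wraps the same functions
(`inst/cli/mocapnet`, or `motion_cli()` in-process): subcommands
`synth`, `fit`, `predict`, `evaluate`, `scan`, `switch-demo`, operating
on a flat marker CSV dialect (`frame,time_s,<marker>_x,_y,_z,...`), TRC
files (read-only), and a JSON model file.

See the vignette (`vignettes/centralized-motion-networks.Rmd`) for the
model, its assumptions, and the numerical choices.

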