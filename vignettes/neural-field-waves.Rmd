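---
title: "Propagating waves in a refractory neural field: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating waves in a refractory neural field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`nfwaves` simulates and analyzes a two-variable neural field with
refractoriness on a periodic two-dimensional domain. At each position the
coarse-grained state is the probability `f` that local neurons are firing
and the probability `h` that they are resting-depleted (refractory neurons
make up the remainder, by normalization). In time rescaled by the membrane
constant τ the dynamics are

    df/dt = -f + (1 - f - h) H(u - κ)
    dh/dt = -p h + f

where `H` is the Heaviside step (with `H(0) = 1`), κ is the firing
threshold on the synaptic input `u = w * f` (a spatial convolution), and
`p` is the refractory recovery rate — the nonlinear negative feedback that
lets localized activity travel instead of spreading.

The coupling function is a Mexican hat built from modified Bessel
functions,

    w(r) = W_E wK(r/σ_E) - W_I wK(r/σ_I),   wK(r) = (2/3π)[K0(r) - K0(2r)],

with short-range excitation (scale σ_E) and longer-range inhibition
(σ_I). At `r = 0` the Bessel difference has the finite limit `ln 2`, which
the implementation uses directly rather than evaluating `K0` at zero. The
kernel's single sign change at radius `r0` splits the plane into an
excitatory disc and an inhibitory annulus; the signed integrals over those
regions, `g_plus > 0` and `g_minus < 0`, are the model's scalar
excitation/inhibition coordinates. Four kernel parameters map onto two
coordinates, so `invert_ei()` returns *one feasible* kernel per target,
found by exploiting that `g_±` are linear in the coupling strengths at
fixed spatial scales: a one-dimensional root-find in the strength ratio
matches the `g_plus/|g_minus|` ratio, a scale factor then matches the
magnitudes, and candidate spatial scales are multi-started from a seeded
Latin hypercube.

## Semi-analytic solutions

**Bumps.** A stationary radially symmetric bump has constant interior
values `f = p/(1+2p)`, `h = 1/(1+2p)` — an exact fixed point of the
dynamics with the firing indicator active. Its radius solves a threshold
condition at the boundary, implemented exactly as the residual
`f_in [ I(ρ) - 2κ ] - κ` where `I(ρ)` is the kernel integrated over the
bump disc at a boundary point. Note the `-2κ` term: the residual vanishes
where the raw boundary input `u(ρ) = f_in I(ρ)` crosses the *effective*
level `u* = κ(1+4p)/(1+2p)`, not κ itself. We did not re-derive this
constant offset from the two-variable dynamics; it is retained as printed
in the source derivation, exposed through attributes `u` and `u_star` of
`bump_existence_residual()`, and every root/crossing consistency is tested
against the same convention. Because the boundary-input curve is concave
there are at most two radii: the smaller is unstable (a perturbation
collapses or inflates it), the larger is stable against radial
perturbations but can be unstable to translation.

**Shift instability.** The growth rate of a translation perturbation is
estimated by direct simulation: the rasterized bump is displaced by a
sub-grid spectral shift (0.2–0.4 cells), integrated noise-free, and the
center-of-mass displacement is fitted log-linearly over the window where
it grows from 0.01 to 1 grid cells. This transparent estimator reproduces
the sign and ordering of the instability (weaker inhibition → faster
drift) without a linearized eigenproblem, whose published form we did not
reproduce. At desk-scale parameters, note, small bumps near strong
inhibition can be genuinely stable — grid pinning also suppresses drift
below a threshold on coarse grids, which is why the regime reference
points below use 0.5-unit spacing.

**1D traveling waves.** In the comoving frame the active stretch
`[-L, 0]` of a wave moving at speed `c` obeys the linear system
`-c F' = -2F - H + 1`, `-c H' = F - p H`, whose solution through
`F(0) = H(0) = 0` is a damped oscillation about the interior fixed point
with decay `α = (2+p)/2` and frequency `β = sqrt(p(4-p))/2` (requiring
`p < 4`). Two sign conventions matter and are worth stating because they
are easy to get wrong: with mixing coefficients
`A = (2-α+1/p)/β` and `B = {α-2-p[(α-2)²+β²]}/β` the sine terms enter
with a **plus** sign, `1 - e^{αx/c}[cos(βx/c) + A sin(βx/c)]`; and behind
the wave the recovery tail is
`H = (H(-L) + F(-L)/(1-p)) e^{p(x+L)/c} - F(-L)/(1-p) e^{(x+L)/c}`,
which decays to quiescence far behind the wave. Both choices are the
unique ones satisfying the comoving equations (the identity
`f_in(α - Aβ) = 1`, equivalent to `F'(0) = -1/c`, pins the first; decay
at `-∞` pins the second), and the test suite checks the ODE residuals of
the implemented profile to 1e-5.

The pair `(c, L)` is then fixed by requiring the synaptic input to equal κ
at both boundaries, `u(0) = u(-L) = κ`, with the kernel evaluated on the
line (`w(|x|)`: the 1D field is genuinely one-dimensional — a *planar*
wave of the 2D field would integrate the kernel transversally and is
inhibition-dominated to the point of never reaching threshold).
`solve_wave1d()` minimizes the summed squared boundary residuals by
Nelder-Mead over `(log c, log L)` from a seeded Latin-hypercube
multi-start on `c ∈ (0.1, 50)`, `L ∈ (0.1, 30)`, accepts minima below
`1e-10 κ²`, deduplicates them and returns them sorted with the fastest,
longest wave last. Degenerate near-stationary minima (`c → 0`) exist and
are reported alongside the genuine wave. Existence requires a
near-balanced line integral of the kernel (`f_in ∫w < κ`, else the active
region never terminates): the reference kernel scaled to
`W_E = 288.8, W_I = 176.88` satisfies this at `p = 0.3` and yields
`c ≈ 1.113`, `L ≈ 6.96` in field units, confirmed by a 1024-site periodic
line simulation at 0.25-unit spacing to within 5%.

**2D teardrop waves.** The boundary of a 2D traveling wave is
parametrized in polar coordinates by an elliptical front
(`θ ≤ π/2`, half-length `L_f`, half-width `L_w`) and a tail branch
`L_w - L_a[1 - 1/(1 - L_b cos²θ)]` with curvature parameters `L_a`,
`0 < L_b < 1`. The printed tail-length relation
`L_t = L_w + L_a L_b/(1-L_b²)` does not equal the actual boundary radius
at `θ = π`, which is `L_w + L_a L_b/(1-L_b)`; both are carried on the
shape object (`L_t` and `tail_reach`) and only the latter is used
geometrically. The interior is filled chord-by-chord with the 1D profile
using the local chord length, and `fit_wave2d()` adjusts the five
parameters so the synaptic input along 64 boundary angles matches κ, by a
deterministic compass (pattern) search over a log/logit reparametrization
with seeded multi-starts.

Two numerical choices here deviate from the plainest construction, for
measured reasons. First, the fit rasterizes candidate states with `s × s`
sub-cell averaging (`supersample = 4`): the kernel's central peak is a
couple of cells wide, so nearest-grid-point rasterization makes single
boundary cells perturb `u` at nearby boundary points by O(0.5 κ),
swamping the residual. Second, the fit includes the exponential recovery
tail behind the parametric boundary (`include_tail = TRUE`): the decaying
activity there contributes order-one input at the tail boundary, without
which the threshold condition is unsatisfiable there (the default build
remains exactly zero outside the boundary, which is what the simulator's
initial conditions use). Even so, at desk resolution the family bottoms
out around 0.15–0.3 κ maximum boundary deviation — the corner where the
front ellipse meets the tail is a curvature discontinuity the true wave
does not have — so `fit_wave2d()` flags convergence against a 0.05 κ
target but always returns the best shape with its residual. Fitted shapes
still seed simulations that keep speed within 10%.

## Direct simulation

`simulate_field()` integrates the two equations with classical RK4 and
FFT circular convolution on the periodic square lattice. The kernel is
sampled with per-cell 4-point Gauss–Legendre integration
(`kernel_grid(cell_average = TRUE)`), not midpoint sampling: the
excitation/inhibition near-cancellation that wave solutions live on is
misrepresented by midpoint sampling at the reference resolution (a
measured factor-6 error in boundary inputs on a line at unit spacing).
Defaults mirror the reference setup — 601×601 cells, one field unit
(0.1 mm) spacing, `dt = 0.01` rescaled (0.1 ms at τ = 10 ms), κ = 1,
`p = 0.42` — while tests and the desk-scale reference points run 128×128.

Noise is multiplicative, `μ = f ξ` with `ξ` i.i.d. zero-mean Gaussian per
cell, added to `df/dt` and subtracted from `dh/dt`, drawn once per step
and held fixed across the four RK4 stages. It is deliberately *not*
Euler–Maruyama-rescaled by `1/√dt`; σ_ξ values are therefore tied to the
fixed `dt = 0.01`, matching the plain additive formulation of the source
model. Probabilistic bounds (`f, h ≥ 0`, `f + h ≤ 1`) are restored by
clamping after each step and clamp events are counted in the run log. The
single-kick mode applies one i.i.d. Gaussian perturbation to `f` at start,
which is how the phase-portrait transients are generated.

Because the firing rule is a hard threshold, the moving front is not
smooth in time: halving `dt` at a region-II point changes the field after
10 ms by ≈6e-5 RMS (front-cell switching times, not RK4 order, limit the
agreement); the suite asserts < 1e-4.

## Tracking and regimes

Patterns are connected components of `{f > 0.5 f_in}` under wrap-aware
8-connectivity (components under 4 cells discarded); centers of mass are
`f`-weighted circular means per axis, exact for blobs wrapped across the
periodic seam. Identities link frame to frame by nearest periodic
distance. Velocities are central differences of the unwrapped path
smoothed by a 10-point moving average; accelerations are differences of
the smoothed velocities; norms are taken last.

Sliding 20 ms windows (50% overlap) are labelled *bump*
(`v_tot < v_eps`), *traveling* (moving, `a_tot < a_eps`) or *rotating*
(both above threshold and near-constant, relative SD < 25%). The source
analysis gives no numeric thresholds; we use
`v_eps = 0.5 spacing` per rescaled time unit (0.05 cells/ms at τ = 10 ms)
and `a_eps = v_eps/2` per rescaled time, both configurable. Movie-level
regimes: *III* when the pattern count grows by splitting after the 50 ms
transient, *IV* when a component covers > 25% of the domain or spans it,
else *I*/*II* by majority vote of the window labels (a stationary outcome
is reported as `"bump"` rather than forced into I–IV; it can occur at
desk scale where grid pinning stabilizes marginal bumps). Dwell-time
segmentation of the label series gives mean lifetimes per state and the
transition count for noise-switching analysis.

**Desk-scale reference points.** The full 601×601 multi-second sweeps are
not reproducible interactively, so `regime_point()` pins one kernel
family — `σ_E = 4`, `σ_I = 6.93` (the reference kernel's scale ratio),
`W_E = 40`, on a 128-cell grid at 0.5-unit spacing — whose inhibition
ratio `q = W_I/W_E` traverses the regimes in the same direction the full
model does as `|g_minus|` falls: `q = 0.58` rotating (I), `0.52`
traveling (II), `0.45` splitting (III), with the rotating/traveling
bistable point at `q = 0.54`. These values were chosen once, by mapping
bump radii and seeded-wave behavior across the `(W_E, q, σ)` family until
all three single-wave regimes appeared at a pattern size (bump radius
5–10 field units) that fits the 64-unit domain; at the bistable point a
noise-free run travels indefinitely while σ_ξ = 0.2 drives repeated
switching between rotating and traveling labels, and σ_ξ = 0.01 drives
none. Waves are nucleated by `seed_wave_state()`: a bump-sized teardrop
whose refractory field is shifted transversally by one field unit —
without that bias a marginal wave stalls back into a symmetric bump.

## Fluctuation statistics

The kinematic statistics operate on per-pattern velocity series:

* `periodogram()` — Hann window, one-sided DFT power, coefficients
  normalized to unit sum (DC excluded).
* `spectral_dof()` — `(ΣS)²/(N ΣS²)`, which is 1 for a flat spectrum of
  any length and `1/N` for a single-bin spectrum. The printed form of
  this statistic in the source places `N` in the numerator, which would
  give `N²` in the flat case; the implemented form is the one consistent
  with both stated limiting values.
* `approx_entropy()` — Pincus ApEn with self-matches and natural logs;
  defaults `m = 2`, `r = 0.2 sd` (the standard convention; the source
  states none). ApEn rises then falls with `r`; monotone decrease holds
  past the matching peak, which is what the suite asserts.
* `dfa()` — integrate-and-demean, non-overlapping boxes from the series
  start (trailing remainder dropped), per-box linear detrend, RMS
  fluctuation, and a log-log slope over ~20 log-spaced box sizes from 10
  to N/4 with the two smallest sizes excluded from the fit (small-n
  bias). No reversed-pass variant. Calibration on `make_reference_noise()`
  series of length 2^14 recovers 0.5 (white), 1.5 (Brownian) and 1.0
  (spectrally shaped 1/f) within the estimator's spread; the acceptance
  script averages 20 seeds.

## Spatiotemporal spectra

`spatiotemporal_spectrum()` takes the 3D DFT of `f(x, y, t)` with a Hann
window along time only (space is periodic), squares the modulus, folds
±temporal frequencies, and averages the two spatial axes over annuli one
frequency cell wide using bin *means* (sums would re-introduce
annulus-area bias). A rigidly translating pattern concentrates power on
the line `v f + ω = 0`, so `velocity_power_profile()` sums, for each
candidate speed, the linear interpolation of the spectrum at
`f = ω/v` over ω > 0 (the static `ω = 0` row is excluded), revealing the
distribution of propagation speeds; the default grid is 100 log-spaced
speeds across the resolvable range. The analyzed signal is `f` itself,
not a thresholded mask.

## Scope and limitations

* The synthetic regimes are single- or few-wave desk-scale analogues; the
  601×601 collective runs with seven interacting waves are supported by
  the same code (`make_initial("random_waves")`) but are not exercised in
  the test suite for time reasons. Problem sizes used by the tests:
  128×128 grids, ≤ 1 s simulated time, 1024-site lines.
* Ordering claims (DoF rising as inhibition falls, rotating lifetimes
  exceeding traveling ones) are phenomena of the full collective runs;
  the suite verifies the mechanisms (classification, dwell segmentation,
  switching) on scaled runs rather than asserting the collective numbers.
* No Evans-function or spectral stability machinery; no stable-bump
  regime at small `p`; Bessel kernels only; square periodic domains only.
* Movies persist as RDS containers with full configuration and seed
  attached; tables as CSV; manifests as JSON. Every stage's randomness
  descends deterministically from one global seed via a fixed splitting
  rule, so stages can be re-run independently.
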