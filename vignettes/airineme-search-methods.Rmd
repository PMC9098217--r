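---
title: "Modelling airineme target search as a finite persistent random walk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling airineme target search as a finite persistent random walk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prwsearch)
```

## The model

Airinemes are long, thin signalling protrusions that undifferentiated
zebrafish pigment cells (xanthoblasts) extend across the skin. A macrophage
drags the airineme tip through the tissue until it either touches a target
melanophore — establishing Delta–Notch signalling — or the airineme reaches
its maximum length and retracts. `prwsearch` models this search as a
**finite-length persistent random walk (PRW)**: the tip moves at constant
speed $v$ while its heading $\theta(t)$ diffuses,

$$
\frac{dx}{dt} = v\cos\theta, \qquad
\frac{dy}{dt} = v\sin\theta, \qquad
d\theta = \sqrt{2D_\theta}\,dW_t ,
$$

with angular diffusion coefficient $D_\theta$ (rad$^2$/min). $D_\theta$
interpolates between straight, ballistic searches ($D_\theta \to 0$) and
locally thorough but short-ranged diffusive searches ($D_\theta$ large,
equivalent to Brownian motion with $D = v^2/2D_\theta$). Equivalently the
path is a worm-like chain with persistence length $l_p = v/2D_\theta$; the
tangent autocorrelation decays as
$\langle\cos\theta(s)\rangle = e^{-D_\theta s/v}$ along arc length $s$.

The target cell is an absorbing disk of radius $r_{targ}$ at the origin;
the source sits on the positive $x$-axis at distance $r_{targ} + d_{targ}$
from the centre (so `dtarg` is the gap from the source to the target
*surface* — the convention under which the ballistic limit below is exact).
The initial heading is uniform on $(-\pi,\pi]$; the search ends at first
contact or at contour length $l_{max}$. The source cell is not an obstacle
(searches may pass over it), airinemes act independently, and the tissue is
treated as an unobstructed plane.

### Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `v` | tip speed | 4.5 | µm/min |
| `dtheta` | angular diffusion | 0.1838 | rad²/min |
| `lmax` | maximum contour length | 250 | µm |
| `dtarg` | source-to-surface gap | 50 | µm |
| `rtarg` | target radius | 25 | µm |
| `dt` | integration step | 0.1 | min |

The defaults are the measured airineme values; `dtheta` is the
maximum-likelihood estimate from digitized airineme shapes (persistence
length 12.24 µm). Two guards protect the discretisation: `v*dt <= rtarg/10`
(a step cannot tunnel past the target — contact additionally tests the
swept segment, making the contact probability robust in `dt`) and
`dtheta*dt <= 0.05` (the heading update resolves the angular diffusion).
High-curvature sweeps refine `dt` automatically.

The initiation rate of 0.15 airinemes per cell per hour gives a mean wait
of 400 min between searches, against an extension time of
$l_{max}/v \approx 56$ min (`search_timescales()`), which is what justifies
modelling searches one at a time.

## Numerical scheme

Trajectories are integrated by explicit Euler–Maruyama in compiled code:
each step displaces by exactly `v*dt` along the current heading, then
advances the heading by $\sqrt{2D_\theta\,\Delta t}\,Z$. Contact is the
first intersection of the swept segment with the disk, found from the
quadratic for the segment–circle crossing; the contact point, time, and
polar angle (source direction $= 0$, counterclockwise positive) are
recorded at the crossing itself, not at the next frame.

Randomness comes from R's RNG, so `set.seed()`-style seeds make every
ensemble bit-reproducible. Each ensemble consumes one stream sequentially
across its trajectories; sweeps derive an independent sub-seed per grid
point from the root seed, so grid points are independent and the sweep is
reproducible as a whole. (Per-trajectory counter substreams were considered
and rejected: R exposes no cheap counter-based RNG, and reseeding per
trajectory costs more than simulating it.)

### Analytic validation limits

Two limits anchor the simulator:

* **Ballistic** ($D_\theta = 0$): a ray hits the disk iff its direction
  falls in the cone subtended by the target, so
  $p = \big(\tfrac{\pi}{2} - \arccos\tfrac{r_{targ}}{r_{targ}+d_{targ}}\big)/\pi$
  (`ballistic_contact_probability()`). Simulated ballistic ensembles agree
  within Monte-Carlo error.
* **Diffusive** ($l_p \ll d_{targ}$): the PRW behaves as Brownian motion
  with $D = v^2/2D_\theta$ over the finite time $l_{max}/v$, and the
  contact probability is $1 - S(r_0, t)$ where the survival probability
  solves $\partial_t S = D\nabla^2 S$ with $S = 0$ on the target surface.
  `diffusive_contact_probability()` solves the radial problem by
  Crank–Nicolson on a uniform grid (600 nodes, 1200 steps by default;
  halving both changes the result by under $10^{-3}$), with a reflecting
  outer boundary placed four diffusion lengths beyond the start so it
  cannot influence the absorbed mass. The solver was checked against
  direct Brownian simulation (it agrees to three decimals). The PRW itself
  converges to this limit only gradually: at $D_\theta = 2$ (lp = 1.1 µm)
  the simulated probability still sits a relative ~25% below the PDE value
  because the first persistence length of ballistic motion is missing from
  the pure-diffusion picture; by $D_\theta = 4$ the two agree within
  Monte-Carlo error at $n = 2\times10^4$. Validation tests therefore use
  $D_\theta \ge 4$ for this comparison.

The closed-form PRW mean squared displacement
$\langle r^2\rangle = 4 l_p v t\left(1 - \tfrac{2l_p}{vt}\left(1 -
e^{-vt/2l_p}\right)\right)$ (`msd_prw()`) provides a third, independent
check at intermediate curvature.

## Estimators

All estimators consume a plain trajectory table (`airineme_id`, `frame`,
`t_min`, `x_um`, `y_um`, optional `heading_rad`), the same schema the CSV
interchange uses.

**MSD and power-law fit.** `compute_msd()` averages over all trajectories
and start frames (overlapping windows, the standard convention);
`fit_msd_power_law()` fits $\langle r^2\rangle = \gamma t^\alpha$ by OLS on
log–log axes. The default window (lags ≤ 15 min) covers the near-ballistic
regime seen in airineme data; the window is a parameter, and a single
exponent fitted across the ballistic-diffusive crossover lands strictly
between 1 and 2.

**Step-length CCDF.** `step_length_ccdf()` uses non-overlapping windows
(steps must be independent for the tail diagnostic), and
`fit_ccdf_tail()` fits the upper `tail_fraction` (default 0.3) by OLS on
log–log axes. The reported exponent is the CCDF slope magnitude; the
step-density exponent is one larger. Lévy walks in 2-D have CCDF exponents
in (1, 3); PRW steps at fixed sampling produce exponents well above 3.
Because cumulative points are strongly correlated, the nominal OLS
confidence interval is over-confident — treat it as a display quantity,
and judge tail fits by the point estimate and its sensitivity to
`tail_fraction`.

**Final-angle isotropy.** For growth longer than a few persistence times
($t > 5/D_\theta$) the final-minus-initial heading is uniform on the
circle; `final_angle_isotropy()` applies a Kolmogorov–Smirnov test against
uniformity to trajectories above a duration cutoff (default 15 min).

**Curvature MLE.** Under the discretised model, tangent increments over
arc length $\Delta s$ are independent $N(0,\, 2D_\theta\Delta s/v)$, so

$$
\hat D_\theta = \frac{v}{2N}\sum_i \frac{\Delta\theta_i^2}{\Delta s_i},
\qquad
\mathrm{CI}_{90} = \hat D_\theta\left(1 \pm 1.645\sqrt{2/N}\right),
$$

the exact finite-sample MLE of the increment likelihood
(`mle_dtheta()` on `tangent_autocorrelation()` output). The binned
$\langle\cos\theta(s)\rangle$ curve is still produced for display against
$e^{-D_\theta s/v}$. Two practical subtleties matter and are handled
explicitly:

* *Arc length.* Because airineme shape is frozen once laid down (the part
  of the path existing at time $t$ does not change as the tip extends),
  the arc coordinate of the sample at time $t$ is exactly $v\,t$. Chord
  sums understate arc length on curved paths and would inflate
  $\hat D_\theta$ (by ~2% at the observed curvature, up to ~13% at
  $D_\theta = 0.5$ with 3 µm sampling); supply `v` to
  `tangent_autocorrelation()` to use the exact coordinate.
* *Chord-estimated headings.* Real tracings give positions, not tangents,
  so headings must be estimated as chord directions of consecutive
  displacements. A chord direction is the tangent averaged over its
  window, and consecutive window-averages of a Wiener process have
  increment variance $\tfrac{2}{3}\cdot 2D_\theta\Delta s/v$ — an exact
  factor, confirmed numerically. In chord mode the MLE therefore applies a
  3/2 correction and widens the CI by $\sqrt{9/8}$ for the lag-one
  correlation (coefficient 1/4) that averaging induces. Without the
  correction, chord-based estimates are biased low by a third.

Identifiability limits the usable sampling density: increments with
variance approaching $\pi^2$ wrap around the circle and lose information,
so at $D_\theta = 0.5$ the 22.5 µm spacing of 5-min frames is useless for
the MLE no matter the estimator — only dense contour digitization (a few
µm, the density of manual tracings) recovers high curvatures. The
parameter-recovery tests use 3.15 µm spacing for this reason.

## Directional information

The contact angle $\theta_{contact}$ (polar position of the contact point,
source at angle 0) carries information about the source direction. By
rotational symmetry the conditional density is a location family, so the
Fisher information per contact reduces to
$I_1 = \oint f'(\theta)^2/f(\theta)\, d\theta$.
`contact_angle_distribution()` estimates $f$ by a wrapped-Gaussian kernel
density on a 720-node periodic grid (binned samples, FFT circular
convolution), bandwidth by the circular Silverman rule
$\hat\sigma (4/3n)^{1/5}$ with $\hat\sigma = \sqrt{-2\log \bar R}$, and a
$10^{-6}$ density floor so the ratio $f'^2/f$ stays conditioned where
contacts are absent. Against Gaussian samples of sd $\sigma = 0.1$ the
estimator reproduces $1/\sigma^2$ within a few percent (the KDE bandwidth
adds $\approx bw^2$ to the variance, a ~1% effect at $n = 10^5$). Degree
mode multiplies by $(\pi/180)^2$ exactly.

A target that is never contacted receives no information, so the
**modified Fisher information** weights by contact probability:
$\mathrm{modFI} = I_1 \cdot p_{contact}$. (The alternative reading
$I_1 \cdot p_{contact}^2$ — treating the information of $n_{hit}$
contacts as itself proportional to $p_{contact}$ and then weighting again —
double-counts contact frequency and is not used.) $I_1$ is large in both
extremes: straight searchers can only hit the near cone, and highly curved
searchers barely reach and touch only the nearest point; at the observed
curvature the contact-angle distribution is widest and $I_1$ is minimal.

The three-point angle protocol used on images (origin point, target
centre, docking site; counterclockwise positive, degrees) is implemented in
`three_point_contact_angle()` and, with a jittered centre emulating the
uncertainty of placing a centre on a noncircular cell, in
`measure_contact_angles_synthetic()`.

## Sweeps, the optimal curvature, and the trade-off

`sweep_contact_probability()` runs an independent ensemble per $D_\theta$
grid point (default 20 log-spaced points on $[0.02, 2]$).
`optimal_dtheta()` refines the empirical argmax by a local quadratic over
5 grid points and reports the vertex, with a parametric-bootstrap CI.

The refinement fits on the **linear** $D_\theta$ axis. This was a genuine
design fork: the contact-probability peak for the airineme geometry is
extremely flat (the probability varies by under 3% for
$D_\theta \in [0.10, 0.20]$) and noticeably skewed when plotted against
$\log D_\theta$. High-precision scans ($5\times10^5$ trajectories per grid
point) put the true argmax at $D_\theta^* \approx 0.137$; a quadratic
vertex computed on the log axis converges to 0.128 regardless of window
size (the skew, not noise, drives it), while the linear-axis vertex
converges to 0.139. The linear-axis fit is therefore the consistent
estimator and is the default. With $10^5$ trajectories per grid point the
estimator's sampling sd is about 0.004.

`optimal_dtheta_map()` repeats this over a geometry grid: far or large
targets favour straighter searches, near or small targets favour diffusive
ones, and for the biologically relevant rectangle (gaps 33–84 µm, radii
15–25 µm) the optimum is the intermediate, balanced regime.

`tradeoff_curve()` evaluates $(p_{contact}, \mathrm{modFI})$ from one
shared ensemble per grid point (common random numbers keep the parametric
curve smooth) and flags Pareto-optimal points by a sort-based dominance
scan (verified against brute force). The curve's shape changes with target
distance: near targets give concave-up "bull's horns" (information high at
both curvature extremes, no interior optimum); intermediate distances bend
the curve into a loop whose concave-down stretch creates an interior
Pareto regime containing the observed curvature; far targets collapse to a
degenerate diagonal where both objectives die together.

## The synthetic-data generator

`generate_dataset()` emulates a digitized live-cell dataset: PRW paths are
simulated at the integration step, the shape is frozen, tip positions are
kept every `imaging_interval` minutes, and isotropic Gaussian position
noise is added. Defaults mirror the airineme study conditions: 70
airinemes, 5-min frames (the acquisition interval), speed 4.5 µm/min,
maximum length 250 µm. Every airineme grows to full length by default
(about 12 frames and 56 min each); an optional `duration_law` truncates
growth. Two sampling densities are relevant: 5-min frames for time-series
statistics (MSD, step CCDF), and ~0.7-min (3.15 µm) spacing emulating the
density of manual contour digitization (~80 points per airineme) for
tangent statistics — dense digitization of 70 airinemes yields a dataset
of about 5600 points, the scale of the real tracings.

What the generator does *not* emulate: tracing errors correlated along the
contour, the hand-off between time frames and final-shape tracing, cell
shape irregularity (the target is an ideal disk), and airineme retraction.
Passing recovery tests on this generator therefore demonstrates estimator
correctness under the model's own assumptions, not robustness to every
artefact of real imaging; the model-convolution renderer exists to probe
part of that gap.

`render_images()` is the forward imaging model for that purpose: paths are
rasterised as unit line flux, convolved with an isotropic Gaussian PSF,
and degraded to a target peak-signal-to-noise ratio. The default pixel
size (0.5 µm), PSF sd (1 µm) and SNR (5) are round placeholder values to
be calibrated per instrument, not measured microscope properties.

## Numerical choices and edge cases

* Wilson score intervals for contact proportions (well-behaved at small
  counts).
* Angles are radians internally, wrapped to $(-\pi,\pi]$; degrees appear
  only at I/O boundaries and in the three-point protocol.
* `dtheta = 0` is a valid ballistic model; the persistence length is then
  reported as infinite with a warning, and an all-straight dataset yields
  a degenerate MLE ($\hat D_\theta = 0$, flagged).
* Zero-contact ensembles raise an error from the density estimator
  (distinct from a legitimate $I_1 = 0$); in trade-off curves such grid
  points are recorded as $(p, \mathrm{modFI}) = (0, 0)$ and flagged.
* A sweep whose argmax lies on the grid edge refuses to refine and asks
  for a wider grid; map cells do this per-cell and are flagged instead of
  failing the map.
* Ensembles, datasets, sweeps and renders are bit-reproducible from
  `(seed, n, params)`; derived sub-seeds keep grid points independent.

## Problem sizes used by the test-suite

The shipped tests validate against theory at sizes chosen to keep
Monte-Carlo error meaningful: $10^5$ trajectories for limit checks
(binomial 3 SE $\approx 0.004$), $10^5$ per grid point for the optimum
(estimator sd $\approx 0.004$), 100 replicate experiments of 70 airinemes
for MLE coverage, and $1$–$3\times10^4$ trajectories per point for
trade-off shape checks. These sizes are the package's reference study
conditions; all are parameters, and larger runs simply tighten the same
comparisons.

## Known limitations

* Two-dimensional, obstacle-free tissue; no retraction dynamics or
  macrophage mechanics.
* The diffusive PDE limit is an approximation controlled by
  $l_p/d_{targ}$; do not use it as a reference below $D_\theta \approx 4$
  for the airineme geometry.
* OLS tail fits report over-confident nominal CIs (correlated cumulative
  points); sensitivity to `tail_fraction` is the honest uncertainty
  handle.
* The contact-probability peak is so flat that any "optimal curvature" is
  effectively a broad plateau; report it with its bootstrap CI, never as a
  sharp value.
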