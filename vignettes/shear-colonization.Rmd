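---
title: "Methods: simulating and analysing bacterial surface colonization under flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing bacterial surface colonization under flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shearcolony)
```

`shearcolony` analyses single-cell time-lapse data of bacteria attached to
a flow-exposed surface: segmentation, trajectory linking, division and
detachment event detection, mean-square-displacement (MSD) phenotyping,
growth-rate decomposition, and a bistable divider-fraction growth model.
Because real microscopy data are large and external, the package is built
around an agent-based generator whose event log is exact ground truth;
every downstream stage can therefore be validated as a measurement of a
known process. This vignette records the model, its assumptions, the
numerical choices, and the design decisions taken where the problem was
genuinely open.

## The colony model

Agents are rigid rods of newborn length 2 µm and width 1 µm on a flat
domain. Each agent carries one of three phenotypes:

* **continuous dividers** elongate linearly from their birth length to
  twice the newborn length with the *anchored* pole fixed, then divide;
* **lagged dividers** behave identically after a fixed initial delay;
* **non-dividers** never divide and jitter both poles with a much smaller
  amplitude (they are anchored at both poles).

At division the mother is replaced by two end-to-end daughters. Each
daughter independently becomes a divider with probability `f`
(`divider_fraction_f`), otherwise a non-divider — the bistable daughter
assignment that drives the population-level behaviour. Non-divider is
absorbing on the simulated horizon (~6 h): whether growth-arrested cells
can resume dividing is not observable within that window, so the model
does not speculate.

### Division clock

Continuous dividers draw a division time

\[ \tau_d = \tau_{\min} + \mathrm{Exp}\!\left(\frac{1}{\bar\tau - \tau_{\min}}\right), \]

an exponential left-truncated at the floor `division_time_floor`
(20 min, the lower edge of the observed support) and parameterized so that
the *realized mean* equals `mean_division_time` (40 min). Truncating an
exponential is the same as shifting it (memorylessness), so the only free
choice is which mean the parameter names: we pin the realized mean,
because that is the quantity the division-time statistics and the growth
model consume. `clock = "fixed"` replaces the draw by its mean —
zero-variance mode, in which a pure-divider colony doubles exactly every
40 min (10 cells become 80 in 120 min).

### Lagged dividers

The lag is modelled as a property of the *initially attached* cohort: a
fraction `lagged_fraction` (default 0.125) of the initial dividers waits
`lagged_delay` before its clock starts; daughters born later are lagged
with probability `daughter_lagged_fraction`, default 0. This is what makes
the per-birth-bin mean division time start high and relax to the
continuous-divider mean as the lagged cohort divides out — the observed
time-resolved behaviour. The delay distribution is unknown; a fixed,
configurable delay is the simplest choice, and its default (260 min)
places the initial mixture mean, `0.875 * 40 + 0.125 * (260 + 40) =
72.5` min, inside the observed 65–105 min band.

### Geometry, anchoring, and contact

Divider pole jitters default to 0.04 (anchored) and 0.08 µm/frame (free)
per coordinate — a 2:1 asymmetry mirroring the observed old/new pole
mobility ratio — and non-dividers to 0.004 µm/frame, which keeps their
end-of-trajectory MSD two orders of magnitude below the dividers'. At
separation each daughter contracts to 85% of the newborn length, opening a
~0.6 µm septum gap; without it, sister cells would render as one object
and divisions would be invisible to any segmentation. Hard overlaps
between capsules are resolved by an axial push (two relaxation passes per
frame, spatial-grid culled); doubly anchored non-dividers resist pushing,
dividers yield. No further mechanics (EPS, bending, second layers) is
modelled. If the projected cell area exceeds 90% of the surface the
simulation stops with a single-layer-violation warning and a truncated
history, since the single-layer assumption underlying `N ∝ covered area`
has failed.

### Detachment and reattachment

Each attached agent detaches as a Poisson event (`detachment_rate`, 1/h).
A detached cell reattaches with probability `reattachment_prob` at a
downstream offset drawn from `reattachment_offset` (default 5–10 µm, the
observed hop length), otherwise it leaves the system; advection is not
simulated explicitly, so detach–reattach is an instantaneous repositioning
one frame later. `shear_regime_defaults()` provides four presets (ulow →
high) whose only claim is ordinal: detachment pressure rises and
reattachment success falls with shear.

### Initial conditions

Initial cells are placed by sequential minimum-distance sampling (centres
at least 1.75 cell lengths apart) at density `initial_density`
(10⁻² cells/µm²), with uniform orientations, and are dividers with
probability `f` (lagged with probability `lagged_fraction` among them).
`initial_phase` chooses between synchronous newborn cells (`"newborn"`,
the default, needed for the exact zero-variance doubling arithmetic) and a
uniform residual cell-cycle fraction (`"uniform"`, the realistic
asynchronous-attachment condition used for rate estimation — a
synchronized fixed-clock population produces a staircase `N(t)` whose
log-linear slope is biased low).

All stochastic draws come from one seeded stream; identical configurations
give identical histories.

## Growth model and age structure

With daughter-divider probability `f` and mean generation `tau_bar`, the
dividing subpopulation obeys `N_d(t + tau_bar) = 2 f N_d(t)`, hence

\[ \eta_{\mathrm{eff}} = \frac{\ln 2f}{\bar\tau_d}, \]

with stationarity at `f = 1/2`. Two caveats matter when checking this
against the simulator:

* **Age structure.** The generational argument is exact for a fixed clock.
  For an exponential clock the Malthusian rate solves the Euler–Lotka
  equation `2f E[e^{-eta tau}] = 1` and exceeds `ln(2f)/mean(tau)` (e.g.
  `f = 0.8` with a 20 + Exp(32) min clock yields ~0.59 /h rather than
  0.54 /h). Rate-recovery checks therefore use `clock = "fixed"`;
  fraction-recovery checks are clock-shape-insensitive and use the
  exponential clock.
* **Transients.** The attached count carries two decaying transients: the
  divider/non-divider composition relaxes from its initial share `1 - f`
  to the branching steady state `(1-f)/( (2f-1) + (1-f) )`-weighted
  mixture, and the initial division burst echoes through the first
  generations. Both decay over roughly four generations, so growth-rate
  fits use a burn-in (the recovery test fits minutes 240–360 of a 360-min
  run). `division_growth_rate()` (log-slope of cumulative divisions) is
  free of the composition transient but carries an opposite-signed burst
  deficit; it is provided as an oracle utility.

`fit_mean_division_time()` solves the one-dimensional least-squares
problem for `tau_bar` in rate space (residuals on `eta_eff`, matching how
the model is overlaid on rate–fraction data); a fraction-space variant is
available via `space = "fraction"`. A single pair `(f = 0.80, eta_eff =
0.54 /h)` gives `tau_bar ≈ 52` min. Note the deliberate coexistence of two
constants: the dividers' clock mean (40 min) and the fitted model
generation (52 min) are kept distinct (`mean_division_time` vs
`model_division_time`), as the data they summarize differ.

## Rendering, and what passing tests do not show

`render_frames()` draws each attached cell as an anti-aliased capsule
whose rounded ends terminate exactly at the poles, applies a Gaussian
blur, adds Gaussian noise, and omits a cell from a frame with probability
`flicker_prob` (detection flicker; the ground-truth table records the
omission). Intensity convention is configurable (dark cells on a light
background by default). Pixel size defaults to 0.1 µm/px, at which a
2 × 1 µm cell covers ~180–200 px.

The renderer deliberately does **not** emulate phase-contrast halos,
mosaic stitching, z-stacks, defocused second layers, or illumination
drift. Passing the pipeline on rendered stacks therefore demonstrates the
correctness of the *algorithms* (segmentation geometry, linking, event
detection, estimators) under controlled noise, flicker, and crowding — not
robustness to real optical artifacts, which would need real data.

## Segmentation numerics

The per-frame pipeline is: background subtraction → difference-of-Gaussians
bandpass (`bandpass_low = 1`, `bandpass_high = 8` px; the named scales are
calibrated on the renderer and exposed in the parameters) → fixed
intensity threshold → 8-connected components (a diagonal-merge pass on top
of `EBImage::bwlabel`, which is 4-connected) → minimum-area filter →
moment-ellipse fit → eccentricity band `[0.5, 0.995]` (drops round-looking
pole-standing cells) → poles at `centroid ± (major/2)(cos θ, sin θ)`.
Moments include the 1/12 px² pixel-variance term; a 2:1 rod fits an
ellipse of eccentricity ≈ 0.87. Coordinates map pixel (row, col) to µm
with the origin at the top-left pixel centre; all tabular output is in µm.

Two choices deserve explanation:

* **Background.** The classical background model (mean of the first 10
  frames) assumes a sparsely occupied start. Our monolayer starts at full
  density and anchored cells barely move, so that background contains the
  cells and cancels them. `segment_stack()` therefore defaults to a flat
  (median-of-first-frame) illumination estimate and lets the bandpass
  remove residual background; the frame-average model remains available
  (`background = "first_frames"`) and `background_model()` keeps its exact
  contract.
* **Threshold.** The threshold is one constant per experiment. On
  well-contrasted stacks, perturbing it by ±18% translates the count
  curve without changing the fitted growth rate (< 1%;
  `threshold_sensitivity()` quantifies this), so rate estimates do not
  hinge on the manual choice.

Touching cells are *not* split (no watershed); the simulator keeps density
and contact below the regime where this matters, which is also why the
acceptance checks stop at the single-layer horizon.

## Tracking

`link_trajectories()` performs greedy frame-to-frame assignment: candidate
pairs within `search_radius` (1.5 µm) of the constant-velocity predicted
position are linked in order of increasing distance. Tracks may be missed
for up to `memory_frames` (3) consecutive frames and resumed (gap closing
across flicker). A link is withheld when a track faces at least two fresh
detections shorter than 0.7× its length inside `division_pair_radius`
(2 µm, one cell length): that is a completed division, the mother
trajectory ends, and both daughters start fresh — mirroring how a tracker
loses the mother centroid at separation. `detect_division_events()` then
pairs trajectory ends with the two nearest daughter starts (distance
tie-break); a daughter's own eventual division time is its trajectory
duration. Pole labels, which an ellipse fit leaves arbitrary, are made
consistent along each trajectory by minimal-displacement matching, with
ties resolved toward the previous labelling.

In high-frame-rate mode, a trajectory end that is neither a division nor
the end of the movie is a detachment; a start that is neither a daughter
nor the first frame is an attachment; an intra-trajectory step larger than
`detach_displacement_threshold` (5 µm/frame, from the observed 5–10 µm
hops) counts as a detach–reattach pair. Linking search radius and memory
have no published values; the defaults are validated on synthetic
fixtures only.

## MSD phenotyping

For a trajectory of `N` points the lag-`k` MSD is
`sum_{i=1}^{N-k} (x_{i+k} - x_i)^2 / norm`. Two normalizations are
implemented: the `"printed"` form divides by `N` (a convention that
appears in the field) and the standard `"pairs"` form divides by `N - k`.
At the maximal lag `tau = T` the sum has a single term, so the printed
form would scale the end-of-trajectory MSD by `1/N` and defeat any fixed
threshold; the classifier therefore evaluates the end MSD with the pairs
form — the squared displacement between first and last positions, which
is what an anchored elongating cell's ~1 µm² signature refers to.

`classify_phenotype()` calls a trajectory a **divider** if its end MSD
exceeds `msd_threshold` ((0.5 µm)² = 0.25 µm²), otherwise a
**non-divider** if it lasted longer than `min_duration` (40 min, the mean
division time), otherwise **censored** — too short to distinguish a
non-divider from a cell that detached before dividing. Censored
trajectories are excluded from phenotype fractions and from division-time
statistics. The MSD growth-law exponent is deliberately not used: attached
cells are sub-diffusive in both classes and the exponent does not
discriminate.

`divider_fraction_series()` emulates cumulative divider/non-divider
counting over observation time: a trajectory joins the divider count at
its first crossing of `sqrt(msd_threshold)` displacement from its start,
and the non-divider count once it is older than `min_duration` without
having crossed. The time-averaged fraction is the model-facing measurement
of `f`. Its known small upward bias (cells mid-elongation at the movie end
are not yet countable) is ~2 percentage points under the acceptance
conditions.

Lagged dividers are identified among *division times*: `tau_d` above
`lag_divider_cutoff` (160 min) departs from the exponential bulk.

## Division-time statistics

`division_time_statistics()` fits the exponential rate on the bulk
(`tau ≤ 160` min) by truncated-exponential maximum likelihood, solving
`1/lambda = mean(tau) + c e^{-lambda c} / (1 - e^{-lambda c})` with
`uniroot`; a naive `1/mean` on the truncated bulk would be biased low by
~3 min at the 40-min scale. Zero-variance samples are flagged degenerate
(rate set to 1/mean with a warning). When birth times are supplied the
function also returns the mean division time per 40-min birth bin; in a
growing colony the late bins must be read with their follow-up horizon in
mind — the acceptance computation uses bins with at least 160 min of
residual observation, where right-censoring is below 0.1%.

## Channel physics

Velocity in the rectangular culture channel (10 mm × 1 mm × 150 µm,
width ≫ height) is the Fourier-series Stokes solution for a cuboid duct,
truncated when the next term changes the mid-width wall shear by less than
10⁻⁶ relative; hyperbolic-cosine ratios are evaluated in log space to
avoid overflow. The near-wall shear rate is the velocity gradient averaged
over the monolayer height (3 µm) at mid-width — equivalently
`v(z_m)/z_m` — which for a parabolic profile lowers the wall value by the
factor `1 - z_m/h = 0.98`. Wall shear stress is `mu * gamma_dot` with
`mu(37°C) = 0.691 mPa s`; the four reference regimes (7, 29, 72, 116 s⁻¹)
map to 5, 20, 50, 80 mPa after rounding. Shear rate is treated as the
primary regime descriptor; the quoted mean velocities are not reconciled
against it.

Damköhler numbers compare transport and consumption times:
`Da_O2 = (e²/D) / (c_O2 h / (mu_O2 B))` for membrane-diffused oxygen and
`Da_n = (L/v) / (c_glu h / (mu_glu B))` for advected glucose; both ≪ 1
means no limitation. The oxygen diffusivity through the membrane has no
canonical value here and is a required input (a literature value is
~3.4 × 10⁻⁹ m²/s); the advection length printed in the transport estimate
(10⁻³ m) differs from the channel length (10⁻² m), an inconsistency the
implementation surfaces rather than patches — `damkohler_numbers()` uses
the geometry it is given. The symbol µ is used in the field for both
viscosity and consumption rates; fields are named `viscosity_mu`,
`mu_O2`, `mu_glu` to disambiguate.

## Problem sizes

The test suite validates the imaging pipeline on a 50 × 50 µm colony
(~25 initial cells, 81 frames at 0.1 µm/px) where ground-truth counts are
recovered exactly on noiseless stacks, and exercises event-level
statistics on 200–225 µm domains (400–500 initial cells, 360 min). The
acceptance script uses one 400-cell mixture run (> 1500 division events)
and five 500-cell replicates for fraction recovery; it completes in well
under a minute on one CPU. These sizes were chosen as the smallest at
which the binomial and Monte-Carlo error bands quoted alongside each check
are meaningful.

## Limitations

* Trajectory-level acceptance checks bypass pixels; rendered-stack checks
  run at reduced scale. Nothing here demonstrates robustness to real
  phase-contrast artifacts, stage drift, or focus loss.
* The simulator's jitter is a Gaussian random walk, not the sub-diffusive
  motion of real anchored cells; MSD *levels* are matched by construction,
  MSD *shapes* are not.
* Division-detection assumes daughters become resolvable within one frame
  (the septum-contraction gap); densely packed late-stage colonies violate
  this and are outside the single-layer horizon anyway.
* The growth model is i.i.d. across daughters with no inheritance,
  age-structure refinements, or reversion of non-dividers.
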