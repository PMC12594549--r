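---
title: "Virtual detector spacing for SRS dose QA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual detector spacing for SRS dose QA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finepitch)
```

## The problem and the method

Stereotactic radiosurgery (SRS) concentrates a very high dose on targets of
the order of 1 cm, with the dose falling from the prescription level to a
few percent within millimetres. Verifying a planned dose distribution
against a measurement therefore needs millimetre-scale spatial sampling.
General-purpose diode arrays sample at a 10 mm pitch: along a central
profile of a 1 cm target they see only the flat top and the low-dose tails,
with no point inside the penumbra at all.

The workflow this package simulates recovers resolution from such an array
by *couch-shift synthesis*: the array measurement is repeated with the
treatment couch translated by small known amounts, each acquisition's
samples are tagged with their shifted beam-frame coordinates, and the union
of the acquisitions forms a single virtual measurement with a finer
effective pitch. Two shifted acquisitions at offsets {0, 5} mm give a 5 mm
virtual spacing from a 10 mm array; ten acquisitions at 1 mm increments give
1 mm.

Everything — the reference ("planned") dose, the detector, the shifts, the
scoring — is simulated, so the package is a laboratory for the *method*, not
a clinical tool: it answers how virtual spacing, detector geometry, noise
and shift direction interact with the RMSE and gamma metrics under fully
controlled conditions.

## The synthetic dose model

Reference distributions use a radially symmetric flat-top profile with an
error-function penumbra. For a target of radius $R$ centred at $c$:

$$D(r) = b\,D_{max} + (1-b)\,D_{max}\,\Phi\!\left(\frac{R - r}{\sigma}\right)$$

with $\Phi$ the standard normal CDF, $r$ the distance to $c$, $b$ a small
uniform background. This shape was chosen over alternatives (e.g. clipped
cosine or linear ramps) because it is infinitely smooth, it places the 50%
dose level *exactly* at the field edge $r = R$ (giving an analytic handle on
the 50% isodose diameter), and small-field photon penumbrae are empirically
close to error functions.

Parameters, defaults, and rationale:

* `target_diameter` = 10 mm — the 1 cm lesion scenario.
* `penumbra_sigma` = 2 mm — a 20–80% penumbra of $1.68\sigma \approx 3.4$ mm,
  typical of 6 MV FFF small fields at depth.
* `background` = 0.01 of $D_{max}$ — keeps out-of-field points below the 10%
  gamma threshold, so gamma evaluates only in-field points.
* `dose_max` = 100 — internal doses are percent-of-maximum; a Gy mode is
  carried as metadata only, and all metrics renormalise to percent of the
  grid maximum, making them invariant under joint rescaling.
* Grids default to 1 mm spacing, the dose-calculation grid of the emulated
  plans. The single-field grid spans ±50 mm; the two-target (SIMT) grid
  spans ±120 mm SI × ±60 mm RL so that shifted diode footprints around both
  targets stay inside the grid.

The SIMT scenario is the pointwise *sum* of two single-target fields at
SI = ±60 mm (no renormalisation). Summing doubles the small background near
the midline, which is physically sensible (two fields each contribute
scatter) and irrelevant to the metrics because it stays far below threshold.
Targets closer than `diameter + 6 sigma` set an overlap flag in the grid
metadata rather than erroring: an overlapping sum is still a valid dose
distribution, just no longer two resolvable targets.

Coordinates everywhere: millimetres, isocenter origin, axis 1 =
superior–inferior (SI, positive superior), axis 2 = right–left (RL, positive
right). Dose lookup between nodes is bilinear with no extrapolation.

## The detector model

A detector layout is a rectangular grid of samplers at a given pitch
(default 10 × 10 mm over a 200 × 200 mm extent, a simplification of the
array's true diagonal pattern at its nominal spacing). Each reading is the
mean reference dose over the detector's *averaging aperture*, computed by
midpoint sub-sampling at ≤ 0.5 mm steps, then scaled by multiplicative
Gaussian noise $(1 + \varepsilon)$, $\varepsilon \sim N(0, 0.005)$ by
default.

Two apertures matter:

* **Active area, 0.8 × 0.8 mm² (the default).** The silicon diodes of the
  emulated array have sub-millimetre active areas, and the published
  behaviour of the method — virtual 1 mm measurements whose profile RMSE
  almost reaches film's — is only reproducible with an aperture much smaller
  than the diode package. This default represents the device's actual
  dose-averaging element.
* **Diode-unit envelope, 7 × 3 mm² (opt-in).** The diode *units* are
  elongated along SI, and partial-volume effects over that envelope are the
  mechanism proposed for direction-dependent differences between SI- and
  RL-shifted syntheses. Passing `footprint = c(7, 3)` averages over the full
  envelope — a deliberately extreme partial-volume model used by the
  anisotropy analyses and by the acceptance computations that specify it.

Noise is multiplicative because array repeat-to-repeat deviations scale
with signal; its magnitude (0.5%) is a configurable stand-in — the emulated
study reports replicate scatter but no noise model. Noise seeds produce
bit-reproducible readings and restore the caller's RNG state. An optional
couch-positioning error hook (`shift_error_sd`) perturbs each commanded
shift while the recorded coordinates keep the commanded value, emulating
setup error; it is off by default.

Sign convention (documented because nothing in the emulated workflow fixes
it): a couch translation that displaces the detector by $+d$ in the beam
frame assigns the diode nominally at $x$ the merged coordinate $x + d$.
Sampling with shift $d$ is then equivariant to translating the field by
$-d$, which the tests assert.

## Shift schedules and merging

`plan_shifts(pitch, t, axis)` returns the offsets $\{(k\,t) \bmod
\text{pitch}\}$ in increasing order. When $t$ divides the pitch this is
$\{0, t, \dots, \text{pitch}-t\}$ with $\text{pitch}/t$ acquisitions, and
merging keeps every sample. Spacings that do not divide the pitch (4 and
3 mm from 10 mm) still generate a uniform lattice from more offsets — 4 mm
needs $\{0,2,4,6,8\}$, 3 mm needs all ten 1 mm offsets — and the merge then
assigns only the samples that land on the target lattice, discarding (and
counting) the rest. This mirrors how a virtual grid is populated in
practice: every acquisition is a full array readout, and the virtual grid
takes from each the diodes that fall on its nodes.

Merging validates that exactly one acquisition per offset is supplied (by
the shift recorded in each measurement's metadata), refuses mixed axes, and
averages points that coincide within 0.01 mm with a warning — the
coincidence tolerance is deliberately loose enough that repeated
zero-offset acquisitions remain usable. The lattice-membership test uses
half that tolerance (0.005 mm) so near-coincident points are averaged, not
silently dropped. Merged output is sorted by position, making the result
independent of acquisition order.

## Scoring

**Profile RMSE.** The central-axis profile is scored as
$\sqrt{\tfrac1n \sum_i (D_{ref,i} - D_{meas,i})^2}$ in percent of the
reference maximum. Two pairings are available, and the distinction is
substantive:

* `at = "measurement"` pairs the reference at the sparse measured
  positions. A noiseless point-detector sampling scores exactly 0 — useful
  as an identity check, but blind to undersampling.
* `at = "grid"` (the experiment's choice) linearly interpolates the measured
  profile onto the reference grid's positions along the line and scores the
  *shape*. A 10 mm measurement that straddles the penumbra with a straight
  line is then penalised for the gradient it never sampled. This is the
  only pairing under which the emulated study's signature result — RMSE
  falling steeply as the virtual spacing is refined — can arise, since at
  matched positions a measurement sampled from the same grid is nearly
  perfect at any pitch.

The published RMSE formula prints an upper summation limit of $n-1$;
treating that as a typesetting slip, all $n$ pairs are used, with
`drop_last = TRUE` available to reproduce the printed limit.

**Gamma.** For each measured point at or above the threshold (applied to the
*measured* dose as percent of the reference global maximum, matching how
evaluated points are selected in array-QA software), the implementation
minimises
$\sqrt{\,d^2/\delta^2 + (D_{ref}(r) - D_e)^2/\Delta D^2\,}$ over reference
positions within $3\delta$, evaluating the reference bilinearly on a search
lattice of step `min(0.05, delta/10)` mm anchored at the point. Global
normalization ($\Delta D$ anchored to the reference maximum) is the
default, as in common array-QA practice; local normalization is available.
Numerical choices:

* The 0.05 mm search step keeps the discretisation error of the minimum far
  below $10^{-3}$, the agreement the test suite demands against an
  exhaustive dense search. (A coarser step of $\delta/10$ would be cheap but
  cannot guarantee that bound near piecewise-bilinear minima.)
* Candidates farther than $\gamma(r_i)\,\delta$ are pruned: the distance
  term alone already exceeds the incumbent there, so pruning is lossless.
  This makes well-agreeing points (the common case) nearly free.
* Candidates outside the grid extent are excluded rather than extrapolated;
  points near the edge are therefore compared against a truncated search
  region, consistently in implementation and tests.

Two textbook "limits" of gamma deserve a caution. Because the minimum
always includes $r = r_i$, letting $\Delta D \to \infty$ drives every gamma
to zero — it does **not** converge to a pure distance-to-agreement test.
The defensible statements, which the tests assert, are: on a spatially flat
reference, gamma equals the pure dose difference $|\Delta D_i|/\Delta D$ for
any $\delta$; in general $\gamma \le \text{DTA}/\delta$ and
$\gamma \le |\Delta D_i|/\Delta D$; and on a steep linear profile the
minimiser pins near the dose-matching point, with a closed form
$\gamma = d\sqrt{ab/(a+b)}$ ($a = 1/\delta^2$, $b = s^2/\Delta D^2$, $s$ the
dose gradient, $d$ the DTA) that the implementation reproduces.

## The replication experiment

`run_experiment()` fixes a scenario, spacing list (default 10, 5, 4, 3, 2,
1 mm), shift axis, replicate count (default 3, as in the emulated study),
gamma tolerances (3%/3, 3%/2, 2%/2, 3%/1 mm, 10% threshold) and noise, and
derives every per-acquisition seed deterministically from one master seed
(affine combinations with large primes, reduced mod $2^{31}-1$; film gets
its own stream). Within a replicate, one acquisition is simulated per
distinct offset and every requested spacing merges its subset — exactly as
a physical session would reuse the same ten couch positions — so spacings
share acquisitions within a replicate but never across replicates. The
report contains every spacing × tolerance × replicate cell plus film rows,
as tidy data frames with a mean ± SD summary.

Problem sizes (101 × 101 and 241 × 121 grids, 3 replicates, ≤ 10
acquisitions per replicate) were chosen so a full two-scenario study runs in
seconds while still exercising every code path at the emulated geometry.

## What the simulation does and does not show

Measurements here are *sampled from the same grid they are scored against*.
That closed loop is what makes the study controlled — every deviation is
attributable to sampling geometry, aperture averaging, or injected noise —
but it also means the simulation cannot reproduce effects that live in the
difference between a planned and a *delivered* dose: MLC positioning error,
output drift, phantom setup error, detector calibration, angular response,
film darkening and scanner corrections are all out of scope. Consequently
gamma pass rates are optimistic relative to published measured values
(with the small default aperture, most configurations pass at 100%), and
the directional anisotropy that the envelope footprint induces is largely
absorbed by gamma's distance-to-agreement: a 7 × 3 mm² aperture biases a
5 mm penumbra sample by the equivalent of a ~0.4–0.5 mm shift, which
3%/1 mm gamma forgives. The package states this plainly rather than tuning
the simulation until a directional pass-rate gap appears: under these study
conditions SI- and RL-shifted syntheses score identically, and the
anisotropy is demonstrated instead at the sampling level, where the
elongated footprint measurably attenuates an SI gradient more than an RL
one.

What the passing tests *do* establish: the merge is exactly equivalent to
direct fine-pitch sampling for ideal detectors; the gamma implementation
agrees with an exhaustive search to $10^{-3}$; scoring identities and
invariances (zero RMSE and 100% pass on perfect agreement, scale
covariance, tolerance monotonicity) hold; and the method's central
qualitative claim — profile RMSE falling monotonically, by more than a
factor of two, as the virtual spacing is refined from 10 mm to 1 mm —
emerges from the simulation on both scenarios.

## Known limitations

* 2D coronal plane only; no 3D dose, no heterogeneity, no beam model.
* The array's diagonal diode pattern is simplified to a rectangular grid.
* Noise magnitudes are stand-ins, surfaced in the configuration.
* Non-divisor virtual spacings discard off-lattice samples; a future
  refinement could assign them to nearest nodes with distance weighting.
* The optional DICOM RT Dose import is an extension point; the plain-text
  grid format and measurement CSV are the supported interchange formats.
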