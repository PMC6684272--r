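---
title: "Models of perch grasping: traced surfaces, stick-slip statistics, wrench spaces and tau control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of perch grasping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perchgrip)
```

`perchgrip` packages four models of how a bird (or a perching robot)
holds onto a rough cylindrical perch, plus the synthetic-data
generators needed to validate every estimator end to end. This
vignette is the package's own account of the science: the models and
their assumptions, the parameters that matter, what a green test does
and does not establish, and the numerical decisions taken where the
design was genuinely open.

## 1. Surface metrology

A perch surface enters the package as a `surface_profile`: a uniformly
sampled 1D trace of height (µm) against circumferential arc length
(mm), the form produced by unwrapping a structured-light scan of a
branch. Two operations mirror the standard scan-processing pipeline:

* `highpass_detrend(profile, cutoff_wavelength_mm = 1)` subtracts the
  long-wavelength shape (branch curvature, bow) and keeps roughness
  below the cutoff. The 1 mm default is about 5% of a 19 mm perch
  diameter and 20 claw-tip radii: features longer than that read as
  "shape" to a claw, not as asperities.
* `compute_rms(profile)` returns `R_RMS = sqrt(mean(y_i^2))`, with no
  internal mean removal — detrending is an explicit, separate step, so
  the statistic always means the same thing.

**Numerical choice — the filter family.** Only the cutoff wavelength
is conventionally reported for this step, not a filter family. We use
a zero-phase low-pass with the order-8 Butterworth magnitude response,
applied in the (spatial) frequency domain with odd-reflection padding.
Zero phase matters because a phase shift would move asperities
laterally and corrupt every traced-surface result downstream. We chose
the sharp filter over the simpler moving-average smoother because a
moving average's transition band is so wide that detrending is visibly
non-idempotent (re-detrending changes mid-band components by up to
`H(1-H) = 0.25`); with the order-8 response, re-application changes
pure tones outside the transition band by under 2%, and the broadband
change is bounded by `0.25 × RMS` concentrated in a narrow band at the
cutoff. The test suite asserts exactly these two statements rather
than a vague "filters are idempotent".

## 2. Claw-asperity engagement: the traced surface

A claw tip is modelled as a circle of radius `r_a` (µm) sliding in 2D
along the profile. The **traced surface** is the path of the tip's
lowest point:

$$z(x) = \max_{|x'-x| \le r_a}\left[y(x') + \sqrt{r_a^2-(x-x')^2}\right] - r_a .$$

Asperities narrower than the tip vanish from the traced surface —
the geometric reason large animals see smooth perches where insects
see ladders. `trace_surface()` evaluates this by looping over window
offsets (O(n·w)); the test suite holds it equal to an independent
per-position brute-force evaluation on 10^4-sample profiles.

The **usable surface** `n_a` is the fraction of 1 µm segments of the
traced surface whose slope angle strictly exceeds the minimum angle
for static friction. θ_min is the angle between the vertical and the
net contact force when F_T/F_N is at its maximum, so a task that
requires a higher friction ratio demands steeper asperities.

**Penetration correction.** An elastic surface lets the tip sink in.
With a rigid sphere of radius R indenting an elastic half-space to
depth `d = DR·R`, the Hertz half-width is `a = R·sqrt(DR)`, and the
chord from the bottom of the tip to the contact edge has slope

$$m = \frac{1-\sqrt{1-DR}}{\sqrt{DR}},$$

with the continuous limit m = 0 at DR = 0. The effective threshold
becomes `theta_eff = max(0, theta_min - atan(m))`. A depth ratio of
0.05 (2.5 µm penetration at a 50 µm tip under ~10% bodyweight) buys
6.46° of slope — substantial when θ_min is small. The printed final
formula for m is typographically ambiguous between a `DR` and a
`sqrt(DR)` denominator; the derivation steps (`a = R·sqrt(DR)`,
`m = (R - sqrt(R^2-a^2))/a`) force the `sqrt(DR)` form, which is what
we implement, verified against a direct geometric construction to
1e-9 over DR ∈ [1e-6, 0.99].

**Directionality.** A claw hooks asperity faces that rise in its drag
direction; only those count toward `n_a`. The sign convention is a
package decision (a `direction = "both"` mode exists for sensitivity
analysis). On a symmetric 20° sawtooth with θ_min = 10° this gives
`n_a = 0.5` — exactly the one-sided count.

**Scaling policies.** `sweep_usable_surface()` evaluates `n_a` over
grids of `r_a` and θ_min under three depth-ratio policies: `zero`
(rigid), `fixed` (e.g. 0.05), and `isometric`, where DR grows
linearly with `r_a` relative to a reference pair. Isometry enters
because perching forces track bodyweight (∝ length³) while tip radius
tracks length, so depth/radius is preserved only at the reference
scale. Under the isometric policy the advantage of small claws at
steep θ_min flattens and can reverse when shallow asperities suffice.
`fit_exponential_offset()` summarizes `n_a(r_a)` as
`A·exp(-r_a/λ) + c`; the offset c is real on approximately fractal
surfaces, which keep features at every scale.

**Claw geometry fits.** `fit_sphere_tip()` recovers the tip radius
from width-vs-height microscopy via the circle relation
`(w/2)^2 = 2Rh - h^2`, solved as a through-origin linear regression —
algebraic, deterministic, and exact on circular data.
`fit_penetration_curve()` fits depth against normal force as a cubic
constrained through the origin, the standard way to interpolate
penetration at low loads from measurements taken at higher loads
(0.4–3 bw) where sensor noise is negligible.

## 3. Stick-slip friction statistics

Dragged toe pads and claws load elastically, release, and re-stick.
`extract_slip_peaks()` finds the F_T/F_N values immediately before
each slip with a running-maximum detector: an event fires when the
ratio falls by at least `drop_fraction` (default 0.2) of the running
peak. The 20% default is a package decision — the slip detector is
not standardized — and is exposed as an argument; on generated traces
it cleanly separates asperity releases from ramp jitter.

`fit_coulomb()` is the through-origin least-squares slope
`mu = sum(F_N F_T)/sum(F_N^2)`: zero normal force can hold zero shear,
so the line has no intercept.

Two Monte Carlo procedures quantify how birds manage the randomness of
claw friction, both resampling the empirical peak distribution
(no standard distribution fits slip peaks well):

* `load_sharing_sd(peaks, k)` — the SD of the mean of k independent
  draws over n_trials trials. For i.i.d. draws this is σ/√k: engaging
  more claws narrows the spread of the force each one must supply.
  The reported Monte Carlo standard error uses a kurtosis-aware
  formula, since slip-peak distributions are skewed.
* `expected_max_friction(peaks, d)` — the expected best asperity
  found in a drag of length d. Each trial draws
  `floor(N_a) + Bernoulli(frac(N_a))` samples (so the mean count is
  exactly `N_a(d) = density × d`) and takes the maximum; trials with
  zero draws contribute 0, so the curve correctly starts near zero as
  d → 0 (no asperity met, no interlock friction). The suite checks
  the Monte Carlo against the exact order-statistic expectation under
  the empirical distribution,
  `E[max] = Σ v_(i) [(i/N)^n - ((i-1)/N)^n]`, and against the
  analytic `H_n/β` (exponential) and `n/(n+1)·b` (uniform) closed
  forms.

`curl_angle_to_drag_distance()` is a linear map with a user-supplied
coefficient: the angle-to-distance conversion is never measured
directly, so the package refuses to guess it.

## 4. Grasp stability: the wrench space

The stable-grasp model treats the bird as a 2D rigid body gripping a
circular perch at five contacts — toe pads P1, P2 (foot centre), P3
and claws C1, C2 — mirrored about the foot-centre ray. Observed
geometry: claws at ±85° and outer pads at ±45° on 19 mm (0.75 in)
perches; ±45° and ±20° on the 38 mm (1.5 in) perch. The 6 mm perch is
deliberately not modelled: a fully wrapped foot is limited by muscle
and structure, not surface friction, and `build_layout(0.25)` says so
in its error.

A wrench query (F_x, F_y in bw; T_z in bw·mm; squeeze F_sqz in bw) is
feasible if contact forces exist satisfying:

1–3. force balance in x and y, and torque balance about the perch
     axis (contact normals point toward the perch centre and thus
     contribute no torque; shear at radius ρ contributes ρ·s each);
4–5. squeeze equalities: the b_x-components of each half of the
     foot's contacts sum to `+F_sqz + max(F_x,0)` and
     `-F_sqz + min(F_x,0)` respectively;
6–7. Coulomb cones `|shear| ≤ μ·normal`, normals ≥ 0, and claw
     normals capped at 3 bw (heavy loading wears claws; 3 bw is also
     about the largest squeeze force seen).

**LP formulation.** In 2D the Coulomb constraint is linear, so
feasibility is decided exactly as a linear program minimizing total
normal force (the bird's presumed effort), solved with
`boot::simplex`. The original implementation of this model used a
general nonlinear solver; the LP is mathematically equivalent here and
removes initialization sensitivity. The suite cross-checks verdicts
against an independent oracle that decomposes each 2D friction cone
into its two extreme rays and exhaustively enumerates basic solutions
of the equality system — sound and complete for deciding feasibility —
on ≥ 200 random queries per run.

**Frames and conventions.** Wrench queries are expressed in the
perch-fixed frame; the contact set and the squeeze axis rotate with
the landing angle. This is what makes the feasible force region rotate
with the foot, as it should. The centre pad appears in both squeeze
equalities as the model equations state, which (combined with the x
balance) forces its shear to carry no squeeze-axis component; a
`split_center_pad` flag assigns half of its x-force to each side
instead, for sensitivity analysis. Constraints are positively
homogeneous, so scaling wrench, squeeze and caps together preserves
feasibility — a property the suite exercises.

**Safety margins.** `safety_margin()` bisects on added load along a
body-frame direction until infeasibility (tolerance 1e-3 bw). SM_x and
SM_T take the minimum over both senses; SM_y is searched only along
+b_y (away from the perch), because pushing into the perch merely
loads the normals. Margins against a landing force trace are emitted
only while all claws are in contact (`margin_trace`). For a
representative 19 mm layout with moderate squeeze, SM_x exceeds SM_y:
sideways pulls load one half of the foot harder, pull-off unloads the
toes.

## 5. Landing kinematics and tau theory

The approach is summarized by τ(t) = s/v, the visually available
time-to-contact estimate. `compute_tau()` differentiates the distance
trace by central differences with second-order one-sided endpoints —
a deliberate choice: for a constant-deceleration stop, s(t) is
quadratic and both stencils are exact, so the fitted τ̇ is exactly 0.5
(acceptance target t1). `fit_tau_dot()` reports the OLS slope
magnitude; τ decreases to zero at contact so the raw slope is
negative, but the positive convention matches the 0.5/0.8/0.94 scale
on which landing control is discussed (0.5 < τ̇ < 1 is a controlled
collision: braking still under way at touchdown).

`segment_stages()` reproduces the six-stage structure from the foot
spread and claw angle traces: resting ends at the first sample
reaching 10% of the peak spread; spreading at 90%; open at the peak
(first sample attaining the maximum — the stated tie-break for
plateaus); pre-shaping at contact; foot wrapping when the claw makes
stable contact; claw curling at the end of tracking. Stable contact
was determined visually in the original workflow; the default
criterion here is a mean claw-angle rate below 0.5°/ms across a 5 ms
window (both configurable), or an explicitly supplied time. Measured
kinematics are conventionally low-pass filtered (8th-order
Butterworth, 100 Hz) before analysis; `segment_stages(lowpass_hz =
100)` applies the package's zero-phase filter first, while the default
(no filtering) keeps boundaries exact on noise-free synthetic trials.

`detect_superfast()` flags claw displacements of ≥ 0.3 mm (about one
tracking pixel) completed within 2 ms starting from quiescence.
Two milliseconds is ~4% of a 20 Hz wingbeat period and far below any
vertebrate muscle contraction time, pointing to elastic-tendon energy
release. "No perceptible motion" is not quantified anywhere
authoritative; the quiescence speed cap defaults to 0.05 mm/ms and is
exposed as a parameter.

## 6. What the generators emulate — and what they do not

Every generator embeds its ground truth so that downstream estimators
can be scored without external data (a closure property the suite
relies on).

* `gen_surface_profile` — spectral synthesis: Gaussian random phases,
  power-law amplitude `|k|^(-spectral_exponent/2)`, inverse FFT, then
  an **exact** rescale to the target RMS (the RMS contract holds to
  machine precision for every seed). This reproduces the self-affine
  character of natural perch surfaces — roughness at every scale, the
  reason `n_a(r_a)` needs an offset — but makes no attempt to match
  the species-specific spectra of particular woods: generated
  surfaces are parametric stand-ins, and a green recovery test
  establishes estimator correctness, not ecological realism.
* `gen_drag_trace` — Poisson-spaced asperities (only mean densities
  are reported for real surfaces), i.i.d. peak values from a chosen
  family, linear elastic ramps, snap-to-grid peaks so ground truth is
  recoverable exactly. Real traces have correlated peak quality along
  the surface; the i.i.d. assumption matches the Monte Carlo
  procedures' own assumption, and nothing downstream depends on
  spatial correlation.
* `gen_landing_trial` — the constant-τ̇ approach is generated in
  closed form, `s ∝ (T-t)^(1/τ̇)`, rather than by integrating a
  controller; constancy is the modelled behaviour, not a derived
  property. Stage traces are piecewise linear with a quadratic cap at
  the spread peak (real peaks are smooth, and a symmetric cap keeps
  the argmax stable under zero-phase filtering). Forces follow
  fast-rise/slow-decay envelopes. Tracking noise defaults to zero;
  the noisy-recovery tests use 0.05° angle noise — filtered-tracking
  grade — and the two-sample boundary-recovery guarantee should not
  be expected at substantially higher noise, where peak localization
  degrades first.
* `gen_claw_profile` — a circular-arc tip blended tangentially into
  straight flanks at the opening half-angle; profiles differing only
  in flank angle are identical below the tangency height
  `r(1 - sin φ)`, which the geometry tests exploit.

Defaults are the stated world: stage durations (spreading 40 ms, open
21 ms, pre-shaping 31 ms, foot wrapping 19 ms, claw curling 185 ms),
3000 Hz sampling, a 30 g bird, 50 µm tip radius, DR = 0.05,
claw cap 3 bw. Where no value is stated anywhere (resting duration,
drag speed, residual ratio after slip, noise levels) we chose
realistic values once and documented them here.

## 7. Numerical choices, degenerate inputs, limitations

* All randomness flows through one seeded generator per call
  (`withr::with_seed`); fixed seeds give bit-identical outputs and
  never disturb the caller's RNG state.
* Strict inequality at the `n_a` threshold: a perfectly flat surface
  has `n_a = 0` even at `theta_eff = 0`.
* `trace_surface` guards against under-resolution (spacing > r_a/5
  warns, or errors in strict mode) and keeps the `|dx| = r_a` window
  ring under floating-point noise from mm-scale coordinates.
* Profiles coarser than the 1 µm slope-evaluation step are linearly
  interpolated, with a warning.
* LP verdicts distinguish proven infeasibility from non-convergence;
  solutions are checked against a 1e-8 bw residual tolerance before
  being reported feasible.
* The grasp model is strictly planar: no out-of-plane forces,
  in-plane torques, contact migration, or adhesion (claw hooking is
  represented through a large μ_claw, consistent with the Coulomb
  treatment).
* The engagement model is 2D profile-based — no areal tracing — and
  elastic only: no plasticity, fracture, or claw wear.
* Safety margins are reported agnostically: a positive margin during
  observed slipping is not classified as control failure, since some
  slipping can be deliberate.
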