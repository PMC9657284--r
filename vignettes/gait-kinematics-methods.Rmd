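---
title: "Stride-level equine gait kinematics: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stride-level equine gait kinematics: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoofbeat)
```

## What the package computes

Quantitative lameness assessment in horses rests on the vertical motion of
three axial landmarks — poll (head), withers and pelvis (between the tubera
sacrale) — relative to the footfall pattern of the four limbs. hoofbeat
implements the full chain from per-limb hoof-on/off events and vertical
acceleration to per-stride variables, for the four symmetrical gaits walk,
trot, tölt and pace:

* temporal limb variables: stride, stance and swing durations, duty factor
  (stance/stride), diagonal and lateral dissociation (signed % of stride,
  positive when the hind hoof lands before the diagonal or ipsilateral fore
  hoof), and suspension (% of stride with no hoof on the ground);
* vertical range of motion (ROMz) per segment, and the timing of each
  segment's two minima and two maxima per stride, expressed as percent of
  the reference limb stance (left/right forelimb for head and withers,
  left/right hindlimb for pelvis), with values below 0 or above 100 for
  extrema before contact or after lift-off;
* movement-symmetry indices HDmin/HDmax, WDmin/WDmax, PDmin/PDmax (signed
  left-referenced minus right-referenced extremum value, mm) and the
  standard screening filter (exclude when |HD| exceeds 16 mm or |PD|
  exceeds 8 mm at straight-line trot, strict inequality);
* between-segment timing differences of minima and maxima (head–withers,
  head–pelvis, withers–pelvis) as percent of stride;
* descriptive (median/IQR) and mixed-model group summaries (`lme4` with a
  per-horse random intercept, `emmeans` EMMs and Tukey-adjusted contrasts).

A stride is the half-open interval between consecutive left-hind hoof
contacts; every instant belongs to exactly one stride. All event times are
absolute seconds; conversion to percent of stride or stance happens only in
the metrics layer.

Because no public recordings exist for this class of data, the package
carries a first-class synthetic generator whose defaults encode published
reference kinematics of sound Warmblood, Iberian and Icelandic horses (in
hand and ridden), and every downstream stage is tested against it.

## The synthetic gait generator

### Footfall geometry

A template fixes the stride duration, fore/hind stance durations and the
two dissociations. Contacts are placed at stride phases: left hind at 0,
right hind at 50 %StrD, left fore at the lateral dissociation, right fore
at the diagonal dissociation (walk and trot) or half a stride from the left
fore (tölt and pace, where diagonal dissociation is not defined). The
published medians for lateral and diagonal dissociation are each medians of
their own distributions and disagree with exact bilateral symmetry by up to
1 %StrD; placing each pair from its own printed value realizes both exactly
for the left-hind-anchored pairs, at the cost of that same (real) 1 %StrD
wobble in the mirrored pairs. The per-stride dissociation reported by the
analysis is the mean over both limb pairs, so it sits within half that
inconsistency of the template value.

Stances that begin before the recording but overlap it are emitted too;
otherwise the first stride would show spurious suspension.

### Axial displacement waveform

The reference data prescribe where the extrema of each segment fall, not
the waveform shape. The generator therefore uses the minimal smooth
waveform with two oscillations per stride and freely placeable extrema: a
phase-modulated cosine

$$z(\phi) = -\tfrac{R}{2}\,\cos\!\big(\psi(\phi) - \psi_0\big),\qquad
\psi(\phi) = 4\pi\phi + \beta\sin(4\pi\phi + \gamma),$$

with $\phi$ the within-stride fraction and $R$ the ROMz in mm. With
$|\beta| < 1$ the phase $\psi$ is strictly increasing, so the stride
contains exactly two minima and two maxima, the waveform attains $\pm R/2$
exactly, and it repeats exactly every half stride — the left and right
half-stride patterns of a perfectly symmetric horse. $\beta$, $\gamma$ and
$\psi_0$ have closed forms from the requested minimum and maximum phases;
across all shipped templates $|\beta| \le 0.35$. The acceleration channel
is the analytic second derivative (m/s²), so the integration stage can be
tested against exact ground truth.

Walk and tölt phase structure emerges from the per-segment extremum phases
rather than from an extra rule: the walk withers minima sit near stance
onset, a quarter stride from the head/pelvis minima, and the tölt pelvis
runs a quarter stride out of phase with head and withers.

### Asymmetry, noise and jitter

Movement asymmetry (a lame-like pattern) is injected multiplicatively: the
segment's waveform is scaled by
$g(\phi) = 1 + a_1\cos 2\pi(\phi - m) + a_2\cos 2\pi(\phi - x)$, a
stride-frequency envelope anchored at the left-referenced minimum $m$ and
maximum $x$, with $(a_1, a_2)$ solved exactly from the requested HDmin/HDmax
(or PDmin/PDmax) deltas. The envelope leaves extremum *locations* exact
when a single delta per segment is set, scales rather than fights the local
curvature (an additive bump of the sizes needed for the screening
thresholds would annihilate the extremum), and its cross-talk between the
min- and max-indices is bounded by $\cos 2\pi(m - x) \approx 0$ since the
extrema sit close to a quarter stride apart. `inject_asymmetry()` applies
the same envelope to an already simulated trial, solving against the
trial's measured extremum values, so injected and recovered indices agree
within fractions of a millimetre.

Measurement noise is white Gaussian, specified in mm on displacement and
scaled by $(4\pi/T)^2$ on acceleration. Optional stride-to-stride jitter
perturbs stride durations, event times and amplitudes with SDs derived from
the published interquartile ranges via the normal-distribution factor
0.7413 (the reference tables report IQRs only; whether within- or
between-horse variation dominates them is not stated, so this is a modeling
choice, kept behind an explicit `jitter` switch). One integer seed drives
all draws through a single generator pass.

Defaults the reference tables do not cover, chosen once: tölt ROMz
45/35/45 mm and pace 55/40/50 mm (head/withers/pelvis; the source shows
these only graphically, in the vicinity of the Icelandic trot values), and
ridden-walk ROMz reuses the in-hand Icelandic values.

## Analysis conventions and numerical choices

**Event detection.** Real deployments use proprietary detectors on limb
inertial signals; the package's surrogate declares stance where the
stylized limb signal stays below 5% of its robust (95th-percentile)
amplitude for at least 40 ms. Runs touching the trace boundaries are
discarded — their onset or lift-off was not observed. On simulator output
the surrogate matches the truth to within one sample; the default analysis
path nevertheless uses the ground-truth pass-through, keeping detector
error out of parameter-recovery results.

**Double integration.** Acceleration is integrated twice per stride window
(cumulative trapezoid). Drift correction is anchored on the stride cycle:
the per-stride mean of velocity is removed (exactly cancelling the linear
displacement drift produced by the unknown initial velocity), the residual
linear drift is removed by requiring the displacement to match at the two
window endpoints one stride apart, and the per-stride mean of displacement
is removed. A least-squares line subtraction would be wrong here: the
best-fit line through one period of $A\sin$ has slope $-6A/(\pi T)$, so
"detrending" a clean sinusoid distorts it by almost twice its amplitude.
Endpoint anchoring uses only the cyclicity of gait. On analytic inputs the
recovered ROMz is accurate to ~0.2%, well inside the 2% acceptance band.

**Extremum location.** Extrema are found on the raw-sample window (not the
normalized grid) and refined with a three-point parabola, giving sub-sample
timing — at 200 Hz and pace stance durations, the 1%-of-stance recovery
band is ~0.3 samples, finer than any fixed grid. The two minima (maxima)
retained are the deepest (highest) at least 20% of a stride apart.
Normalized 101-point strides (0–100%, piecewise-cubic resampling, per-stride
mean removed) are produced for waveform summaries and plots.

**Left/right assignment.** A segment's two minima sit half a stride apart,
so either can be expressed against either reference stance; the label is a
convention. The package assigns "left" to the extremum nearest the gait's
expected stance phase: minima near midstance in every gait; maxima near
lift-off (anchor 100% of stance) in trot and pace, near midstance (60%) in
the vaulting walk, and at the stance boundary (50%) in tölt. These anchors
restate the qualitative mechanics of each gait and reproduce the reference
convention for every shipped template with a margin of at least 8% of
stance.

**Stance-relative timing** wraps the extremum-to-contact offset about the
stance midpoint, so an extremum late in a long walk stance (e.g. 87% of a
stance that spans 65% of the stride) is not aliased onto the previous
cycle, while out-of-stance values such as the Warmblood trot pelvis maximum
near 110% are preserved.

**Phase differences** between segments use nearest-in-time pairing against
both of the partner segment's extrema, wrapped to (−50, 50] %StrD, positive
when the first-named segment peaks first. Head/withers are referenced to
fore stances and the pelvis to hind stances, so left–left pairing alone
would be off by half a stride in trot. At walk and tölt some true offsets
sit essentially at the ±25 %StrD alias boundary; published values there mix
both pairings (walk head–withers minima reported at both +23 and +28), and
under the nearest rule this package reports the ≈−22 to +23 representative.
Round-trip tests compare against the template-implied offsets under the
package's own rule.

**Dissociation pairing** matches each hind contact to the nearest fore
contact under the same signed wrap; suspension is the window length minus
the union of all stance intervals overlapping it, clamped at zero.

**Inclusion filter.** "Exceeds" is strict: 16.0 mm head and 8.0 mm pelvis
values are retained. Indices are stored signed; thresholds compare absolute
values. Missing indices give an "indeterminate" decision rather than a
default.

**Mixed models.** The model layer is deliberately thin over established
tools: `lme4::lmer` fits (ROMz ~ breed × segment, and per-variable
one-way breed models, each with a per-horse random intercept),
`emmeans` EMMs with Tukey-adjusted pairwise contrasts at α = 0.05, and
exported residual/fitted tables for adequacy checks. Satterthwaite degrees
of freedom by default; the large replicate loops in the test suite use
asymptotic inference for speed. Designs without at least two breeds of two
horses are reported non-estimable instead of silently fitted. Strides enter
as rows (pooled-stride convention) with the horse intercept absorbing
repeated measurement; per-horse pre-aggregation is a caller-side
alternative.

## Problem sizes used by tests and scripts

Round-trip tests simulate 4 strides per template at 200 Hz — the recovery
errors are set by quadrature and refinement, not by stride count, and
interior strides are representative after the first. The statistical-stage
checks run 200 replicates per scenario at 10 horses × 3 breeds × 6 strides
(size) and 20 horses × 2 breeds (power, 25 mm head offset, between-horse SD
21 mm and stride SD 10 mm as implied by the reference confidence-interval
widths). The workflow scripts use 8 strides per trial.

## What passing tests do and do not show

The generator reproduces the *timing and range structure* of the reference
data: footfall geometry, two-per-stride extrema at prescribed stance
phases, ROMz, and left/right symmetry with controllable departures. It does
not emulate raw 6-axis IMU physics (orientation drift, mounting artifacts,
gravity-axis identification), speed dependence of ROMz, surface effects,
canter/gallop, or circular locomotion. Round-trip success therefore
validates the analysis chain's correctness and conventions, not its
robustness to every artifact of field recordings; the surrogate detector in
particular is a stand-in for proprietary event detectors, not a model of
them. Reported group-level numbers from the cohort generator are
qualitative reproductions of the reference pattern (smallest upper-body
motion in Icelandic horses, largest in Warmbloods), not re-estimates of the
published fits, whose raw data are unavailable.
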