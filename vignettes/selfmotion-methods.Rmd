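---
title: "Methods: self-motion measures, hearing-aid simulation, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-motion measures, hearing-aid simulation, and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `selfmotion`, the
parameters that matter, the assumptions behind the synthetic-data
generator, and the numerical choices made where the design was genuinely
open. It states no number that the package's tests or the acceptance
script do not themselves compute.

## 1. Sensor model and gaze fusion

Three streams enter the pipeline: head yaw (and horizontal translation)
from a motion tracker, nominally 200 Hz; torso yaw from the same tracker;
and horizontal eye-in-head rotation from a two-electrode EOG at 33 Hz in
calibrated degree-equivalent units. Angles are in degrees, 0° straight
ahead, positive leftward (counterclockwise from above), wrapped to
(−180°, 180°]. This convention has to be fixed once because the
head-gaze-ratio exclusion rules are sign-based.

**EOG drift correction.** EOG electronics drift slowly. The drift estimate
is the raw series, padded at both ends by linear extrapolation (a line fit
to the outermost half-window of samples) and smoothed by a centred
500-sample moving average (~15 s at 33 Hz); the estimate is subtracted.
The padding is the only reading under which a centred 500-sample average
is defined over the full support. `correct_eog_drift()` refuses series
shorter than the window; `fuse()` caps the window just below the series
length so short recordings remain usable.

Two properties of this corrector matter downstream and are verified by
tests:

* It removes the accumulating random-walk component. A single random-walk
  path can wander arbitrarily little, so the ≥95%-variance-removed
  property is asserted over a seed ensemble (pooled residual variance over
  pooled drift variance), with the residual isolated exactly via the
  corrector's linearity: `correct(clean + drift) − correct(clean)`.
* It is *not* transparent to slow eye-in-head signal. Any genuine
  eye-in-head content slower than ~15 s is absorbed into the drift
  estimate and removed. Section 5 discusses what this does to parameter
  recovery.

**Fusion.** All streams are linearly interpolated onto a common 120-Hz
axis over the overlapping time support and summed: gaze = head yaw +
eye-in-head. Linear interpolation (no anti-alias filter) is a documented
simplification: head motion is slow relative to 200 Hz, so 200→120 Hz
aliasing is negligible.

**Saccade detection.** Angular velocity is estimated by central
differences of a 50-ms moving-average-smoothed copy of the series — the
same estimator used for the speed measures, so the two never disagree.
Runs of |velocity| above threshold become events; events closer than 50 ms
merge; events below 3° amplitude are dropped. Thresholds default to
50 deg/s for eye/gaze and 20 deg/s for head, standard oculomotor and
head-kinematics ranges, and are exposed as arguments because the exact
original values are not recoverable. The saccade mask used by the ratio
measure is the union of eye- and head-saccade samples.

## 2. Movement measures

`GazeStd`/`HeadStd` are sample standard deviations of the yaw
trajectories; speeds are mean |velocity|; `NGazeJumps` is the gaze-saccade
count divided by duration, reported per minute (the unit is a package
choice, recorded in the output metadata). `TargetGazeRMS`/`TargetHeadRMS`
are RMS wrapped angular differences against the piecewise-constant
active-speaker azimuth; environments without a defined target yield `NA`
by construction, not an error.

`HeadGazeRatio` averages per-sample ratios |head re torso| / |gaze re
torso| over samples that survive three exclusions: (a) not during a
head/eye saccade, (b) |head| ≤ |gaze| with equal sign, (c) |gaze| ≥ 10°.
Two deliberately resolved ambiguities:

* *Aggregation*: the mean of per-sample ratios (not the ratio of means) —
  the per-point exclusions only make sense per sample.
* *Sign rule at head = 0*: included. A zero head angle is meaningful
  "all-eyes" behaviour; excluding zeros would bias the ratio upward.

Rule (b) forces every included sample ratio into [0, 1], which is tested
as a property. When nothing survives the exclusions the ratio is an `NA`
value, mirroring the real-world situation where the measure is simply not
defined for some participant–environment cells.

## 3. Scene rendering, head motion, and the microphone model

Scenes are rendered to a 29-direction layout: a 16-slot horizontal ring at
ear level (first slot 11.25°, 22.5° spacing), 6-slot rings at ±45°
elevation, and a pole. Ear-level sources use pairwise constant-power
amplitude panning between the two nearest ring slots (g₁²+g₂²=1, so
rendered power equals source power at every azimuth — tested to ±0.1 dB);
elevated sources snap to the nearest direction. Moving sources update
their gains block-wise (1024 samples) with a linear cross-fade across the
block.

**Head motion.** Per block, each ring channel is re-panned to its
head-relative direction (direction − yaw); translation displaces the
listening position inside the 1.76-m ring, changing per-channel azimuth
and a distance gain (a second-order effect for normal sway). Elevated
rings rotate by nearest-slot snap; the pole is yaw-invariant. Two
numerical details are load-bearing:

* With zero translation the relative azimuth is computed directly from
  the layout angles, so a zero or slot-multiple yaw is *bit-exact* — this
  is what makes "SNRrelative of the no-motion trajectory is exactly 0" an
  identity rather than a tolerance.
* A rotate-then-counter-rotate round trip is exact at multiples of the
  22.5° slot spacing and is tested there. At non-multiples, *any* local
  panning law leaks a p·q fraction of amplitude into neighbouring slots
  on the way back; this is an inherent property of panning on a 16-point
  grid, not an implementation artifact, and is the reason the inversion
  property is stated at slot multiples.

**Microphone model.** Measured head/hearing-aid impulse responses are
supported from multichannel WAV files; the default is a parametric,
synthetic stand-in with three ingredients per (direction, ear, mic):
a Woodworth interaural delay (head radius 8.75 cm), a first-order
head-shadow filter on the contralateral side (one-pole/one-zero,
corner at c/a; high-frequency gain shrinking with lateral angle, floored
at 0.05), and an axial front/rear-microphone delay d/c·cos(incidence)
with d = 10 mm. Delays are realized as windowed-sinc fractional-delay
FIRs with an integer/fractional split and a fixed base latency, because a
plain short windowed sinc attenuates delays that approach the window edge
(the ±11-sample ear delays would otherwise be damaged). The responses are
128 taps so the shadow filter's tail is not truncated. The model is
left/right symmetric at 0° (exactly), has no pinna cues, no elevation
spectral cues, and no room reverberation — adequate for power-based SNR
measures, inadequate for perceptual prediction.

## 4. ADM and shadow processing

Each side runs an independent first-order adaptive differential
microphone. Cardioids come from delay-and-subtract with the d/c = 29.2 µs
fractional delay (64-tap design; null depth tracks delay accuracy
directly, which is why the taps are generous and DC-normalized). The mix
`y = c_front − β·c_back` adapts β by a block NLMS step (block 64 samples,
step 0.01) toward minimizing block output power, hard-clipped into [0, 1]
after every update — the clip is what confines the steered null to the
rear hemisphere. The exact adaptation recursion of the original algorithm
is not published in enough detail to reproduce, so the update rule is the
package's own; the constraint and the blockwise broadband β are the
specified behaviour. β is initialized at 0 (pass-through of the front
cardioid), and `converged_beta()` summarizes the final fifth of the
trajectory.

**Compensation.** A bare differential output is tilted +6 dB/oct, which
would corrupt broadband SNR comparisons against the front microphone. The
equalizer is a 512-tap linear-phase FIR designed by frequency sampling to
the exact inverse of the front-cardioid frontal response 2|sin(ωτ)|,
gain-capped below 150 Hz and around the 17-kHz differential notch. A
first-order IIR was considered and rejected: with its cutoff at c/(2πd)
it leaves the tilt uncompensated through the speech band, and even a
low-cutoff leaky integrator cannot meet the ±3 dB frontal-preservation
contract at the 8-kHz band edge; the FIR meets it with margin (tested per
octave).

**Shadow processing.** The recorded per-block β trajectory and the same
delays and compensation are re-applied to the clean target-only and
noise-only signals. Every operation is linear for frozen states, so
`y_target + y_noise` reconstructs the processed mixture to float
precision (tested at 10⁻⁶ of full scale), which is what makes "SNR after
an adaptive nonlinear algorithm" well defined.

**Segmental better-ear SNR.** 200-ms non-overlapping windows; per window
and ear 10·log₁₀(Σtarget²/Σnoise²), clamped to [−10, +35] dB — the
conventional segmental-SNR limits; the clamp bounds are configurable
because the original processing chain may not have clamped. Better-ear
selection is per window, independently in each condition; windows with
silent noise clamp high, windows silent in both components clamp low
(degenerate but defined). `SNRrelative` and `SNRimprovementADM` are mean
window-wise differences, so any common linear filtering cancels.

## 5. The synthetic generator, and what passing tests do and do not show

The generator emulates the *statistical structure* the analysis assumes,
not the content of real recordings:

* **Speech surrogate**: stationary speech-shaped noise (flat to ~500 Hz,
  ~−9 dB/oct above) with 4-Hz sinusoidal amplitude modulation. SNR
  measures only need power structure; intelligibility, pauses, and
  Lombard effects are not modelled.
* **Scenes**: exponential speaker turns over a set of talker azimuths
  (default mean 5 s, three talkers at ±30°/0°), with the target source
  following the active speaker, plus 16 independent speech-shaped babble
  sources evenly on the ring as the diffuse background. Noise level is
  calibrated in one step against the no-motion frontal reference (the dB
  shift is exact up to clamping), so a requested reference SNR is hit
  within the clamp's reach.
* **Behaviour**: gaze fixates the target and jumps to each new azimuth
  after a sampled latency (default 0.3 ± 0.1 s) via a raised-cosine
  saccade whose duration grows with amplitude; spontaneous glances with
  return occur at ~2/min. The head carries a fixed fraction γ of the
  torso-relative gaze at every sample and the eye the remainder, so the
  γ-relation holds exactly once a fixation settles; sensor streams add
  head tremor (0.3°), EOG noise (1°), and EOG random-walk drift
  (0.05°/sample at 33 Hz). Group profiles default to γ = 0.60 / 0.75 /
  0.94 for young-normal / older-normal / hearing-impaired-like
  behaviour; only the last is anchored to reported group behaviour, the
  others are free parameters chosen to reproduce the young < old <
  impaired ordering. Everything is reproducible bit-for-bit from
  (seed, arguments).

**What the recovery experiment can and cannot claim.** The drift
corrector removes all eye-in-head content slower than its ~15-s window
(Section 1). During a fixation at azimuth A, the fused gaze therefore
reads A − (1−γ)·MA₁₅(gaze) instead of A; with long speaker turns —
which are length-biased, a random sample tends to land in a long dwell —
the local 15-s mean is a sizeable fraction of A and the measured ratio is
inflated, most strongly at low γ. This is a structural property of the
prescribed drift-correction method, not an implementation defect, and it
applies to real data too. The estimator is close to unbiased only where
eye-in-head is near zero-mean at the 15-s scale. The recovery experiment
(`gamma_recovery_experiment()`) therefore uses a lively alternating ±30°
dialogue with 1-s mean turns, drawing an independent track per replicate;
under those conditions the median recovered ratio stays within the ±0.05
recovery tolerance across the γ grid, with the residual bias positive
and largest at γ = 0.3. Passing this says the pipeline recovers a known
head contribution *under behaviour whose eye excursions are short-lived*;
it does not certify the ratio as unbiased for listeners who hold
eccentric eye positions for many seconds.

## 6. Statistics

One mixed ANOVA per measure: group between participants, environment
within, Type III sums of squares on a multivariate linear model
(sum-to-zero contrasts). Greenhouse-Geisser-corrected degrees of freedom
and p-values are reported whenever Mauchly's test rejects sphericity at
0.05. Effect size is partial η² from the univariate SS table. The
Benjamini-Hochberg adjustment is applied jointly across all main-effect
and interaction p-values of the ANOVAs run in one pipeline invocation —
one family per analysis run. Pairwise group comparisons within each
environment use Welch t-tests with Bonferroni correction, the family
being the pairs actually tested in that environment. Participants missing
more than half the environments are excluded with a warning; remaining
incomplete participants are dropped listwise per measure (the four
undefined ratio cells in a real dataset are handled this way). A
degenerate constant outcome returns F = 0, p = 1 rather than an error.
One caveat encoded in the tests: "the corrected p is never smaller" holds
for F > 1; for F < 1, shrinking degrees of freedom lowers the p-value,
so the monotonicity test constructs a design with a real within effect.

## 7. Problem sizes and runtime choices

Audio-bearing tests run 0.25–4-s scenes at 44.1 kHz with 4–8 babble
sources; the ADM acceptance benchmark runs the full 10 s × 13 rear angles
(about a minute on one CPU); trajectory-only experiments use the full
120-s recordings. These sizes were chosen so each check exercises the
full code path with comfortable statistical margin; nothing in the
methods depends on them.

## 8. Known limitations

* The parametric microphone model has no pinna, elevation, or room cues;
  absolute reference SNR values for a given scene are model-specific, so
  cross-condition *differences* (SNRrelative, SNRimprovementADM) are the
  meaningful outputs.
* The ADM is broadband: a single β per block. Per-band implementations
  can null off-axis interferers better at wide spacings.
* The head-gaze ratio inherits the drift-corrector's insensitivity to
  sustained eye eccentricity (Section 5).
* Rotation inversion is exact only at slot multiples of the 22.5° ring
  (Section 3).
* Speeds are computed over the full series including saccades; excluding
  saccadic samples would lower the means and is not what the measure
  definitions specify.
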