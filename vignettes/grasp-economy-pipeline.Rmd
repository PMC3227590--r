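---
title: "Methods: simulating and scoring closed-loop prosthetic grasping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring closed-loop prosthetic grasping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspecon)
```

## The problem

Economical grasping — applying just enough grip force to lift an object
without slip, scaled to its weight — depends on two interacting processes: a
feedforward plan (anticipating the force to command) and feedback correction
(adjusting within the action from sensed consequences). When a prosthetic hand
sits between the user and the object, both processes can be manipulated:
feedback channels can be added (a vibrotactile force display) or removed
(darkness), and feedforward reliability can be degraded by injecting random
delays into the hand controller. `graspecon` implements the full analysis
machinery for studying this: a grasp-and-lift trial simulator with known
ground truth, automatic phase segmentation and rule-based error detection,
per-trial measures with a per-subject compound grasp score, the spatial
vibrotactile force encoder, adaptive-staircase psychophysics for the display's
resolution, and generators for three experiment designs. No human data ship
with the package; every analysis runs on simulated trials whose true outcomes
are known, which is what makes the detector and the score testable.

## The trial simulator

A trial follows the canonical grasp-and-lift sequence: reach/close, contact,
force ramp, lift, hold, replace, release.

**Controller.** The hand uses a gated-ramp differential controller: while the
flexor signal is held the hand closes at 0.12 m/s; once contact is made the
grip force ramps at 5 N/s for as long as the flexor is held, saturating at
15 N; the extensor opens the hand at 0.12 m/s. These constants (and the
1 kHz force / 240 Hz position sensor rates, the 0–10 N linear range of the
force sensor, and the 150 g / 300 g, 55 mm objects) are the package defaults.

**Contact preload.** Closing onto the object registers a small contact force
(0.3 N by default) before the ramp engages. This has two roles: it is
physically what a force sensor pinched between fingertip and object reads at
contact, and it anchors the segmentation — the contact-force threshold
crossing lands at the moment of contact even when a random pre-ramp delay
holds the ramp off, so the segmented ramp span contains the delay and the
ramp-duration measure can subtract it exactly.

**Subject model.** The simulated subject plans a flexor hold duration per
object-weight belief (the feedforward component). With a feedback channel
available (visual and/or vibrotactile) the flexor release time is blended,
with gain `feedback_gain`, toward the moment the *perceived* force — the true
force plus Gaussian perceptual noise, with SD shrinking as the square root of
the number of channels — crosses the planned target, lagged by a reaction
time. With no channels the subject releases purely on planned timing, so an
injected pre-ramp delay eats directly into the realized ramp and hence the
attained force. This is the minimal model that reproduces the
feedforward-versus-feedback contrast.

**Physics.** The grasp is a two-finger opposition grip: it holds iff
`2 * mu * F_grip >= F_load`, with a closed boundary. The friction coefficient
of the low-friction film is not known quantitatively; the default `mu = 0.4`
is a plausible value for a slick film and is configurable. The lift is a
minimum-jerk profile (10 cm, 1 s — stereotyped human point-to-point motion;
the study does not report lift kinematics), so the load is
`m * (g + a_z(t))` with peak acceleration `10/sqrt(3) * A / T^2` (about
0.58 m/s²). Three failure regimes follow from the attained force: below 1 N
the grasp is not stable and the lift fails outright; between 1 N and the
static threshold `m g / (2 mu)` the object never leaves the table while the
hand rises (detected as a slip); between the static and dynamic thresholds the
cone opens mid-lift and the object is left behind.

**Stylised failure kinematics.** The detector works from relative velocities
and accelerations, so each simulated failure is given a frank kinematic
signature: a slipping object's upward velocity decays gently (1.5 m/s², far
below the 5 m/s² drop criterion) and it stays behind the hand; a dropped
object free-falls (9.81 m/s² relative acceleration) while the grip reading
stays above 1 N for a short interval, as when an object slides out of a
maintained squeeze; a failed lift leaves the object still while the hand
completes the motion with grip below 1 N. Drops are injected as rare mid-hold
grip mishaps (`early_release_prob`), since a correctly gripped rigid object
has no other way to fall in this model.

**Within-trial retries.** A subject whose grip cannot hold the static weight
sees the lift fail, lowers the hand and ramps again with a larger target —
feedforward subjects re-execute their plan, feedback subjects ramp to a raised
perceived target — up to five attempts. Trials therefore normally end with the
object lifted, at the cost of one counted error per failed attempt and a
longer trial. This matters for the compound score: without retries, a trial
that never elevates the object has no defined grasp force (the measure is
flagged, never imputed) and would silently drop out of condition means.

**Randomness.** Each trial takes one root seed, split internally into
independent substreams (delays, perception, mishaps, sensor noise), so
identical configurations and seeds are bit-identical and components can be
varied in isolation.

## Segmentation and error detection

Positions are smoothed with a 20 ms moving average before central-difference
differentiation — 240 Hz tracking cannot be double-differentiated raw — and
the force ramp is located as the first sustained (20 ms) crossing of a 0.2 N
contact threshold (above sensor noise, below the 1 N stable-grasp level),
ending where the force first comes within 0.01 N of its plateau. Elevation is
the object base rising 5 mm above its resting baseline (above tracker noise).
On noise-free simulator output every boundary lands within 10 ms of ground
truth; the residual error is set by the 240 Hz grid and the smoothing window.

The error rules are the study's operational definitions: a **drop** is a
stable grasp (grip > 1 N, fingers closed on the object) whose object gains
more than 5 m/s² of downward acceleration over the thumb; a **slip** is a
stable grasp whose thumb gains more than 0.05 m/s of upward velocity over the
object; a **failed lift** is the same velocity criterion with grip below 1 N.
Each contiguous run of samples satisfying a rule yields one event at its
onset; onsets within 60 ms are then merged greedily left-to-right (the
earliest event of a merge group, and its kind, are kept). The onset-collapse
is deliberate: a single 140 ms free fall satisfies the drop rule continuously
and must count as one error, not three. "Stable grasp" additionally checks
that the aperture is at the object's contact diameter, since force alone
cannot verify thumb–forefinger opposition.

## Per-trial measures and the grasp score

For trial *i*: *f_i* is the mean grip force (N) over the object's elevation;
*r_i* the force-ramp duration (ms) excluding injected pre-ramp delay; *d_i*
the trial duration (ms) excluding all injected delays; *e_i* the
de-duplicated error count. The compound score is

  s_i = norm(f, i) + norm(r, i) + norm(d, i) + e_i,
  norm(x, i) = (x_i − target(x)) / (peak(x) − target(x)),

with target(x) the per-subject minimum over error-free trials and peak(x) the
per-subject maximum over all trials. Zero marks the subject's best
performance; each error adds a full unit; higher is worse.

Edge cases are resolved explicitly: when peak equals target every trial is
equally good and the norm is 0 (the ratio is 0/0); values below target give
negative norms, retained rather than clipped, since the definition imposes no
clipping; a subject with no error-free trials gets a flagged fallback target
(the overall minimum); a trial whose object was never elevated has *f*
undefined and its score flagged undefined, never imputed. Grasp force on
saturated trials is computed from the clipped sensor signal and flagged.

## Psychophysics of the vibrotactile display

The display maps grip force linearly onto a stimulation locus along eight
motors spanning the forearm (0 = wrist at 0 N, 255 = elbow at 10 N and
above, clipped not wrapped), with between-motor loci rendered by linear
duty-cycle crossfade of the two neighbours — the duty-weighted centroid
recovers the locus exactly, which is the invariant the tests check.

Display resolution is measured with a two-interval forced-choice adaptive
staircase targeting the separation at which responses are 75% correct. The
package uses the weighted up–down rule: the separation falls by the down-step
after a correct response and rises by `p/(1−p)` times that step (3:1 at 75%)
after an incorrect one, which makes the equilibrium sit exactly at the target
proportion regardless of step size. Two refinements keep the threshold
estimate unbiased within a short run. First, the down-step starts large
(8 display units by default) and halves at each reversal until it reaches its
final value (1 unit), removing the slow descent from a wide starting
separation; the asymmetry ratio is maintained throughout, so the equilibrium
never moves. Second, the converged threshold is the mean separation over the
reversals that occur at the final step size, excluding the first of them. The
step sizes matter beyond convenience: the stationary distribution of the walk
satisfies E[P(correct at s)] = target, and since the psychometric function is
concave above its midpoint, evaluating the observer at the *mean* separation
overstates performance by an amount that grows with the stationary spread —
small terminal steps keep that Jensen gap inside a percentage point or two.
With a simulated cumulative-Gaussian observer (sigma = 20 display units) and
60-trial runs, the observer's true percent correct at the mean converged
separation comes out near 76%, within the ±3-point calibration band the
package's acceptance checks use; 20-trial runs (the study's per-location
budget) are noticeably more biased, which is why pooling locations and
subjects before fitting matters.

Psychometric functions are cumulative Gaussians with an optional lapse rate
(bounded at 0.05), fitted by maximum likelihood to the raw per-trial
responses — never to binned proportions, because the staircase concentrates
samples unevenly. The JND at criterion p is `qnorm(p) * sigma`. Perfectly
separable response sets drive sigma to its lower bound and are flagged
degenerate rather than reported as real thresholds. The discriminable-level
count walks greedily from the wrist, stepping by the linearly interpolated
local JND until the span is exhausted.

## Experiment designs and the simulated cohorts

`build_design()` reproduces the three block structures: (1) four blocks of
20 + 20 trials per object weight, visual feedback throughout, vibrotactile
feedback alternating under two counterbalanced orders; (2) three blocks of
12 + 12 with the third in darkness, vibrotactile feedback a between-group
factor (the control group receives uncorrelated random stimuli, which carry
no force information by construction, so their policy simply lacks the
tactile channel); (3) heavy object only, delays drawn uniformly from 0 to
1.5 s at movement onset and ramp onset, four feedback configurations
(none/tactile/visual/both) of 12 trials per phase over two phases, orders
counterbalanced across four groups (2 × 2 of visual order × tactile order).
The end-of-trial peak-force display is always available and drives
trial-to-trial learning in every condition, matching the protocols. Delays
are drawn independently per insertion point per trial; whether the original
apparatus redrew per insertion point is not documented.

Learning is a bracketed search per object: probe the plan downward while
trials stay error-free, retreat upward after failures, and bisect once both a
failing and a succeeding plan are known, settling on the lowest known success
when the bracket closes within 0.5 N. Under deterministic conditions this
converges within 0.5 N of the minimal stable force in under ten trials, which
is what makes the heavy/light force contrast emerge after the first block.

## What the generator does and does not emulate

The generator reproduces the apparatus constants, the multi-rate sensing with
saturation, the outcome taxonomy with exact ground truth, and the
feedforward/feedback manipulation. It does not emulate: EMG control noise
(the study used binary FSR switches, and so does the model), five-digit hand
kinematics (two-finger opposition only), horizontal transport kinematics,
anticipatory grip-load coupling within the lift, object compliance or
rotation, or perceptual learning of the display. Passing tests therefore
validate the analysis rules and the score machinery on data whose generating
process is known — they do not certify detector thresholds against real
tracker noise, and the stylised failure episodes make event kinds cleaner
than real slips, where velocity and acceleration criteria can genuinely
co-occur.

## Numerical choices and problem sizes

Tolerances and sizes used in the validation suite, chosen once as desk-scale
defaults: 500 staircases of 60 trials for the calibration check; 200
randomized trials spanning all outcome regimes (forces drawn clear of the
friction-cone boundaries, where episode kinematics would be marginal) for
detector/ground-truth equivalence; 50 seeds × 2,000 records for parameter
recovery; 20 condensed cohorts (4 subjects, 6 trials per condition-block) for
the delays-feedback signature. The psychometric fit uses L-BFGS-B on (bias,
log sigma, lapse) with sigma bounded in [1e-3, 1e4]; ties in simultaneous
event onsets rank drop before slip before failed lift (the more specific rule
wins); trial tables aggregate with `na.rm = TRUE` where a flagged undefined
measure occurs.

## Known limitations

The grasp-force/ramp relation is exactly linear, so `f` and `r` are nearly
collinear in simulated cohorts — real data decouple them through imperfect
sensor contact. Retry kinematics reuse the full lift profile rather than a
shortened probe. The drop mishap's persisting grip reading is a modelling
convenience for the detector's stable-grasp gate. The discriminable-level
count depends on the empirical JND profile; the package computes it from
whatever profile is supplied and makes no claim about the original hardware's
value.
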