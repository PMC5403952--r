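---
title: "Cyclogram disparity analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclogram disparity analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclogait)
```

This vignette documents the models behind `cyclogait`, the assumptions
they make, the parameters that matter, and the choices taken where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Data model

A trial is one stride of one subject: nine sagittal series — ankle,
knee and hip crossed with angle (deg), moment (N·m/kg) and power (W/kg)
— on the 50-point stride grid (0, 2, …, 98% of cycle), with a sub-phase
label 1–7 (LR, MSt, TSt, PSw, ISw, MSw, TSw) per sample. Labels are
carried in the data rather than derived from events because
pathological gait has irregular sub-phase durations and the analysis
feeds per-trial durations to the disparity network. The grid is
half-open (0–98%) so that sample 1 is foot strike and the next stride's
foot strike is not duplicated; sample 50 connects back to sample 1 when
a cyclogram trajectory is drawn.

Sign conventions are fixed once for the synthetic templates —
flexion/dorsiflexion positive, extensor moment positive, power positive
in generation — but the pipeline itself is convention-invariant: every
error is an absolute difference normalized by a curve range.

Raw time series are brought onto the grid by linear interpolation
between two successive ipsilateral foot strikes; moments are normalized
by body mass; smoothing uses a second-order low-pass Butterworth filter
applied forward and backward (zero phase). The cutoff defaults to 6 Hz
at the native sample rate — standard practice for gait kinematics — and
is exposed, since the appropriate value is study-specific; zero-phase
filtering is used because phase lag would shift curves relative to
their sub-phase labels. The forward–backward pass is implemented with
steady-state initial conditions and odd-reflection end padding so a
constant series passes through unchanged and 50-sample series do not
acquire end transients; coefficients come from `signal::butter`.

## The 36 cyclogram relationships

Pairing the nine variables gives six groups: angle–angle,
moment–moment and power–power across joints (3 pairs each; a joint is
never paired with itself within a variable type), and angle–moment,
angle–power, moment–power within and across joints (9 pairs each).
For the mixed groups, the only enumeration consistent with 9 pairs per
group and 3 within-joint pairs is one pair per *ordered* joint
combination with the first-named variable type always first — e.g.
(angle of joint *i*, moment of joint *j*) for all nine (i, j)
combinations. Both orientations of an across-joint mixed coupling would
give 12, and unordered couplings only 6; neither matches. The
enumeration is canonical (groups in the order above, joints ordered
ankle < knee < hip) and every downstream tie-break refers to this
order.

## Normal reference

The reference is the conventional trials-averaging method: the
pointwise mean per variable across normal trials on the percent-of-cycle
grid, with no time warping, which is justified by the consistency of
normal sub-phase durations. Pathological trials are never averaged —
their sub-phase durations vary trial to trial, so a pointwise mean
would blur phase transitions; they are analysed per trial through the
network arrangement instead. Only left-side (non-dominant, stability
role) trials enter references and analyses by default, matching the
functional role of the prosthetic side; the side is configurable. The
per-variable range (max − min of the mean curve) is stored on the
reference and is the single normalization denominator used everywhere
downstream.

## Disparity network

Each cyclogram pair gets its own feed-forward network with layer sizes
30–7–3 and linear activations throughout. The input matrix per subject
is 30 × 50: rows 1–10 the first variable for 10 trials, rows 11–20 the
second variable, rows 21–30 the sub-phase labels; columns are stride
samples. Targets are 3 × 50: the two trial-averaged normal curves and
the canonical labels. The 3 output neurons therefore read as the two
predicted variable curves plus a predicted phase signal — the only
interpretation consistent with a 3-row target.

**Normalization.** Inputs and targets are range-normalized before
training — variables via (x − min)/range of the reference curve, labels
via (l − 1)/6 — so that "MSE < 0.9" is meaningful across variables
whose raw units differ by two orders of magnitude.

**Training.** Stride-sample columns are split at random 60/20/20 into
training/validation/test. Given the split, the two weight layers are
fitted from a seeded random initialization by alternating exact
least-squares updates: with linear activations the composed map is a
rank-limited linear map, each layer's optimum given the other is a
closed-form solve, and with 3 outputs and 7 hidden units the factored
map attains the full least-squares solution within one or two
alternations. This optimizer was chosen over iterative backpropagation
because it is exact and deterministic on the highly collinear trial
rows (10 near-copies of each variable), where first-order descent
converges slowly along small-eigenvalue directions; the result is, by
construction, the solution backpropagation would approach in the limit.
A network is accepted when (1) the final training MSE on normalized
data is below 0.9, (2) validation and test MSE are of similar
magnitude — operationalized as |MSE_test − MSE_val| ≤ 0.5 ×
max(MSE_test, MSE_val), with the factor exposed, since "similar
characteristics" admits no unique quantitative form — and (3) the
regression R (Pearson correlation between flattened predictions and
targets, as in standard NN-toolbox regression plots) exceeds 0.9 on all
three splits. Otherwise weights are reinitialized, up to 10 restarts,
after which the network is returned *flagged* as failed — downstream
stages exclude flagged networks loudly, never silently.

Training pools one 30 × 50 arrangement per subject (e.g. 10 subjects ×
50 columns), which makes the least-squares problem overdetermined and
the fitted map unique. Subjects with fewer than 10 trials are resampled
with replacement to 10 (seeded) and flagged, keeping the fixed 30-row
layout.

## Closeness and per-sub-phase errors

Simulating a subject through a trained network yields a 3 × 50
prediction whose first two rows are curves over the gait cycle. The
closeness statistic is C = (1 − e) × 100 with e the mean, over both
curves and all 50 samples, of |predicted − conventional|/range, each
point clipped at 1 so that one full range is 100% error; C is affine
and strictly decreasing in e and bounded in [0, 100].

The per-sub-phase mean normalized error applies the same normalized
absolute error but averages within the samples labeled with each phase,
reported × 100. Normalizing by the reference range was an open choice:
the error could also have been left in raw units, but range
normalization is unit-free and comparable across the 36 heterogeneous
pairs, which is what the per-phase argmax ("worst pair") requires.
Phase grouping uses the canonical reference labels, since predictions
and targets live on the reference timeline. Empty phases are flagged
missing and excluded from the argmax rather than scored zero. Ties in
the argmax break by canonical pair order, deterministically.

## Manipulation and dominance

For each sub-phase, the two variables of that phase's worst pair are
manipulated in turn: the variable's samples labeled with the phase are
replaced by the reference curve values at those grid points
(idempotent by construction), the *unchanged* network is re-simulated,
and the full 7-phase error vector is recomputed. Substitution is
restricted to the labeled samples — the reading of "modification of the
variable values at the particular sub-phase" adopted here — rather than
the whole cycle, which would conflate phases. It operates on the
10-trial input rows, not on the targets, because the target is the
normal profile by construction.

A candidate is admissible when it strictly improves its own-phase error
and worsens neither cyclically adjacent phase (LR and TSw are
neighbours across the stride boundary) by more than a relative
tolerance; the default 5% is exposed, since ties and "large neighboring
error" are qualitative notions. Among admissible candidates the lowest
own-phase post-error wins; two candidates within tolerance are both
reported (a tie — manipulating either yields the same result); no
admissible candidate means no parameter is selected for that phase,
which is the expected outcome at mid-swing, where the shank should
extend ballistically under momentum and gravity.

The knee-only restriction re-expresses hip/ankle selections for
prosthetic-knee design: among the pairs coupling the selected variable
with a knee variable, the pair with the lowest Phase-2 error at that
sub-phase contributes its knee variable. Per-subject results aggregate
to a cohort table by per-phase majority vote, ties reported — the
aggregation rule is not prescribed anywhere, and a vote is the simplest
rule that is symmetric in subjects.

## Synthetic generator

The generator exists because no real gait recordings are distributed
with the method; every quantitative check in the package therefore
rests on *recovery properties* on synthetic data, not on curve
identity.

Templates are periodic splines (`stats::splinefun`,
`method = "periodic"`) through a small knot set per variable,
approximating normative sagittal morphology (stance knee flexion wave,
late-stance plantarflexor moment peak, push-off power burst, swing knee
flexion to ~60°, and so on). They are parametric, not digitized from
any figure. Canonical sub-phase boundaries follow the standard
Rancho/Perry percentages: 10/30/50/60/73/87.

A cohort profile perturbs the templates with: per-(variable, phase)
excursion scales about the cycle mean and offsets in fractions of the
range; Gaussian jitter of the six boundary percentages (snapped to the
grid, each phase kept non-empty); additive Gaussian trial noise,
low-pass smoothed so it resembles residual measurement error rather
than white noise — smoothing is applied to the noise component only, so
the zero-noise limit reproduces the template bit-exactly; and a
per-subject constant offset shared across that subject's trials. The
default severities are ordered orthosis < transtibial < transfemoral:
orthosis mildly attenuates all kinetics (×0.85), transtibial attenuates
ankle power/moment (×0.45/×0.55), and transfemoral strongly attenuates
knee power/moment (×0.25/×0.4), stiffens the stance knee angle (×0.6)
and distorts hip kinetics (×0.75), with boundary jitter 0.5/1.5/2/2.5%
and trial noise 2–5% of range. The magnitudes are free parameters of
the generator (no quantitative description of pathological deviation
exists to copy), chosen once as plausible deficit patterns; what the
tests verify is that the *ordering* of cohort closeness and the
recovery of planted deficits follow from them.

What the generator does **not** emulate: bilateral asymmetry beyond the
side convention, speed effects, frontal/transverse planes,
ground-reaction forces, marker noise or soft-tissue artefact, and
correlated compensation strategies across joints. Passing tests
therefore show that the pipeline recovers structure it is designed to
detect under its own assumptions — they do not certify performance on
real amputee recordings.

## Numerical choices and degenerate inputs

* Pseudo-inverses in the network fit use `MASS::ginv` (SVD-based), so
  rank-deficient hidden layers cannot crash the solve.
* The similarity criterion guards against 0/0 with a machine-epsilon
  floor; regression R of a constant split is defined as 0 (fails the
  gate honestly).
* A zero reference range (flat mean curve) is rejected when the
  reference is built — every downstream normalization divides by it.
* Boundary jitter clamps each of the six boundaries between 2% and 98%
  and enforces a minimum one-sample phase width.
* Trial CSVs serialize numerics at 17 significant digits so write/read
  round trips are bit-equal.
* Seeds: every stochastic stage takes an explicit integer seed; derived
  seeds use a multiplicative-congruential mix kept below 2^31. The
  seeding helper restores the caller's RNG state, and forces its seed
  argument before saving that state so a seed expression that itself
  draws randomness is not rolled back.

## Problem sizes

The shipped tests and the acceptance script use a training cohort of 10
subjects × 10 trials (100 trials averaged into the reference, 500
columns per network fit), 5 held-out normal subjects, 10 subjects per
cohort for the ordering check, and 10/20 seeded repetitions for the
planted-deficit recovery checks. These sizes keep the full suite around
half a minute while leaving every network fit overdetermined; the
planted-deficit fixture scales knee power to 0.2 at loading response
with no boundary jitter, the cleanest realization of a single-variable
deficit in a single phase.

## Known limitations

* The disparity model is linear end to end; a genuinely nonlinear
  coupling between pathological inputs and deviation from normal would
  be scored only through its linear projection.
* Closeness aggregates a subject over 36 pairs by the unweighted mean;
  pairs with large reference ranges are not up- or down-weighted.
* The manipulation stage evaluates one variable at a time against the
  worst pair only; interactions between simultaneous substitutions at
  different phases are out of scope.
* Real-data error magnitudes cannot be reproduced or validated here;
  only structural and recovery properties are testable at desk scale.
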