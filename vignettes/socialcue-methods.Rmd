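---
title: "Models and methods behind socialcue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind socialcue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialcue)
```

## The scientific problem

A decision maker watching another individual can treat that individual's
gaze as a cue, but only to the degree that the gaze is informative. The
task modelled here puts a social cue (a conspecific's face turning toward
one of two objects) in competition with a non-social cue (the objects'
learned reward probabilities), and manipulates the *reliability* of each
across three 50-trial block conditions:

| condition | face reliability | object reliability |
|-----------|------------------|--------------------|
| Face      | 0.90             | 0.60               |
| Object    | 0.60             | 0.90               |
| Mixed     | 0.90             | 0.90               |

A trial is **incongruent** when the face points away from the better
object; only on those trials does the choice reveal which cue drove it.
The package implements the full analysis chain around this design:
trial-schedule and choice-agent simulation, mixed-effects behavioral
models, event-related design matrices for region-of-interest (ROI) BOLD
series, and a trial-epoch time-course procedure with permutation
inference. Every stage has a generative counterpart so that each analysis
can be validated by parameter recovery on data whose ground truth is
known.

## Task generator and choice agents

`make_session_schedule()` draws, independently per trial, the
better-object side (uniform), the rewarded side (equal to the better side
with probability `p_object`) and the face direction (equal to the rewarded
side with probability `p_face`). Under independent generation the expected
incongruent proportions are about 42% (Face), 45% (Object) and 18%
(Mixed). Published descriptions of such designs sometimes report slightly
different realized proportions (which depend on unstated sequence
constraints); we generate independently and treat the nominal
reliabilities, not realized proportions, as the specification.

Timing follows the printed task structure: an inter-trial interval of
3–4 s and an action–outcome delay of 3–5 s for the scanner version
(`experiment = "exp2"`), a 300 ms delay and 3–5 s ITI for the stimulation
version (`"exp3"`). Onsets are recomputed cumulatively once the agent's
reaction times are drawn, so `onset_outcome = onset_decision + rt + delay`
exactly.

Agents (`agent_params()`) choose via one of three policies on the signed
cues (left = −1, right = +1):

* **logistic** — `P(right) = plogis(w_face·face + w_object·object +
  w_interaction·face·object + bias)`;
* **linear** — the same linear predictor mapped through
  `P(right) = 0.5 + 0.5·(·)` and clipped to [0, 1]. Under the symmetric
  ±1 choice coding, the linear-probability mixed model recovers these
  weights *as is*, which is what makes clean recovery studies possible;
* **mixture** — follow the face with probability `follow_face_prob`,
  otherwise take the better object. This is the analytically convenient
  agent: with follow probability *q* and lapse rate *l*, accuracy under
  the reliable-cue convention is 1 − *l*/2 on congruent trials and
  `(1−l)q + l/2` on incongruent trials, so the incongruency coefficient
  of the accuracy model equals `(q − 1)(1 − l)` in expectation.

`session_sd` adds mean-zero session-level jitter to every policy
parameter (weights, follow probability, lapse). This is the generative
analogue of the per-session random effects the behavioral models estimate;
without it, fitted random-effect variances sit at zero and the models are
exercised only on their degenerate path.

Accuracy has two conventions. The default (`"reliable_cue"`) scores a
choice correct when it matches the side indicated by the condition's
high-reliability source — the face in the Face condition, the better
object in the Object condition, and either of the two (they agree except
on incongruent trials, where both are equally reliable) in the Mixed
condition. It is deterministic given the schedule, which analytic oracles
need. The `"reward"` convention scores against the realized rewarded side.

Ultrasound stimulation of a site is modelled by
`apply_tus_perturbation()` as a down-weighting of one cue channel: mSTS
degrades the face channel, EVC the object channel, and dmFPC the channel
that is *reliable in the current condition* — the signature of a region
that regulates information use by reliability rather than carrying one
cue. For weight agents the weight is multiplied by `factor`; for mixture
agents a fraction `1 − factor` of the channel's deliberate follows become
coin flips, so degrading a channel the agent rarely uses barely moves
behavior.

The two-face repetition design (`make_exp1_schedule()`) crosses direction
repetition with identity repetition in four equal cells; a directed first
face is always followed by the same direction, a neutral first face by a
left/right second face in balance.

## Behavioral mixed models

All four models share one engine: maximum-likelihood fits with
independent per-session random intercept and slopes
(`lme4`/`lmerTest`), *F* statistics with Satterthwaite degrees of freedom,
and 95% CIs from the same *t* distribution.

* choice ~ face × object (per condition);
* accuracy ~ incongruency (0 congruent / 1 incongruent);
* accuracy ~ stimulation indicator (sham 0 / active 1), per trial subset,
  optionally with incongruency and its interaction;
* choice ~ cue × stimulation indicator, whose interaction is the
  stimulation-induced change in the cue's weight.

Three estimation rules deserve comment.

**Link.** The choice model is written in linear form but is conceptually a
model of a binary choice. The default is the linear-probability link
(identity), whose coefficients live on the same scale as the generative
linear-policy weights and as published coefficient magnitudes for this
kind of model; a logistic link is available (`link = "logistic"`), with a
fallback to the linear link if separation is detected.

**Hessian rule.** All terms enter as random effects first. If the
optimizer's Hessian at the optimum is not positive definite (minimum
eigenvalue ≤ 1e−6), or the fit fails outright, the model is refit with
*every* term as a fixed effect (all at once, not by stepwise pruning) and
flagged `fell_back_to_fixed`. A variance component estimated exactly at
zero (a "singular" fit) does not by itself trigger the fallback: the
constrained Hessian there is typically still positive definite and the
remaining variance components are reliably estimated, whereas demoting
everything to fixed effects would discard genuinely present slope
variance and produce anti-conservative intervals.

**Diagnostics.** `check_model_diagnostics()` stores a Kolmogorov–Smirnov
p-value for residual normality and, given a nested reduced fit on the same
data, a likelihood-ratio test. With a single session the engine refuses
random effects and fits fixed-only with a warning.

## Hemodynamic model and design matrices

The hemodynamic response is a single gamma density with mean lag 3 s and
SD 1.5 s — moment-matched to shape 4 and scale 0.75 s — sampled on
[0, 30] s and normalized to unit discrete integral, so convolved-regressor
amplitudes keep signal units. A monkey HRF peaks earlier than the human
one; no undershoot is modelled.

`build_design()` expands a session's trials into the registered regressor
sets: 13 regressors for the two-face repetition analyses (500 ms decision
boxcars; the identity variant swaps the two repetition regressors) and 14
for the gaze-versus-object task (1 s decision boxcars, 2 s outcome
boxcars, three unconvolved one-TR spike regressors), plus appended
confound columns. Reaction-time regressors are z-scored within session.
Events are laid down on a fine grid of TR/10 = 148 ms, convolved there,
and sampled at TR midpoints; all indexing is half-open and onsets are in
seconds from run start.

Two constructional choices: (1) registered regressors with no events — or
whose amplitudes are all zero, e.g. no rewarded trial in a class — are
dropped with a warning rather than kept as zero columns, preserving full
column rank; (2) the left/right motor-response regressors are time-locked
to the movement itself (cue onset + RT) rather than to the cue. Locked to
the cue they would reproduce the trial-class partition event for event and
the design would be exactly singular in any session without invalid or
missed trials.

High-pass filtering removes a Gaussian-weighted running-line trend. The
Gaussian width is `sqrt(2·log 2)·cutoff/(2π)` ≈ 18.7 s at the default
100 s cutoff, chosen so the filter has exactly half-amplitude response at
the cutoff frequency (a sine at twice the cutoff period is attenuated by
more than 50%, one at a fifth of the cutoff period passes above 90%). The
same filter must be applied to the data and to the convolved design
columns (`highpass_design()`); unconvolved spikes and confounds are left
alone.

First-level fits are ordinary least squares per session, with no
autocorrelation correction — inference is carried entirely by the group
stage, where per-session contrast values are summarized by a one-sample
*t* test across sessions (sessions as random effects). Zero
between-session variance is reported as a degenerate-variance diagnostic
rather than an infinite *t*.

## ROI BOLD simulator

`simulate_roi_bold()` generates one ROI's series at TR = 1.48 s from a
completed schedule: decision-locked boxcars whose amplitude depends on
congruency, an RT-modulated component, a gamma-convolved fine-grid signal
decimated to TR midpoints, a slow drift (cosines of periods 300–720 s,
all below the high-pass cutoff frequency, so the filter has something to
remove), AR(1) noise driven by white innovations (marginal SD
`noise_sd`, lag-1 autocorrelation `ar1_phi` = 0.3 by default), three
smoothed random-walk confound columns that leak into the signal with
known weights, and optionally a psychophysiological coupling term
`ppi_beta · physio(t) · m(t)`, where `m(t)` is the session's convolved
incongruent-decision regressor — coupling to a source ROI that switches
on with incongruency. The injected parameters ride along as a
`ground_truth` attribute so any downstream estimate can be checked
against them.

What the generator deliberately does *not* emulate: spatial structure
(voxels, smoothing, registration), physiological noise spectra beyond
AR(1), nonlinear HRF saturation, or outcome-locked neural responses.
Passing recovery tests on these series therefore demonstrates the
*statistical machinery* — not robustness to everything real imaging data
can do.

## Time-course procedure

For each session: residualize the series against its confounds, linearly
interpolate to 10 samples per TR (TR sample *i* sits at its interval
midpoint `(i − ½)·TR`, matching the simulator's and design's sampling
convention), cut one epoch per trial from the grid point nearest the
event onset through 7 s, and fit, at every epoch timepoint, a trial-wise
regression of activity on the trial label (direction repetition, or
incongruency) and z-scored RT. Concatenating the label coefficient over
timepoints gives the session's beta time course; the observed statistic
is its mean across sessions. The PPI variant regresses the target ROI on
[incongruency, source activity, incongruency × source], per timepoint,
and tests the interaction.

Significance comes from a within-session permutation: trial labels are
shuffled (counts preserved), everything is refit, session means are
recomputed; 1,000 repetitions form the null. P-values are two-sided with
the add-one estimator `(1 + #{|null| ≥ |obs|})/(1 + n_perm)` — valid under
exchangeability and never exactly zero — computed from the event onset to
the hemodynamic peak (3 s), then Benjamini–Hochberg FDR-corrected across
the timepoints of that window. Across ROI families,
`holm_across_rois()` applies step-down Holm correction; our composition
order is FDR within ROI over timepoints first, Holm across ROIs second,
applied to each ROI's summary p. Only the labels are permuted — RT and
the source ROI's rows stay paired to their trials — so the test targets
the labelled effect while preserving the nuisance structure; permuting
whole rows instead is a defensible alternative the API does not currently
expose.

## Problem sizes and numerical conventions

The test suite and analysis scripts use the study's own scales where the
statistics demand them — 46 sessions × 50 trials for behavioral parameter
recovery (100 replicates, CI coverage checked against 90%), 1,000
permutations in the analysis drivers, 200 permutations × 200 replicates
for type-I calibration — and smaller, 8–16-session versions for the
qualitative BOLD demonstrations. Seeds derive deterministically from a
top-level seed and stream identifiers (session, ROI, purpose), so every
artifact is bit-reproducible. Degenerate inputs fail loudly: constant
trial labels and rank-deficient designs are errors naming the offending
column, constant confounds are dropped with a warning, epochs that run
past the series end exclude the trial with a warning.

## Known limitations

* The linear-probability link can clip: with large weights or strong
  session jitter, generated probabilities saturate and fitted slopes are
  attenuated relative to the nominal weights. Recovery studies should
  keep the linear predictor inside ±1, as the packaged conditions do.
* The high-pass filter is a documented convention, not a bit-exact match
  to any specific neuroimaging toolchain; its frequency response, not its
  implementation, is the contract.
* Mixed-condition accuracy under the reliable-cue convention treats
  either cue as correct on (rare) incongruent trials; analyses of
  incongruency cost therefore use the Face and Object conditions, as the
  accuracy models do.
* Session-level inference ignores first-level serial correlation; with
  AR(1) noise at the simulated level this is conservative-to-neutral for
  the group contrast, but single-session p-values should not be trusted.
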