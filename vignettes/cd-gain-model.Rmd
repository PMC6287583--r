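---
title: "The CD-gain model behind saccadecd: assumptions, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CD-gain model behind saccadecd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(saccadecd)
library(dplyr)
```

## The generative model

`saccadecd` models one double-saccade trial in four steps. With `T1`, `T2`
the target positions (pixels, origin at screen centre, +x right, +y up) and
all noise isotropic Gaussian:

1. **First saccade.** The endpoint is `E1 = g1·T1 + ε1`, where `g1` is a
   multiplicative motor gain (below 1 gives the hypometria typical of
   parkinsonian saccades) and `sd(ε1) = cv·|g1·T1|` — signal-dependent
   motor noise, the standard assumption that endpoint scatter scales with
   intended amplitude.
2. **Internal registration.** The corollary discharge registers the
   displacement as `λ·E1`. The CD gain λ is the package's central
   parameter: λ = 1 is veridical bookkeeping, λ > 1 means the system
   believes it moved further than it did ("amplified" CD), λ < 1 the
   opposite ("diminished" CD).
3. **Second-saccade goal.** The remembered second target is `T2*` — equal to
   `T2` in the visually anchored Baseline condition, `T2` plus memory noise
   (default SD 1°) in the Memory condition. The retinocentric goal is
   `G = T2* − λ·E1`.
4. **Second saccade.** `E2 = E1 + g2·G + ε2`, with the same
   signal-dependent noise rule.

Two consequences drive everything downstream. First, at zero noise the
second-target error is `E2 − T2 = (1 − λ)·E1`, so the error points *toward*
the initial fixation when λ > 1 and *away* from it when λ < 1, and vanishes
identically at λ = 1 — the sign law the test suite checks on every
zero-noise trial. Second, because the ideal second saccade is computed from
the *executed* first-saccade endpoint, trial-to-trial scatter in `E1`
identifies λ separately from plain hypometria: a hypometric but
well-monitored system (g1 < 1, λ = 1) still lands exactly on `T2`.

A deliberate modelling choice: λ multiplies the **executed** first-saccade
vector, not the planned one. The amplified/diminished dichotomy is usually
stated qualitatively; the multiplicative form on the executed movement is
the minimal model in which "overestimating the length of the first saccade"
is a single parameter, and it makes the moment estimator in
`estimate_cd_gain()` exact (`f2 − t2 = (1 − λ)·f1` at `g2 = 1`, hence
`λ̂ = 1 − (f2 − t2)·f1 / |f1|²`). If CD instead copied the *command*, λ
and g1 would trade off and only their product would be identifiable from
endpoint data.

## Task geometry

The screen model is 1024×768 px at 85 Hz viewed from 70 cm, with a fixed
conversion of 22 px/°. The conversion constant is treated as authoritative
rather than derived from monitor size and viewing distance — the two are
not exactly consistent for a 19″ CRT, and all downstream quantities are
reported in pixels of this screen, so the constant is the ground truth.
The first target sits 16° from fixation in one of the four quadrants; its
polar angle within the quadrant is not pinned down by the task description,
so the default is 45° (configurable). The second target lies on the
horizontal meridian on the same side, at one of four candidate positions.
Only the *minimum* spacing of those candidates (≈2.4°) is part of the task
definition; the package places them at exactly 2.4° steps centred under the
first target, again configurable.

All analysis happens after `to_canonical()` reflects every trial into the
upper-right arrangement (x-flip for left-side quadrants, y-flip for lower
ones). The map is an involution and preserves distances and unsigned
angles, so error magnitudes are unaffected; its purpose is purely to let
"inward" mean the same thing on every trial.

## Cohort structure and couplings

`gen_params()` defaults describe the study conditions the package is built
around: 14 patients and 14 age-matched controls, 30 trials per condition
with condition order counterbalanced across subjects, and roughly 6% of
trials invalid (the generator misdirects the first saccade into a random
other quadrant so the screening rule has something to catch; the
behavioural study this emulates excluded 5.8% of real trials).

Patient-specific structure, all configurable:

- **CD gain.** Controls λ = 1.0, patients λ = 1.1 — a modest amplified-CD
  regime, the direction indicated for Parkinson patients. Between-subject
  SD 0.05 on λ and on the motor gains (g1 default 0.9, g2 default 1.0).
- **Striatal binding.** Mean striatal specific binding ratios are drawn at
  2.5 (controls, synthetic scans off by default since controls are not
  scanned) and 1.5 (patients), SD 0.3, with a 0.3 deficit in the hemisphere
  *contralateral* to the symptomatic body side. Symptom laterality is drawn
  8:4:2 left:right:symmetric per 14 patients, and motor MDS-UPDRS at mean
  37, SD 20 — the demographics of the cohort the package emulates.
- **DAT coupling.** The per-subject (cohort-centred) lower-hemisphere mean
  SBR enters λ with slope −0.2 and the motor gains with slope +0.1: lower
  binding means a more amplified CD and more hypometric saccades.
- **Laterality.** On trials whose targets lie on the symptomatic side, λ is
  raised by 0.05 and the gains lowered by 0.03 — worse monitoring toward
  the affected side.

These coupling magnitudes are not printed anywhere in the source material;
they were chosen once as values that produce effects detectable at the
28-subject scale without being caricatures, and the recovery tests treat
them as injected ground truth rather than as quantities to reproduce.

What the generator does **not** emulate: raw gaze samples (input is
fixation-level), main-sequence velocity structure, corrective multi-step
saccades, pupil or blink artefacts, learning or fatigue across trials, and
any medication state. Tests passing on synthetic cohorts therefore
demonstrate that the *estimators recover what the model generates* — they
cannot certify behaviour on real eye-tracking data with richer failure
modes.

## Preprocessing rules

A trial is kept when its first saccade (first inter-fixation displacement
of at least 2°) deviates from the fixation-to-T1 direction by at most 45°,
and some later displacement is directed toward T2 under the same tolerance.
The source description of this screen is qualitative ("directed toward");
the 45° half-angle and 2° minimum amplitude are this package's
operationalisation, exposed as arguments, and validated against the
generator's labels (sensitivity ≥ 0.95 at the defaults). Fixations are then
matched to targets by the closest-fixation rule: `f1` minimises distance to
T1 over the whole trial, `f2` minimises distance to T2 among fixations
*after* `f1`, which keeps the customary return-to-centre fixation from
being selected. Signed errors are fixation minus target in the canonical
frame, giving the convention that hypometric first saccades have negative
errors while hypometric second saccades (stopping above the meridian) have
positive vertical errors.

## Compensation statistic

For each valid trial, the ideal second saccade is the vector from the
executed first-saccade endpoint to the second target; the package reports
its amplitude and absolute direction (`atan2`, degrees CCW from +x in the
canonical frame, range (−180°, 180°]) alongside the executed saccade's. No
reference axis for these angles is inherited from the task; absolute
direction is one consistent choice, and the inward/outward reading is
defined operationally — negative `angle_error = actual − ideal` is a
rotation toward the initial fixation — and validated against the
generator's sign law. Zero-length vectors (first saccade landing exactly on
T2) get amplitude 0, angle `NA`, and a `degenerate` flag rather than an
arbitrary angle.

Predictors are centred before modelling. The default is the grand mean over
the analysis set, matching the single centred predictor the models use;
per-subject centring is available (`center_predictors(..., "subject")`)
because with heterogeneous layouts the two genuinely differ and the choice
is a modelling decision, not a formality.

Laterality coding: with the `symptom_side` reference, targets on the same
screen side as the predominant motor symptoms are `ipsi`. With the
`low_dat_hemisphere` reference, the hemifield-to-hemisphere crossing is
applied exactly once: targets in the hemifield contralateral to the
lower-binding hemisphere are `contra`. Symmetric subjects code as `none`
and are excluded from laterality models (mirroring the restriction of such
analyses to patients with asymmetric symptoms).

## QUEST

The staircase maintains a discretised posterior over the log10
Michelson-contrast threshold on a grid covering the Gaussian prior mean
± 4 SD at 0.01 grain (801 points at the default SD of 1). The likelihood is
a Weibull psychometric function *anchored at the target performance*: the
curve is shifted so that P(correct) is exactly 0.81 at the threshold
parameter, with guess 0.5 (2AFC), slope 3.5 and lapse 0.01. The variant
implemented places each trial at the posterior mean and returns the
posterior mean as the estimate — the mean-QUEST flavour, chosen over
mode/quantile placement for its lower variance at short run lengths. Slope,
lapse, grain and the 64-trial session length are package defaults (the
underlying study does not report its staircase internals) and are all
arguments. The posterior is renormalised after every update and a
degenerate (zero or non-finite mass) update raises an error instead of
silently flattening.

## Inference conventions

All mixed models are fit with `lme4` by REML, at trial level, with the
random structure the paradigm calls for: intercept plus condition slope per
subject for the saccade models, intercept only for the threshold model.
Reported per term: estimate, Wald 95% CI, t value. No p values are
computed; a term is "significant" iff its CI excludes zero. Pruning
(`prune_model()`) iteratively removes the removable term with the smallest
|t| below 2, refitting after each removal, where "removable" respects
marginality — a term is untouchable while any retained higher-order
interaction contains it, and the intercept is never pruned. The one-line
rule this implements does not say whether terms were dropped one at a time
or in blocks; one-at-a-time with refitting is the conservative resolution,
and the recorded trace makes every run auditable. Singular or
non-converged fits are flagged in the result object, never auto-simplified.

Bootstrap CIs resample *subjects* (cluster bootstrap, percentile interval,
1,000 resamples by default) since figure-level error bars in this paradigm
are over participants. The Mann–Whitney implementation reports U, the
tie-corrected normal-approximation Z and a two-sided p, degenerating to
Z = 0, p = 1 when rank variance is zero (e.g. an item scored 0 by
everyone) — `stats::wilcox.test` cross-checks U in the tests but does not
expose Z, which is why the statistic is computed here.

Hemispheric binding ties in `summarize_dat()` are resolved to the left
hemisphere with a warning and a `dat_tie` flag; any downstream laterality
code treats tied subjects as having no asymmetry.

## Problem sizes and numerical tolerances in the test suite

The recovery and coverage studies run 100 simulated cohorts at the full
study scale (14+14 subjects, 30+30 trials); QUEST fidelity uses 100
replicate 64-trial staircases probed 10,000 times each; geometric oracle
equivalence is checked to 1e-9 against an independent complex-arithmetic
oracle on 1,000 random trials; exact-zero claims (veridical regime, λ = 1
sign law) are asserted to 1e-9 absolute. These sizes keep the full suite in
the minutes range on a single CPU while leaving Monte-Carlo margins far
from the pass thresholds.

## Known limitations

- The CD gain is a single scalar per trial; direction-specific or
  amplitude-dependent misestimation is not modelled.
- `estimate_cd_gain()` is exact only at unit second-saccade gain; g2 < 1
  inflates apparent λ. The mixed-model route does not share this
  assumption.
- Wald CIs on lme4 fits are approximate; with 28 subjects their coverage is
  checked empirically (90–98% band) rather than guaranteed.
- The preprocessing tolerances are this package's choices; on real data
  they should be examined against the recording quality, not taken as
  given.
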