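---
title: "Methods: quantifying conditioned-flight ethograms with scsflight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying conditioned-flight ethograms with scsflight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsflight)
library(dplyr)
```

## The paradigm

In serial-compound-stimulus (SCS) flight conditioning, mice learn about a
20 s compound cue made of ten 0.5 s pure-tone pips followed by ten 0.5 s
white-noise (WN) pips at a 1 Hz cycle. In the paired variant the SCS
co-terminates with a 1 s, 0.9 mA footshock, so the tone signals a distal
threat and the WN a proximal one; after two conditioning days, paired animals
freeze to the tone and switch to flight — darting and escape jumping — during
the WN. Control variants decouple cue and shock (unpaired), omit the cue
(shock-only), or invert the pip order (reversed), which moves the WN away
from the shock in time. Five groups result: PA, UN, SO, PA-R, UN-R.

`scsflight` implements the full analysis path for this paradigm: stimulus
schedules, bout segmentation from centroid tracking, trial/period metrics,
and the statistical battery, plus a generative simulator for validation.

## Stimulus schedules

Sessions are laid out as baseline, stimulus blocks separated by pseudorandom
inter-stimulus intervals (ISIs), and a tail. Published totals are enforced
exactly: 590 s (pre-exposure: 180 s baseline, 4 SCS, ISI 90–100 s, 40 s
tail), 820 s (conditioning days; PA/PA-R: 5 SCS+shock, ISI 90–150 s, 60 s
tail; UN/UN-R: 5 SCS and 5 shocks interleaved, gaps 40–60 s, 90 s tail; SO:
5 shocks, ISI 120–160 s, 80 s tail) and 1910 s (extinction: 16 SCS, ISI
60–120 s, 50 s tail).

Three layout choices were genuinely open and are fixed as follows:

* **ISI placement.** Only session totals and ISI ranges are published, not
  gap-by-gap values. We treat the `n − 1` gaps *between* consecutive stimulus
  blocks as the ISIs (the pre-exposure arithmetic confirms this reading:
  180 + 4×20 + 3 gaps summing to 290 + 40 = 590 is feasible for 3 gaps of
  90–100 s but not 4). Gaps are drawn uniformly from the range and then
  jointly shifted — proportionally to each gap's slack — until their sum hits
  the value the total forces, so every gap stays in range and the total is
  exact for any seed.
* **Paired shock placement.** "Co-terminating" is implemented as the shock
  occupying `[scs_onset + 19, scs_onset + 20)`, overlapping the final pip
  cycle and ending exactly at SCS offset.
* **Unpaired ordering.** The exact unpaired sequences are unpublished; what
  is stated is that the SCS could not reliably predict shock. We randomize
  the order of the 5 SCS and 5 shock blocks per seed, rejecting perfectly
  predictive orders (every SCS immediately followed by a shock), and verify a
  guard gap: no shock onset falls within 20 s of an SCS offset (the 40 s
  minimum gap makes this structural). CD1 and CD2 derive distinct sub-seeds
  from one seed, so stimulus timing differs between conditioning days.

All times are real-valued seconds from session start; every window is
half-open `[start, end)`. Pip duration is 0.5 s (one source line prints
"0.5 ms", which is physically implausible for a 1 Hz pip train and is treated
as a typo).

## Bout definitions and detectors

* **Freezing** — complete cessation of movement for ≥ 1 s. Commercial
  trackers score this from proprietary pixel-change statistics; we re-base it
  on centroid speed: maximal runs of frames with `v < eps` (default
  `eps = 0.5` cm/s), keeping runs of at least 1 s. `eps` is a documented
  operational default, not a published constant — the original scoring was
  observer-confirmed, so the noise floor is ours to fix.
* **Darting** — a rapid horizontal burst from rest back to rest with a
  minimum duration of 8 frames (266 ms at 30 frames/s). The original
  analysis used a trained random-forest classifier; its probability cutoff
  is classifier-specific and not portable, but the verbal bout definition
  (accelerate from rest, end at the last frame before a full stop) maps
  directly onto a two-threshold hysteresis rule: arm below `v_stop`
  (4 cm/s), open above `v_start` (10 cm/s), close at the last frame before
  speed returns below `v_stop`.
* **Jumps and tail rattles** — consumed as manual-annotation channels
  (`airborne`, `tail_rattle`): a 2-D centroid cannot certify "all four paws
  off the floor" or tail-tip vibration, so inferring them kinematically is a
  non-goal. Maximal runs of 1 become bouts; a jump's event time is its start.

Detectors are validated two ways: exact equivalence with brute-force
frame-scan oracles on fuzzed speed series, and interval-overlap F1 ≥ 0.9
against the simulator's ground-truth bouts at default parameters.

## Metrics

Speed is `calibration × frame-to-frame centroid displacement × fps` (cm/s),
unsmoothed; the first frame copies the second so series lengths match frame
counts. Distance traveled integrates 0.5 s-binned mean speed over a window.
Per trial, the windows are the 10 s pre-SCS period, the 10 s tone and WN
periods (named by stimulus content, so a reversed SCS has its WN window
first) and the 1 s shock where present.

The **activity index** for a CS window is
`mean speed in window / mean speed pooled over all pre-SCS windows of the
session + number of jumps starting in the window`. The session-pooled
denominator avoids near-zero per-trial denominators; we additionally floor
it at 0.1 cm/s (flagged in output) since a fully motionless session would
otherwise still divide by ~0. A score of 1 with no jumps means "no change
from baseline locomotion".

Difference scores (`mean of first k trials − mean of last k`, default
`k = 4`) carry their sign convention as an attribute; positive means a
decrease over the session. Cohort percentages count animals with ≥ 1 bout
starting in the listed windows. Event histograms bin bout starts into 1 s
bins (one per pip for a 10 s stimulus period), half-open so an edge event
belongs to the later bin. For frequency-based comparisons a seeded 20-animal
subsample matches the large paired group to the smaller controls. Shock
windows are extended 1 s past shock offset for jump/dart counts only, since
startle reactions trail the stimulus; the exact reaction window is not
published and this choice is recorded here.

## The simulator

The generator is a semi-Markov behavioral-state process over
{freeze, locomote, dart, jump}. A state table indexed by (group, session,
period, trial) holds target *occupancies* (fractions of period time); at each
decision point a state is drawn with probability proportional to
`occupancy / E[dwell]`, which by renewal-reward makes realized time fractions
converge to the configured occupancies, and a dwell is sampled with per-state
minima so bouts are well defined (freeze ≥ 1 s; dart 12–18 frames, above the
8-frame detector minimum; jump 8–12 frames; locomote ≥ 0.2 s). Trial
dependence uses logistic curves in the trial index (acquisition of tone
freezing across conditioning, extinction of jumping by mid-Ext1, the rise of
WN freezing across extinction).

Emissions per state: freezing is sub-`eps` jitter (0.02–0.25 cm/s);
locomotion is an AR(1) speed process (autocorrelation time 0.2 s, sd
1.2 cm/s) clipped to [0.8, 9.5] cm/s — above `eps` and below the dart opening
threshold, so the locomote state can produce neither spurious freezes nor
spurious darts; darts are raised-sine speed bursts (peak 22–32 cm/s) whose
endpoints sit below `v_stop`, aimed at a random interior point of the arena;
jumps set the airborne channel with modest horizontal drift. Positions live
in the square inscribed in the 30 cm arena (calibration 1/15 cm/px, i.e. a
~450 px arena in a 640×480 field of view), with reflective folding at the
square's edges; trajectories therefore never leave the arena. Consecutive
same-state segments merge into one ground-truth bout, except darts, which end
at a full stop by definition and therefore stay distinct.

Tail rattling is overlaid as a Poisson bout process (per-period rates,
highest for UN/SO/UN-R during extinction tones), since it is an annotation
channel rather than a kinematic state.

**Calibration.** The source figures report rasters, cohort percentages and
group summary statistics, not per-trial generative rates, so the shipped
occupancies are calibration choices: they encode the qualitative group
profiles (PA: rising tone freezing, WN darting/jumping on CD2, extinction of
flight with a freezing handover; UN/SO: elevated WN locomotion, near-zero
flight; PA-R: persistent tone freezing, almost no WN jumping; UN-R: UN-like)
and were tuned once so that the full pipeline on simulated CD2 cohorts
reproduces the published group-level WN activity-index means (PA n = 32,
UN n = 20) within one published SEM, then frozen. What passing those checks
shows is that the pipeline's measurements are consistent end-to-end — not
that real mice obey a semi-Markov process. Real tracking data differ in ways
the generator deliberately ignores: posture, thigmotaxis, camera noise,
occlusions, drift in calibration, and within-trial timing structure (e.g.
jump latencies locked to pip onsets).

## Statistics

Welch's unpaired t, one-way ANOVA with Tukey HSD, and two-way fixed-effects
(trial × group) ANOVA are delegated to the standard R routines (`t.test`,
`aov`/`TukeyHSD`, and Type II sums of squares via `car::Anova` for unbalanced
cells — the published analyses do not state the SS type; Type II is the
documented choice here, reported in the output). Trial is treated as an
ordinary fixed factor without repeated-measures correlation, matching the
published ordinary two-way ANOVAs; mixed models are out of scope. Degenerate
inputs (all values identical) return F = 0, p = 1 by convention rather than
dividing rounding noise by rounding noise. The test wrappers are validated
against textbook-formula and sums-of-squares oracles and, under null
simulation, reject at ~5% at α = 0.05.

## Validation problem sizes

The shipped validation suite simulates: CD2 cohorts of 32 (PA) and 20 (UN)
animals for the activity-index reproduction; 50 animals per occupancy level
(p = 0.1, 0.5, 0.9, ~160 s custom sessions) for parameter recovery within 3
percentage points; 32-animal PA cohorts for CD2/Ext1/Ext2 ethogram-shape
checks; 1000 fuzzed series for detector-oracle equivalence; and 2000
replicates for null-rejection calibration. These sizes give Monte-Carlo
error comfortably inside the asserted tolerances while keeping the suite
quick to run.

## Known limitations

* Jumps and tail rattles are annotation-driven; datasets without those
  channels get zero counts, not inferred events.
* The dart rule is deterministic and kinematic; it will not reproduce a
  specific classifier's borderline decisions.
* Published real-data F/t/p values cannot be reproduced without the original
  per-animal spreadsheets; the statistical layer is validated by calibration
  and oracles instead.
* The simulator draws states independently across animals; litter, sex and
  cohort effects are not modeled (sex is a label only).
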