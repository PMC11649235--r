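# scsflight

Defensive-ethogram analysis for serial-compound-stimulus (SCS) conditioned
flight in mice.

In SCS flight conditioning, a 20 s compound cue — ten 0.5 s tone pips
followed by ten 0.5 s white-noise (WN) pips at 1 Hz — co-terminates with a
1 s, 0.9 mA footshock. Conditioned animals freeze during the tone (distal
threat) and switch to flight (darting, escape jumping) during the WN
(proximal threat); unpaired, shock-only and reversed-SCS controls dissect
the associative and non-associative contributions to that switch. This
package is for behavioral neuroscientists who have centroid tracking time
series from such experiments (or want to prototype analyses before
collecting them) and need the full quantitative path from raw tracking to
statistics:

* **Schedules** — pip-level stimulus event tables for all five session
  variants (pre-exposure 590 s; conditioning days 820 s; extinction days
  1910 s), with pseudorandom ISIs that hit the published totals exactly.
* **Kinematics** — pixel-to-cm calibration, centroid speed
  (`v = calibration · ||Δp|| · fps`), distance as the area under 0.5 s-binned
  speed.
* **Bout detection** — freezing (speed < ε for ≥ 1 s, default ε = 0.5 cm/s),
  darting (two-threshold hysteresis: arm < 4 cm/s, open > 10 cm/s, close at
  the last frame before returning below 4 cm/s; ≥ 8 frames = 266 ms at
  30 fps), jumps and tail rattles from annotation channels.
* **Metrics** — per-trial/period percent freezing, the activity index
  `Speed_CS / Speed_avg pre-SCS + Jumps`, peri-stimulus 1 s event
  histograms, first-4-vs-last-4 difference scores, pre-SCS-vs-tone
  differences, cohort percentages, seeded 20-animal subsampling.
* **Statistics** — Welch t, one-way ANOVA + Tukey HSD, two-way
  (trial × group) fixed-effects ANOVA with Type II SS, with broom-style
  `tidy()`/`glance()` methods, plus report/plot helpers.
* **Simulator** — a seeded semi-Markov behavioral-state generator whose
  group/session/period/trial occupancy tables emulate the five groups'
  ethograms, emitting bounded 2-D trajectories at 30 frames/s with
  ground-truth bouts, so the entire pipeline is testable end to end.

Everything is data-frame-first and pipe-friendly: trajectories, bouts,
windows and metrics are tibbles.

## Worked example

Simulate a small paired-group cohort on conditioning day 2 and run the full
pipeline (speed → detectors → metrics):

```r
library(scsflight)
library(dplyr)

sched <- build_schedule(session_spec("CD2", "PA", seed = 7))
sched
#> <scs_schedule> CD2 / PA (standard SCS): 5 trials, 5 shocks, 820 s total

co <- simulate_cohort("PA", 8, "CD2", seed = 42)
m <- cohort_metrics(co)

m |>
  filter(period %in% c("tone", "wn"), trial_index > 0) |>
  group_by(period, trial_index) |>
  summarise(freezing = mean(percent_freezing),
            activity = mean(activity_index), .groups = "drop")
#>    period trial_index freezing activity
#>  1 tone             1    63.7     1.47
#>  2 tone             2    75.8     0.942
#>  3 tone             3    84.9     0.742
#>  4 tone             4    90.0     0.485
#>  5 tone             5    90.6     0.457
#>  6 wn               1    10.9    14.3
#>  7 wn               2     5.47   13.7
#>  8 wn               3     9.83   13.7
#>  9 wn               4    12.7    12.4
#> 10 wn               5    12.8    12.2
```

The shape is the conditioned-flight signature: freezing dominates the tone
period and climbs across trials while the tone-period activity index falls
below 1 (less movement than the pre-SCS baseline); the WN period shows
little freezing but activity indices far above 1, driven by darting speed
bursts plus escape jumps (each jump adds 1 to the score).

Group comparisons use the same battery as the published analyses:

```r
m |>
  filter(period == "wn", trial_index > 0) |>
  group_by(animal_id, group) |>
  summarise(ai = mean(activity_index), .groups = "drop") |>
  welch_t(ai, group)   # after adding a control cohort with simulate_cohort()
```

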