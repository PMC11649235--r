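#' Analysis windows of a session schedule
#'
#' Expands a schedule into the per-trial, per-period half-open windows the
#' behavioral metrics are computed over: per trial a 10 s `pre_scs` window
#' ending at SCS onset, a 10 s `tone` window and a 10 s `wn` window (named by
#' stimulus content, so for reversed-SCS schedules the first half of the SCS is
#' `wn` and the second `tone`), a 1 s `shock` window where a shock is present,
#' plus one `baseline` window covering `[0, baseline)`. Shocks not tied to a
#' trial (unpaired/shock-only sessions) appear as `shock` windows with
#' `trial_index == 0`.
#'
#' @param schedule An `scs_schedule` from [build_schedule()].
#' @return A tibble with columns `trial_index`, `period`, `start_s`, `end_s`,
#'   sorted by start.
#' @export
period_windows <- function(schedule) {
  stopifnot(inherits(schedule, "scs_schedule"))
  sp <- schedule$spec
  out <- list(tibble(trial_index = 0L, period = "baseline", start_s = 0,
                     end_s = sp$baseline))
  if (length(schedule$scs_onsets)) {
    if (min(schedule$scs_onsets) < 10) {
      stop_scsflight("First SCS begins less than 10 s into the session; no pre-SCS window fits.",
                     "scsflight_windowing_error")
    }
    first_half <- if (sp$variant == "standard") "tone" else "wn"
    second_half <- if (sp$variant == "standard") "wn" else "tone"
    on <- schedule$scs_onsets
    tr <- seq_along(on)
    out <- c(out, list(
      tibble(trial_index = tr, period = "pre_scs", start_s = on - 10, end_s = on),
      tibble(trial_index = tr, period = first_half, start_s = on, end_s = on + 10),
      tibble(trial_index = tr, period = second_half, start_s = on + 10,
             end_s = on + 20)
    ))
  }
  shocks <- schedule$events[schedule$events$kind == "shock", ]
  if (nrow(shocks)) {
    out <- c(out, list(
      tibble(trial_index = as.integer(shocks$trial_index), period = "shock",
             start_s = shocks$onset_s, end_s = shocks$onset_s + shocks$duration_s)
    ))
  }
  arrange(bind_rows(out), .data$start_s)
}

overlap_len <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
}

#' Percent time freezing within a window
#'
#' 100 x (total overlap of freeze bouts with `[start, end)`) / window length;
#' bouts straddling the window edges contribute only their overlap.
#'
#' @param bouts A [bouts] tibble (only `behavior == "freeze"` rows are used).
#' @param start,end Window bounds in seconds.
#' @return Percentage in `[0, 100]`.
#' @export
percent_freezing <- function(bouts, start, end) {
  if (end <= start) {
    stop_scsflight("Zero-length window.", "scsflight_input_error")
  }
  fb <- bouts[bouts$behavior == "freeze", ]
  if (!nrow(fb)) return(0)
  100 * sum(overlap_len(fb$start_s, fb$end_s, start, end)) / (end - start)
}

#' Session-wide average pre-SCS speed (activity-index denominator)
#'
#' Pools per-frame speeds over all `pre_scs` windows of the session and takes
#' their mean. To avoid near-zero denominators in the activity index, results
#' below `floor` are replaced by `floor` and flagged.
#'
#' @param speed A `speed_series`.
#' @param windows Output of [period_windows()] (needs `pre_scs` rows).
#' @param floor Denominator floor in cm/s (default 0.1).
#' @return A single number with attribute `floored` (`TRUE` if substituted).
#' @export
pre_scs_average_speed <- function(speed, windows, floor = 0.1) {
  pw <- windows[windows$period == "pre_scs", ]
  if (!nrow(pw)) {
    stop_scsflight("No pre-SCS windows in `windows`.", "scsflight_input_error")
  }
  sel <- rep(FALSE, nrow(speed))
  for (i in seq_len(nrow(pw))) {
    sel <- sel | (speed$t_s >= pw$start_s[i] & speed$t_s < pw$end_s[i])
  }
  m <- mean(speed$v_cms[sel])
  if (is.na(m) || m < floor) {
    structure(floor, floored = TRUE)
  } else {
    structure(m, floored = FALSE)
  }
}

#' Activity index for one CS window
#'
#' The activity index combines cue-induced locomotion with escape jumping:
#' (mean speed during the tone or white-noise window) / (session-wide average
#' pre-SCS speed) + (number of jump bouts starting within the window). A score
#' of 1 with no jumps means locomotion unchanged from the pre-SCS baseline.
#'
#' @param speed A `speed_series`.
#' @param jumps A [bouts] tibble (only `behavior == "jump"` rows are used).
#' @param start,end CS window bounds in seconds.
#' @param denom Positive denominator in cm/s, normally from
#'   [pre_scs_average_speed()].
#' @return The dimensionless activity-index score.
#' @export
activity_index <- function(speed, jumps, start, end, denom) {
  if (!is.numeric(denom) || length(denom) != 1L || denom <= 0) {
    stop_scsflight("`denom` must be a single positive speed.",
                   "scsflight_input_error")
  }
  ms <- mean_speed(speed, start, end)
  if (is.na(ms)) ms <- 0
  jb <- jumps[jumps$behavior == "jump", ]
  nj <- sum(jb$start_s >= start & jb$start_s < end)
  ms / denom + nj
}

#' Peri-stimulus event histogram
#'
#' Counts bout start times in consecutive half-open bins across a window (1 s
#' bins across a 10 s stimulus period give one bin per pip). An event exactly
#' on a bin edge belongs to the later bin.
#'
#' @param bouts A [bouts] tibble.
#' @param start,end Window bounds in seconds; `bin_width` must divide the
#'   window length.
#' @param bin_width Bin width in seconds (default 1).
#' @param behavior Optional behavior to restrict to (e.g. `"jump"`).
#' @return A tibble with `bin_start_s`, `bin_end_s`, `count`.
#' @export
bin_events <- function(bouts, start, end, bin_width = 1.0, behavior = NULL) {
  len <- end - start
  nb <- len / bin_width
  if (abs(nb - round(nb)) > 1e-9 || nb < 1) {
    stop_scsflight("`bin_width` must evenly divide the window length.",
                   "scsflight_input_error")
  }
  nb <- as.integer(round(nb))
  if (!is.null(behavior)) bouts <- bouts[bouts$behavior == behavior, ]
  ev <- bouts$start_s[bouts$start_s >= start & bouts$start_s < end]
  idx <- pmin(floor((ev - start) / bin_width), nb - 1L) + 1L
  counts <- tabulate(idx, nbins = nb)
  tibble(bin_start_s = start + (seq_len(nb) - 1L) * bin_width,
         bin_end_s = start + seq_len(nb) * bin_width,
         count = counts)
}

#' First-k minus last-k trial difference score
#'
#' Summarizes within-session change of a per-trial series as
#' `mean(first k) - mean(last k)`. With `orientation = "decrease"` (the
#' default) a positive score means the measure decreased over the session;
#' `"increase"` flips the sign.
#'
#' @param values Numeric per-trial series in trial order (length >= `2k`).
#' @param k Trials per bin (default 4).
#' @param orientation `"decrease"` or `"increase"`.
#' @return A single difference with attribute `orientation`.
#' @export
diff_score <- function(values, k = 4L, orientation = c("decrease", "increase")) {
  orientation <- match.arg(orientation)
  n <- length(values)
  if (n < 2 * k) {
    stop_scsflight("Series must hold at least 2k trials.", "scsflight_input_error")
  }
  d <- mean(values[seq_len(k)]) - mean(values[seq.int(n - k + 1L, n)])
  if (orientation == "increase") d <- -d
  structure(d, orientation = orientation)
}

#' Per-animal pre-SCS versus CS-period freezing difference
#'
#' For each animal: the mean over trials of (CS-period percent freezing minus
#' pre-SCS percent freezing), quantifying how much the cue elevates freezing
#' over the contextual level.
#'
#' @param metrics A trial-metrics tibble (see [trial_metrics()]) holding both
#'   `pre_scs` rows and rows for `period`.
#' @param period CS period to compare against, `"tone"` or `"wn"`.
#' @return A tibble with `animal_id` and `diff` (percentage points).
#' @export
pre_vs_cs_diff <- function(metrics, period = c("tone", "wn")) {
  period <- match.arg(period)
  pre <- metrics[metrics$period == "pre_scs" & metrics$trial_index > 0, ]
  cs <- metrics[metrics$period == period & metrics$trial_index > 0, ]
  key <- c("animal_id", "session", "trial_index")
  j <- dplyr::inner_join(
    cs[, c(key, "percent_freezing")],
    pre[, c(key, "percent_freezing")],
    by = key, suffix = c("_cs", "_pre"))
  if (nrow(j) != nrow(cs) || nrow(j) != nrow(pre)) {
    stop_scsflight("pre-SCS and CS-period trials do not match one-to-one.",
                   "scsflight_input_error")
  }
  j |>
    group_by(.data$animal_id) |>
    summarise(diff = mean(.data$percent_freezing_cs - .data$percent_freezing_pre),
              .groups = "drop")
}

#' Percentage of a cohort expressing a behavior
#'
#' 100 x (number of animals with at least one bout of `behavior` starting
#' inside any of the listed windows) / (number of animals).
#'
#' @param bouts_by_animal A named list of [bouts] tibbles, one per animal, or
#'   a single tibble with an `animal_id` column.
#' @param windows Tibble with `start_s`, `end_s` rows (e.g. the `wn` rows of
#'   [period_windows()]).
#' @param behavior Behavior to score (e.g. `"jump"`).
#' @return Percentage in `[0, 100]`.
#' @export
cohort_percentage <- function(bouts_by_animal, windows, behavior) {
  if (is.data.frame(bouts_by_animal)) {
    bouts_by_animal <- split(bouts_by_animal,
                             bouts_by_animal$animal_id)
  }
  if (!length(bouts_by_animal)) {
    stop_scsflight("Empty cohort.", "scsflight_input_error")
  }
  hit <- vapply(bouts_by_animal, function(b) {
    b <- b[b$behavior == behavior, ]
    if (!nrow(b)) return(FALSE)
    any(vapply(seq_len(nrow(windows)), function(i) {
      any(b$start_s >= windows$start_s[i] & b$start_s < windows$end_s[i])
    }, logical(1)))
  }, logical(1))
  100 * mean(hit)
}

#' Seeded subsample of a cohort
#'
#' Draws `n` animals uniformly without replacement, reproducibly for a given
#' seed (used to match a larger group's population size to smaller control
#' groups before frequency-based comparisons).
#'
#' @param animals Vector of animal identifiers.
#' @param n Subsample size (default 20).
#' @param seed Integer seed.
#' @return A vector of `n` distinct identifiers.
#' @export
subsample_cohort <- function(animals, n = 20L, seed = 1L) {
  if (n > length(animals)) {
    stop_scsflight("`n` exceeds the cohort size.", "scsflight_input_error")
  }
  withr::local_seed(sub_seed(seed, 77L))
  sample(animals, n)
}

#' Per-trial, per-period metrics for one animal-session
#'
#' Aligns bouts and kinematics to the schedule and computes, for every window
#' of [period_windows()]: percent freezing, activity index (tone/wn windows
#' only), jump/dart/tail-rattle counts (bout starts inside the window; shock
#' windows are extended 1 s beyond shock offset for the counts, capturing
#' immediate reactions), distance traveled and mean speed.
#'
#' @param traj A [trajectory()].
#' @param bouts A [bouts] tibble, e.g. from [detect_bouts()].
#' @param schedule The session's `scs_schedule`.
#' @param animal_id,group,sex,session Identifier columns copied into the
#'   output.
#' @param floor Denominator floor passed to [pre_scs_average_speed()].
#' @return A tibble, one row per (trial, period), with columns `animal_id`,
#'   `group`, `sex`, `session`, `trial_index`, `period`, `percent_freezing`,
#'   `activity_index`, `jumps`, `darts`, `tail_rattles`, `distance_cm`,
#'   `mean_speed_cms`, `denom_floored`.
#' @export
trial_metrics <- function(traj, bouts, schedule, animal_id = "a1",
                          group = schedule$spec$group,
                          sex = NA_character_,
                          session = schedule$spec$session,
                          floor = 0.1) {
  speed <- compute_speed(traj)
  windows <- period_windows(schedule)
  has_pre <- any(windows$period == "pre_scs")
  denom <- if (has_pre) pre_scs_average_speed(speed, windows, floor) else
    structure(NA_real_, floored = FALSE)
  count_in <- function(beh, start, end) {
    b <- bouts[bouts$behavior == beh, ]
    sum(b$start_s >= start & b$start_s < end)
  }
  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    cs <- w$period %in% c("tone", "wn")
    # reaction window for event counts: shocks get +1 s beyond offset
    cend <- if (w$period == "shock") w$end_s + 1 else w$end_s
    tibble(
      trial_index = w$trial_index, period = w$period,
      percent_freezing = percent_freezing(bouts, w$start_s, w$end_s),
      activity_index = if (cs && has_pre)
        activity_index(speed, bouts, w$start_s, w$end_s, as.numeric(denom))
      else NA_real_,
      jumps = count_in("jump", w$start_s, cend),
      darts = count_in("dart", w$start_s, cend),
      tail_rattles = count_in("tail_rattle", w$start_s, cend),
      distance_cm = distance_traveled(speed, w$start_s, w$end_s),
      mean_speed_cms = {
        ms <- mean_speed(speed, w$start_s, w$end_s)
        if (is.na(ms)) 0 else ms
      }
    )
  })
  bind_rows(rows) |>
    mutate(animal_id = animal_id, group = group, sex = sex, session = session,
           denom_floored = attr(denom, "floored"), .before = 1)
}

#' Metrics table for a simulated cohort
#'
#' Runs the detector + metrics pipeline over every animal-session row of a
#' [simulate_cohort()] result.
#'
#' @param cohort Nested tibble from [simulate_cohort()].
#' @param ... Passed to [detect_bouts()] (detector thresholds).
#' @return A combined [trial_metrics()] tibble.
#' @export
cohort_metrics <- function(cohort, ...) {
  purrr::pmap(list(cohort$trajectory, cohort$schedule, cohort$animal_id,
                   cohort$group, cohort$sex, cohort$session),
              function(traj, sched, id, grp, sx, sess) {
                b <- detect_bouts(traj, ...)
                trial_metrics(traj, b, sched, animal_id = id, group = grp,
                              sex = sx, session = sess)
              }) |>
    bind_rows()
}

#' Read / write metrics tables
#' @param metrics A [trial_metrics()] tibble.
#' @param path File path.
#' @export
write_metrics <- function(metrics, path) {
  readr::write_csv(metrics, path)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
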