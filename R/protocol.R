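#' Pip events of a single serial compound stimulus (SCS)
#'
#' The SCS is a 20 s compound cue of twenty 0.5 s auditory pips presented at a
#' 1 Hz cycle: ten pips of pure tone followed by ten pips of white noise
#' (`variant = "standard"`), or the inverted order (`variant = "reversed"`).
#' Pip `i` (0-based) starts `i` seconds after the SCS onset, so the SCS spans
#' the half-open interval `[onset, onset + 20)`.
#'
#' @param onset SCS onset in seconds from session start (>= 0).
#' @param variant `"standard"` (tone then white noise) or `"reversed"`.
#' @param trial_index 1-based trial number attached to every pip.
#' @return A tibble of 20 stimulus events with columns `kind`
#'   (`"tone_pip"`/`"wn_pip"`), `onset_s`, `duration_s`, `trial_index`.
#' @examples
#' scs_events(0, "standard", 1)
#' @export
scs_events <- function(onset, variant = c("standard", "reversed"), trial_index = 1L) {
  variant <- match.arg(variant)
  if (!is.numeric(onset) || length(onset) != 1L || is.na(onset) || onset < 0) {
    stop_scsflight("`onset` must be a single non-negative number of seconds.",
                   "scsflight_input_error")
  }
  kinds <- if (variant == "standard") {
    c(rep("tone_pip", 10L), rep("wn_pip", 10L))
  } else {
    c(rep("wn_pip", 10L), rep("tone_pip", 10L))
  }
  tibble(
    kind = kinds,
    onset_s = onset + 0:19,
    duration_s = 0.5,
    trial_index = as.integer(trial_index)
  )
}

#' Built-in session specification
#'
#' Returns the published layout of one session of the conditioning/extinction
#' paradigm for a given group. All five groups share session totals:
#' pre-exposure 590 s, each conditioning day 820 s, each extinction day 1910 s.
#' Groups differ in what happens after the 180 s baseline on conditioning days:
#' paired groups (PA, PA-R) get five SCS presentations each co-terminating with
#' a 1 s, 0.9 mA footshock (ISI 90-150 s, 60 s tail); unpaired groups (UN,
#' UN-R) get five SCS and five shocks interleaved non-predictively (gaps
#' 40-60 s, 90 s tail); the shock-only group (SO) gets five shocks and no SCS
#' (ISI 120-160 s, 80 s tail). Pre-exposure is four SCS, ISI 90-100 s, 40 s
#' tail; extinction is sixteen SCS, ISI 60-120 s, 50 s tail, for every group
#' (SO included). Reversed groups use the reversed pip order at identical
#' timing.
#'
#' @param session One of `"PreExp"`, `"CD1"`, `"CD2"`, `"Ext1"`, `"Ext2"`.
#' @param group One of `"PA"`, `"UN"`, `"SO"`, `"PA_R"`, `"UN_R"`.
#' @param seed Integer seed controlling pseudorandom ISI draws (and, for
#'   unpaired groups, stimulus order). CD1 and CD2 derive distinct sub-seeds
#'   from it so stimulus timing differs between the two conditioning days.
#' @return A `session_spec` list with fields `session`, `group`, `variant`,
#'   `baseline`, `n_trials`, `n_shocks`, `paired`, `isi_range`, `tail`,
#'   `total`, `seed`.
#' @examples
#' session_spec("CD2", "PA", seed = 7)
#' @export
session_spec <- function(session = c("PreExp", "CD1", "CD2", "Ext1", "Ext2"),
                         group = c("PA", "UN", "SO", "PA_R", "UN_R"),
                         seed = 1L) {
  session <- match.arg(session)
  group <- match.arg(group)
  variant <- if (group %in% c("PA_R", "UN_R")) "reversed" else "standard"
  base <- list(session = session, group = group, variant = variant,
               baseline = 180, seed = as.integer(seed))
  spec <- switch(
    session,
    PreExp = c(base, list(n_trials = 4L, n_shocks = 0L, paired = FALSE,
                          isi_range = c(90, 100), tail = 40, total = 590)),
    CD1 = ,
    CD2 = switch(
      group,
      PA = ,
      PA_R = c(base, list(n_trials = 5L, n_shocks = 5L, paired = TRUE,
                          isi_range = c(90, 150), tail = 60, total = 820)),
      UN = ,
      UN_R = c(base, list(n_trials = 5L, n_shocks = 5L, paired = FALSE,
                          isi_range = c(40, 60), tail = 90, total = 820)),
      SO = c(base, list(n_trials = 0L, n_shocks = 5L, paired = FALSE,
                        isi_range = c(120, 160), tail = 80, total = 820))
    ),
    Ext1 = ,
    Ext2 = c(base, list(n_trials = 16L, n_shocks = 0L, paired = FALSE,
                        isi_range = c(60, 120), tail = 50, total = 1910))
  )
  structure(spec, class = "session_spec")
}

#' Custom session specification
#'
#' Build a non-published session layout (used mainly for tests and simulator
#' experiments). `total` defaults to the midpoint-feasible value
#' `baseline + stimulus time + mean ISI * gaps + tail`.
#'
#' @inheritParams session_spec
#' @param baseline,tail Seconds before the first / after the last stimulus.
#' @param n_trials Number of SCS presentations.
#' @param n_shocks Number of footshocks (paired: one per trial).
#' @param paired If `TRUE`, each shock co-terminates with its trial's SCS.
#' @param isi_range Length-2 numeric, `[min, max]` seconds between stimuli.
#' @param variant Pip order, `"standard"` or `"reversed"`.
#' @param total Session length in seconds; ISIs are adjusted to hit it exactly.
#' @export
custom_spec <- function(baseline = 60, n_trials = 2L, n_shocks = 0L,
                        paired = FALSE, isi_range = c(30, 60), tail = 30,
                        total = NULL, variant = "standard",
                        session = "custom", group = "custom", seed = 1L) {
  n_stim <- n_trials + if (paired) 0L else n_shocks
  stim_time <- n_trials * 20 + (if (paired) 0 else n_shocks) * 1
  n_gaps <- max(n_stim - 1L, 0L)
  if (is.null(total)) total <- baseline + stim_time + n_gaps * mean(isi_range) + tail
  structure(list(session = session, group = group, variant = variant,
                 baseline = baseline, n_trials = as.integer(n_trials),
                 n_shocks = as.integer(n_shocks), paired = paired,
                 isi_range = isi_range, tail = tail, total = total,
                 seed = as.integer(seed)),
            class = "session_spec")
}

# Draw n gaps uniformly from range, then move them (proportionally to the
# slack each gap has toward the needed direction) so they sum to `target`
# exactly while staying inside the range.
draw_gaps <- function(n, range, target) {
  if (n == 0L) {
    if (abs(target) > 1e-9) {
      stop_scsflight("Schedule needs a nonzero inter-stimulus total but has no gaps.",
                     "scsflight_constraint_error")
    }
    return(numeric(0))
  }
  lo <- range[1]; hi <- range[2]
  if (target < n * lo - 1e-9 || target > n * hi + 1e-9) {
    stop_scsflight(
      sprintf(paste0("ISI range [%g, %g] cannot reach the required gap total of ",
                     "%.3f s with %d gaps (feasible: [%g, %g] s)."),
              lo, hi, target, n, n * lo, n * hi),
      "scsflight_constraint_error")
  }
  g <- runif(n, lo, hi)
  for (i in 1:50) {
    d <- target - sum(g)
    if (abs(d) < 1e-12) break
    slack <- if (d > 0) hi - g else g - lo
    if (sum(slack) <= 0) break
    g <- g + d * slack / sum(slack)
    g <- pmin(pmax(g, lo), hi)
  }
  # final exact touch-up on the gap with the most room
  d <- target - sum(g)
  i <- if (d > 0) which.max(hi - g) else which.max(g - lo)
  g[i] <- g[i] + d
  g
}

# unpaired stimulus order: random interleave of S (SCS) and K (shock) blocks,
# rejected if every SCS is immediately followed by a shock (perfectly
# predictive) or the sequence is a strict alternation starting with SCS
unpaired_order <- function(n_scs, n_shock) {
  stopifnot(n_scs >= 1, n_shock >= 1)
  repeat {
    ord <- sample(c(rep("scs", n_scs), rep("shock", n_shock)))
    after <- ord[which(ord == "scs") + 1L]
    predictive <- all(!is.na(after) & after == "shock")
    if (!predictive) return(ord)
  }
}

#' Build the full stimulus schedule for one session
#'
#' Lays out one session as: baseline, then the group's stimulus blocks
#' separated by pseudorandom inter-stimulus intervals (ISIs) drawn from the
#' spec's range, then a tail. The drawn ISIs are jointly adjusted (staying
#' within the stated range) so the session length equals the published total
#' exactly. Paired variants place each 1 s shock in `[scs_onset + 19,
#' scs_onset + 20)`, co-terminating with the SCS; unpaired variants interleave
#' SCS and shock blocks in a per-seed randomized, non-predictive order with a
#' guard gap between any SCS offset and the next shock onset; the shock-only
#' layout has shocks and no SCS.
#'
#' @param spec A `session_spec` (from [session_spec()] or [custom_spec()]).
#' @return An `scs_schedule` object: list with `spec`, `events` (tibble
#'   `kind, onset_s, duration_s, trial_index`, sorted by onset), `scs_onsets`
#'   (seconds, one per trial) and `total_duration` (seconds).
#' @examples
#' sched <- build_schedule(session_spec("PreExp", "PA", seed = 1))
#' sched$total_duration  # 590
#' @export
build_schedule <- function(spec) {
  if (!inherits(spec, "session_spec")) {
    stop_scsflight("`spec` must be a session_spec.", "scsflight_input_error")
  }
  # CD1/CD2 share a seed argument but must differ in timing
  day_salt <- switch(spec$session, CD1 = 101L, CD2 = 202L, 0L)
  withr::local_seed(sub_seed(spec$seed, day_salt))

  scs_len <- 20
  shock_len <- 1
  if (spec$paired) {
    blocks <- rep("scs", spec$n_trials)
  } else if (spec$n_trials > 0L && spec$n_shocks > 0L) {
    blocks <- unpaired_order(spec$n_trials, spec$n_shocks)
  } else {
    blocks <- c(rep("scs", spec$n_trials), rep("shock", spec$n_shocks))
  }
  block_len <- ifelse(blocks == "scs", scs_len, shock_len)
  n_gaps <- max(length(blocks) - 1L, 0L)
  gap_total <- spec$total - spec$baseline - sum(block_len) - spec$tail
  if (length(blocks) == 0L) {
    if (abs(gap_total) > 1e-9) {
      stop_scsflight("baseline + tail do not match `total` for an empty schedule.",
                     "scsflight_constraint_error")
    }
    gaps <- numeric(0)
  } else if (n_gaps == 0L) {
    if (abs(gap_total) > 1e-9) {
      stop_scsflight("Single-stimulus schedule cannot absorb a nonzero gap total.",
                     "scsflight_constraint_error")
    }
    gaps <- numeric(0)
  } else {
    gaps <- draw_gaps(n_gaps, spec$isi_range, gap_total)
  }

  onsets <- spec$baseline + c(0, cumsum(block_len[-length(block_len)] +
                                          gaps))[seq_along(blocks)]
  events <- list()
  scs_onsets <- numeric(0)
  trial <- 0L
  for (b in seq_along(blocks)) {
    if (blocks[b] == "scs") {
      trial <- trial + 1L
      scs_onsets <- c(scs_onsets, onsets[b])
      events[[length(events) + 1L]] <- scs_events(onsets[b], spec$variant, trial)
      if (spec$paired) {
        events[[length(events) + 1L]] <- tibble(
          kind = "shock", onset_s = onsets[b] + 19, duration_s = 1,
          trial_index = trial)
      }
    } else {
      events[[length(events) + 1L]] <- tibble(
        kind = "shock", onset_s = onsets[b], duration_s = 1, trial_index = 0L)
    }
  }
  events <- if (length(events)) arrange(bind_rows(events), .data$onset_s,
                                        .data$kind) else
    tibble(kind = character(), onset_s = numeric(), duration_s = numeric(),
           trial_index = integer())
  structure(list(spec = spec, events = events, scs_onsets = scs_onsets,
                 total_duration = spec$total),
            class = "scs_schedule")
}

#' @export
print.scs_schedule <- function(x, ...) {
  cat(sprintf("<scs_schedule> %s / %s (%s SCS): %d trials, %d shocks, %g s total\n",
              x$spec$session, x$spec$group, x$spec$variant, x$spec$n_trials,
              sum(x$events$kind == "shock"), x$total_duration))
  invisible(x)
}

#' Export / import a stimulus schedule as a delimited event table
#'
#' One row per event with columns `kind,onset_s,duration_s,trial_index`. The
#' pair round-trips the event list losslessly; the spec (group, session,
#' totals) travels as commented header lines so a re-imported file rebuilds a
#' complete `scs_schedule`.
#'
#' @param schedule An `scs_schedule`.
#' @param path File path to write to / read from.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns an `scs_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "scs_schedule"))
  sp <- schedule$spec
  hdr <- sprintf(
    "# scsflight_schedule session=%s group=%s variant=%s baseline=%.9g n_trials=%d n_shocks=%d paired=%s isi_min=%.9g isi_max=%.9g tail=%.9g total=%.9g seed=%d",
    sp$session, sp$group, sp$variant, sp$baseline, sp$n_trials, sp$n_shocks,
    sp$paired, sp$isi_range[1], sp$isi_range[2], sp$tail, sp$total, sp$seed)
  cat(hdr, "\n", sep = "", file = path)
  readr::write_csv(schedule$events, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# scsflight_schedule")) {
    stop_scsflight("Not a scsflight schedule file (missing header).",
                   "scsflight_format_error")
  }
  kv <- strsplit(sub("^# scsflight_schedule ", "", hdr), " ")[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  spec <- structure(list(
    session = vals[["session"]], group = vals[["group"]],
    variant = vals[["variant"]], baseline = as.numeric(vals[["baseline"]]),
    n_trials = as.integer(vals[["n_trials"]]),
    n_shocks = as.integer(vals[["n_shocks"]]),
    paired = as.logical(vals[["paired"]]),
    isi_range = c(as.numeric(vals[["isi_min"]]), as.numeric(vals[["isi_max"]])),
    tail = as.numeric(vals[["tail"]]), total = as.numeric(vals[["total"]]),
    seed = as.integer(vals[["seed"]])), class = "session_spec")
  events <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                            col_types = "cddi")
  # SCS onset = earliest pip of each trial
  pip <- events[events$kind != "shock" & events$trial_index > 0L, ]
  scs_onsets <- if (nrow(pip)) as.numeric(tapply(pip$onset_s, pip$trial_index,
                                                 min)) else numeric(0)
  structure(list(spec = spec, events = events, scs_onsets = scs_onsets,
                 total_duration = spec$total),
            class = "scs_schedule")
}
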