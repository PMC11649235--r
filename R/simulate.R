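#' Logistic trial-index learning curve
#'
#' `lo + (hi - lo) / (1 + exp(-slope * (trial - mid)))`: the sigmoid used to
#' modulate behavioral-state occupancies across trials (acquisition when
#' `slope > 0` from `lo` to `hi`, extinction-style decay when the curve is
#' written with `hi` at early trials).
#'
#' @param trial Trial index (vectorized).
#' @param lo,hi Asymptotic occupancies.
#' @param mid Trial of the inflection point.
#' @param slope Steepness per trial.
#' @return Numeric vector of occupancies.
#' @export
logistic_curve <- function(trial, lo, hi, mid, slope) {
  lo + (hi - lo) / (1 + exp(-slope * (trial - mid)))
}

# one state-table row; locomotion absorbs the leftover occupancy
st <- function(session, period, trial = 0L, freeze = 0, dart = 0, jump = 0,
               loco_speed = 2.5) {
  loco <- 1 - freeze - dart - jump
  stopifnot(loco >= -1e-9)
  tibble(session = session, period = period, trial_index = as.integer(trial),
         p_freeze = freeze, p_locomote = max(loco, 0), p_dart = dart,
         p_jump = jump, loco_speed = loco_speed)
}

st_trials <- function(trials, f) bind_rows(lapply(trials, f))

# Default per-(session, period, trial) occupancy tables. Rows with
# trial_index = 0 apply to any trial (baseline/isi/shock and any period
# without trial-specific rows). Occupancies are the target fraction of period
# time in each state; `loco_speed` is the mean walking speed (cm/s) emitted in
# the locomote state for that cell.
default_state_table <- function(group) {
  pre_exp <- bind_rows(
    st("PreExp", "baseline", freeze = 0.05, loco_speed = 3),
    st("PreExp", "isi", freeze = 0.05, loco_speed = 3),
    st("PreExp", "pre_scs", freeze = 0.05, loco_speed = 3),
    st("PreExp", "tone", freeze = 0.05, loco_speed = 3),
    st("PreExp", "wn", freeze = 0.05, loco_speed = 3.5)
  )
  shock_row <- function(sess) st(sess, "shock", freeze = 0, dart = 0.25,
                                 jump = 0.35, loco_speed = 8)
  tbl <- switch(
    group,
    PA = bind_rows(
      pre_exp,
      # CD1: acquisition underway
      st("CD1", "baseline", freeze = 0.10),
      st("CD1", "isi", freeze = 0.30),
      st("CD1", "pre_scs", freeze = 0.30),
      st_trials(1:5, function(t)
        st("CD1", "tone", t, freeze = logistic_curve(t, 0.15, 0.55, 3, 1.1))),
      st_trials(1:5, function(t)
        st("CD1", "wn", t, freeze = 0.05,
           dart = logistic_curve(t, 0.05, 0.18, 3, 1.0),
           jump = logistic_curve(t, 0.01, 0.07, 3, 1.0), loco_speed = 4)),
      shock_row("CD1"),
      # CD2: consolidated freezing to tone, flight to WN
      st("CD2", "baseline", freeze = 0.35),
      st("CD2", "isi", freeze = 0.70),
      st("CD2", "pre_scs", freeze = 0.70),
      st_trials(1:5, function(t)
        st("CD2", "tone", t, freeze = logistic_curve(t, 0.60, 0.90, 2.5, 1.2))),
      st_trials(1:5, function(t)
        st("CD2", "wn", t, freeze = 0.05, dart = 0.42, jump = 0.14,
           loco_speed = 4)),
      shock_row("CD2"),
      # Ext1: jumping extinguishes by mid-session, WN freezing builds
      st("Ext1", "baseline", freeze = 0.30),
      st("Ext1", "isi", freeze = 0.50),
      st("Ext1", "pre_scs", freeze = 0.50),
      st_trials(1:16, function(t)
        st("Ext1", "tone", t, freeze = logistic_curve(t, 0.85, 0.50, 8, 0.5))),
      st_trials(1:16, function(t)
        st("Ext1", "wn", t,
           freeze = logistic_curve(t, 0.05, 0.50, 6, 0.5),
           dart = logistic_curve(t, 0.30, 0.05, 10, 0.4),
           jump = logistic_curve(t, 0.11, 0.00, 4, 1.2),
           loco_speed = logistic_curve(t, 4, 2, 8, 0.5))),
      # Ext2: flight gone, WN now answered with freezing
      st("Ext2", "baseline", freeze = 0.25),
      st("Ext2", "isi", freeze = 0.45),
      st("Ext2", "pre_scs", freeze = 0.45),
      st_trials(1:16, function(t)
        st("Ext2", "tone", t, freeze = logistic_curve(t, 0.50, 0.20, 8, 0.5))),
      st("Ext2", "wn", freeze = 0.60, dart = 0.02, loco_speed = 1.8)
    ),
    UN = bind_rows(
      pre_exp,
      st("CD1", "baseline", freeze = 0.05),
      st("CD1", "isi", freeze = 0.30),
      st("CD1", "pre_scs", freeze = 0.30),
      st("CD1", "tone", freeze = 0.15, loco_speed = 3),
      st_trials(1:5, function(t)
        st("CD1", "wn", t, freeze = 0.05, dart = 0.02,
           jump = if (t == 1) 0.02 else 0, loco_speed = 6)),
      shock_row("CD1"),
      st("CD2", "baseline", freeze = 0.15),
      st("CD2", "isi", freeze = 0.45),
      st("CD2", "pre_scs", freeze = 0.45),
      st("CD2", "tone", freeze = 0.25, loco_speed = 3),
      st_trials(1:5, function(t)
        st("CD2", "wn", t, freeze = 0.03, dart = 0.02,
           jump = if (t == 1) 0.005 else 0, loco_speed = 8)),
      shock_row("CD2"),
      st("Ext1", "baseline", freeze = 0.10),
      st("Ext1", "isi", freeze = 0.25),
      st("Ext1", "pre_scs", freeze = 0.25),
      st_trials(1:16, function(t)
        st("Ext1", "tone", t, freeze = logistic_curve(t, 0.20, 0.10, 8, 0.4),
           loco_speed = 3)),
      st("Ext1", "wn", freeze = 0.05, dart = 0.02, loco_speed = 5),
      st("Ext2", "baseline", freeze = 0.08),
      st("Ext2", "isi", freeze = 0.20),
      st("Ext2", "pre_scs", freeze = 0.20),
      st("Ext2", "tone", freeze = 0.10, loco_speed = 3),
      st("Ext2", "wn", freeze = 0.05, dart = 0.01, loco_speed = 4.5)
    ),
    SO = bind_rows(
      pre_exp,
      st("CD1", "baseline", freeze = 0.05),
      st("CD1", "isi", freeze = 0.25),
      shock_row("CD1"),
      st("CD2", "baseline", freeze = 0.10),
      st("CD2", "isi", freeze = 0.35),
      shock_row("CD2"),
      st("Ext1", "baseline", freeze = 0.10),
      st("Ext1", "isi", freeze = 0.25),
      st("Ext1", "pre_scs", freeze = 0.25),
      st("Ext1", "tone", freeze = 0.15, loco_speed = 3),
      st("Ext1", "wn", freeze = 0.03, dart = 0.10, loco_speed = 5),
      st("Ext2", "baseline", freeze = 0.08),
      st("Ext2", "isi", freeze = 0.20),
      st("Ext2", "pre_scs", freeze = 0.20),
      st("Ext2", "tone", freeze = 0.10, loco_speed = 3),
      st("Ext2", "wn", freeze = 0.03, dart = 0.02, loco_speed = 4.5)
    ),
    PA_R = bind_rows(
      pre_exp,
      st("CD1", "baseline", freeze = 0.10),
      st("CD1", "isi", freeze = 0.30),
      st("CD1", "pre_scs", freeze = 0.30),
      st_trials(1:5, function(t)
        st("CD1", "tone", t, freeze = logistic_curve(t, 0.15, 0.55, 3, 1.1))),
      st("CD1", "wn", freeze = 0.25, loco_speed = 2.5),
      shock_row("CD1"),
      st("CD2", "baseline", freeze = 0.30),
      st("CD2", "isi", freeze = 0.60),
      st("CD2", "pre_scs", freeze = 0.60),
      st_trials(1:5, function(t)
        st("CD2", "tone", t, freeze = logistic_curve(t, 0.60, 0.90, 2.5, 1.2))),
      st_trials(1:5, function(t)
        st("CD2", "wn", t, freeze = 0.35, jump = 0.005, loco_speed = 2.5)),
      shock_row("CD2"),
      # extinction-resistant tone freezing, constant across Ext1/Ext2
      st("Ext1", "baseline", freeze = 0.25),
      st("Ext1", "isi", freeze = 0.50),
      st("Ext1", "pre_scs", freeze = 0.50),
      st("Ext1", "tone", freeze = 0.85),
      st("Ext1", "wn", freeze = 0.30, loco_speed = 2.5),
      st("Ext2", "baseline", freeze = 0.25),
      st("Ext2", "isi", freeze = 0.50),
      st("Ext2", "pre_scs", freeze = 0.50),
      st("Ext2", "tone", freeze = 0.85),
      st("Ext2", "wn", freeze = 0.30, loco_speed = 2.5)
    ),
    UN_R = bind_rows(
      pre_exp,
      st("CD1", "baseline", freeze = 0.05),
      st("CD1", "isi", freeze = 0.25),
      st("CD1", "pre_scs", freeze = 0.25),
      st("CD1", "tone", freeze = 0.15, loco_speed = 3),
      st("CD1", "wn", freeze = 0.03, loco_speed = 6),
      shock_row("CD1"),
      st("CD2", "baseline", freeze = 0.10),
      st("CD2", "isi", freeze = 0.35),
      st("CD2", "pre_scs", freeze = 0.35),
      st("CD2", "tone", freeze = 0.20, loco_speed = 3.5),
      st_trials(1:5, function(t)
        st("CD2", "wn", t, freeze = 0.02, jump = if (t == 1) 0.01 else 0,
           loco_speed = 8.5)),
      shock_row("CD2"),
      st("Ext1", "baseline", freeze = 0.08),
      st("Ext1", "isi", freeze = 0.20),
      st("Ext1", "pre_scs", freeze = 0.20),
      st("Ext1", "tone", freeze = 0.12, loco_speed = 3),
      st("Ext1", "wn", freeze = 0.03, dart = 0.02, loco_speed = 5.5),
      st("Ext2", "baseline", freeze = 0.08),
      st("Ext2", "isi", freeze = 0.18),
      st("Ext2", "pre_scs", freeze = 0.18),
      st("Ext2", "tone", freeze = 0.08, loco_speed = 3),
      st("Ext2", "wn", freeze = 0.03, loco_speed = 5)
    ),
    stop_scsflight(sprintf("Unknown group '%s'.", group),
                   "scsflight_input_error")
  )
  tbl
}

# tail-rattle overlay rates (expected bouts per 10 s of window), by session
# and period; tail rattling is most prevalent in the non-associative control
# groups during the tone period of extinction
default_tail_rattle_table <- function(group) {
  if (group %in% c("UN", "SO", "UN_R")) {
    tibble(session = rep(c("Ext1", "Ext2"), each = 2),
           period = rep(c("tone", "wn"), 2),
           rate = c(0.5, 0.2, 0.2, 0.1))
  } else {
    tibble(session = c("Ext1", "Ext2"), period = "tone", rate = c(0.05, 0.02))
  }
}

#' Default simulation parameters for a group
#'
#' Returns the shipped `sim_params` object for one of the five conditioning
#' groups. The state table encodes the group's qualitative ethogram: the
#' paired (PA) group acquires tone freezing across conditioning trials and
#' shows darting and escape jumping during white noise on CD2, which
#' extinguish over extinction while WN freezing builds; the unpaired (UN) and
#' shock-only (SO) groups show elevated WN locomotion with near-zero flight;
#' the paired-reverse (PA-R) group freezes persistently to tone with almost no
#' WN jumping; the unpaired-reverse (UN-R) group resembles UN. Default
#' occupancy and emission rates were calibrated once so the full pipeline on
#' simulated CD2 cohorts reproduces the published group-level WN activity
#' indices; they are package calibration choices, not measured facts.
#'
#' @param group `"PA"`, `"UN"`, `"SO"`, `"PA_R"` or `"UN_R"`.
#' @param seed Integer seed combined with each animal seed for reproducible
#'   emission noise.
#' @return A `sim_params` object: list with fields `group`, `fps`,
#'   `arena_diameter` (cm), `calibration` (cm/px), `eps` (freeze speed
#'   ceiling, shared with [detect_freezing()]), `state_table`,
#'   `tail_rattle`, `emission` (per-state dwell and speed parameters) and
#'   `seed`.
#' @export
sim_params <- function(group = c("PA", "UN", "SO", "PA_R", "UN_R"), seed = 1L) {
  group <- match.arg(group)
  emission <- list(
    freeze_speed = c(0.02, 0.25),   # cm/s uniform jitter, below eps
    freeze_dwell = c(min = 1.0, exp_mean = 0.5),  # s
    loco_dwell = c(min = 0.2, exp_mean = 0.3),    # s
    loco_sd = 1.2,                  # cm/s AR(1) innovation scale
    loco_tau = 0.2,                 # s speed autocorrelation time
    loco_range = c(0.8, 9.5),       # cm/s clip: above eps, below dart v_start
    dart_frames = c(12L, 18L),      # >= 8-frame minimum
    dart_peak = c(22, 32),          # cm/s
    jump_frames = c(8L, 12L),
    jump_speed = c(2, 3.5),         # cm/s horizontal during airborne
    tail_rattle_dur = c(0.3, 0.6)   # s
  )
  structure(list(group = group, fps = 30, arena_diameter = 30,
                 calibration = 1 / 15, eps = 0.5,
                 state_table = default_state_table(group),
                 tail_rattle = default_tail_rattle_table(group),
                 emission = emission, seed = as.integer(seed)),
            class = "sim_params")
}

#' @rdname sim_params
#' @export
default_params <- sim_params

# expected dwell (s) per state, for converting target occupancies into
# renewal selection probabilities (occupancy ~ q * E[dwell], so q ~ p / E)
expected_dwells <- function(em, fps) {
  c(freeze = unname(em$freeze_dwell["min"] + em$freeze_dwell["exp_mean"]),
    locomote = unname(em$loco_dwell["min"] + em$loco_dwell["exp_mean"]),
    dart = mean(em$dart_frames) / fps,
    jump = mean(em$jump_frames) / fps)
}

# per-frame (period, trial) labelling for a schedule
frame_periods <- function(schedule, fps, n) {
  t <- (seq_len(n) - 1) / fps
  period <- rep("isi", n)
  trial <- integer(n)
  w <- period_windows(schedule)
  # assignment order gives shock precedence over the overlapping CS half
  w <- w[order(match(w$period,
                     c("baseline", "pre_scs", "tone", "wn", "shock"))), ]
  for (i in seq_len(nrow(w))) {
    sel <- t >= w$start_s[i] & t < w$end_s[i]
    period[sel] <- w$period[i]
    trial[sel] <- w$trial_index[i]
  }
  list(period = period, trial = trial, t = t)
}

fold_axis <- function(z, lo, hi) {
  w <- hi - lo
  y <- (z - lo) %% (2 * w)
  ifelse(y > w, 2 * w - y, y) + lo
}

#' Simulate one session of one animal
#'
#' Emits a bounded 2-D centroid trajectory at `params$fps` frames/s for the
#' full session, by sampling behavioral states (freeze / locomote / dart /
#' jump) from the state-table cell matching the current (session, period,
#' trial), with per-state minimum dwells so bouts are well defined. Freezing
#' frames carry sub-`eps` jitter, locomotion is an autocorrelated bounded
#' walk, darts are supra-threshold speed bursts of at least 8 frames, and
#' jumps set the `airborne` channel. Positions stay inside the arena. The
#' result is fully reproducible given (`params$seed`, `animal_seed`).
#'
#' @param schedule An `scs_schedule`; its session label must have rows in
#'   `params$state_table`.
#' @param params A [sim_params()] object.
#' @param animal_seed Integer seed for this animal.
#' @return An `annotated_trajectory`: list with `trajectory` (a
#'   [trajectory()]), `truth_bouts` (ground-truth state intervals tiling the
#'   session, plus `tail_rattle` overlay bouts) and `schedule`.
#' @export
simulate_session <- function(schedule, params, animal_seed = 1L) {
  stopifnot(inherits(schedule, "scs_schedule"), inherits(params, "sim_params"))
  if (params$fps <= 0 || params$calibration <= 0) {
    stop_scsflight("`fps` and `calibration` must be positive.",
                   "scsflight_input_error")
  }
  fps <- params$fps
  dt <- 1 / fps
  em <- params$emission
  n <- as.integer(round(schedule$total_duration * fps))
  fp <- frame_periods(schedule, fps, n)

  sess <- schedule$spec$session
  tbl <- params$state_table[params$state_table$session == sess, ]
  if (!nrow(tbl)) {
    stop_scsflight(sprintf("state_table has no rows for session '%s'.", sess),
                   "scsflight_input_error")
  }
  psum <- tbl$p_freeze + tbl$p_locomote + tbl$p_dart + tbl$p_jump
  if (any(abs(psum - 1) > 1e-6)) {
    stop_scsflight("state_table occupancies must sum to 1 in every row.",
                   "scsflight_input_error")
  }
  # frame -> state-table row (exact trial match, else trial 0 row)
  tkey <- paste(tbl$period, tbl$trial_index)
  ridx <- match(paste(fp$period, fp$trial), tkey)
  fb <- match(paste(fp$period, 0L), tkey)
  ridx[is.na(ridx)] <- fb[is.na(ridx)]
  if (anyNA(ridx)) {
    miss <- unique(fp$period[is.na(ridx)])
    stop_scsflight(sprintf("state_table lacks rows for period(s): %s.",
                           paste(miss, collapse = ", ")),
                   "scsflight_input_error")
  }
  probs <- as.matrix(tbl[, c("p_freeze", "p_locomote", "p_dart", "p_jump")])
  loco_mu <- tbl$loco_speed
  ed <- expected_dwells(em, fps)

  withr::local_seed(sub_seed(params$seed, animal_seed))

  radius_cm <- params$arena_diameter / 2
  half_box <- radius_cm / sqrt(2)  # inscribed square: always inside the arena
  phi <- exp(-dt / em$loco_tau)
  innov_sd <- em$loco_sd * sqrt(1 - phi^2)

  v <- numeric(n)
  theta <- numeric(n)
  airborne <- integer(n)
  seg_state <- character(0)
  seg_start <- integer(0)
  seg_end <- integer(0)
  x <- numeric(n); y <- numeric(n)
  pos_x <- runif(1, -half_box / 2, half_box / 2)
  pos_y <- runif(1, -half_box / 2, half_box / 2)
  heading <- runif(1, 0, 2 * pi)
  states <- c("freeze", "locomote", "dart", "jump")

  i <- 1L
  while (i <= n) {
    r <- ridx[i]
    q <- probs[r, ] / ed
    s <- sample.int(4L, 1L, prob = q)
    m <- switch(
      s,
      max(1L, as.integer(round((em$freeze_dwell["min"] +
                                  rexp(1, 1 / em$freeze_dwell["exp_mean"])) * fps))),
      max(1L, as.integer(round((em$loco_dwell["min"] +
                                  rexp(1, 1 / em$loco_dwell["exp_mean"])) * fps))),
      sample(em$dart_frames[1]:em$dart_frames[2], 1L),
      sample(em$jump_frames[1]:em$jump_frames[2], 1L)
    )
    m <- min(m, n - i + 1L)
    idx <- i:(i + m - 1L)
    if (s == 1L) {                     # freeze: sub-eps jitter
      v[idx] <- runif(m, em$freeze_speed[1], em$freeze_speed[2])
      theta[idx] <- runif(m, 0, 2 * pi)
    } else if (s == 2L) {              # locomote: AR(1) speed, wandering heading
      dev <- stats::filter(rnorm(m, 0, innov_sd), phi, method = "recursive",
                           init = rnorm(1, 0, em$loco_sd))
      vv <- loco_mu[r] + as.numeric(dev)
      v[idx] <- pmin(pmax(vv, em$loco_range[1]), em$loco_range[2])
      heading <- heading + rnorm(1, 0, 0.3)
      theta[idx] <- heading + cumsum(rnorm(m, 0, 0.35))
    } else if (s == 3L) {              # dart: burst aimed at an interior point
      peak <- runif(1, em$dart_peak[1], em$dart_peak[2])
      prof <- if (m >= 2) {
        1 + (peak - 1) * sin(pi * (seq_len(m) - 1) / (m - 1))^2
      } else peak / 2
      v[idx] <- prof
      tx <- runif(1, -half_box / 2, half_box / 2)
      ty <- runif(1, -half_box / 2, half_box / 2)
      heading <- atan2(ty - pos_y, tx - pos_x)
      theta[idx] <- heading + rnorm(m, 0, 0.05)
    } else {                           # jump: airborne, modest horizontal drift
      v[idx] <- runif(m, em$jump_speed[1], em$jump_speed[2])
      heading <- runif(1, 0, 2 * pi)
      theta[idx] <- heading
      airborne[idx] <- 1L
    }
    step <- v[idx] * dt
    step[1] <- if (i == 1L) 0 else step[1]
    nx <- fold_axis(pos_x + cumsum(step * cos(theta[idx])), -half_box, half_box)
    ny <- fold_axis(pos_y + cumsum(step * sin(theta[idx])), -half_box, half_box)
    x[idx] <- nx
    y[idx] <- ny
    pos_x <- nx[m]; pos_y <- ny[m]
    seg_state <- c(seg_state, states[s])
    seg_start <- c(seg_start, i)
    seg_end <- c(seg_end, i + m - 1L)
    i <- i + m
  }

  # merge consecutive same-state segments into ground-truth bouts — except
  # darts: a dart ends at a full stop by definition, so back-to-back dart
  # segments are distinct bouts, matching what a hysteresis detector sees
  keep <- c(TRUE, seg_state[-1] != seg_state[-length(seg_state)] |
              seg_state[-1] == "dart")
  bout_state <- seg_state[keep]
  bout_start <- seg_start[keep]
  bout_end <- c(seg_start[keep][-1] - 1L, n)
  truth <- new_bouts(bout_state, fp$t[bout_start], fp$t[bout_end] + dt)

  # tail-rattle overlay channel
  tail_rattle <- integer(n)
  tr_tbl <- params$tail_rattle[params$tail_rattle$session == sess, ]
  tr_bouts <- empty_bouts()
  if (nrow(tr_tbl)) {
    w <- period_windows(schedule)
    w <- dplyr::inner_join(w, tr_tbl, by = "period")
    for (k in seq_len(nrow(w))) {
      len <- w$end_s[k] - w$start_s[k]
      nb <- rpois(1, w$rate[k] * len / 10)
      if (nb == 0) next
      starts <- runif(nb, w$start_s[k], w$end_s[k] - em$tail_rattle_dur[2])
      durs <- runif(nb, em$tail_rattle_dur[1], em$tail_rattle_dur[2])
      for (b in seq_len(nb)) {
        i0 <- max(1L, as.integer(floor(starts[b] * fps)) + 1L)
        i1 <- min(n, as.integer(ceiling((starts[b] + durs[b]) * fps)))
        if (i1 >= i0) tail_rattle[i0:i1] <- 1L
      }
    }
    rr <- runs_of(tail_rattle == 1L)
    if (nrow(rr)) {
      tr_bouts <- new_bouts("tail_rattle", fp$t[rr[, "start"]],
                            fp$t[rr[, "end"]] + dt)
    }
  }

  cx_px <- 320; cy_px <- 240  # arena center in a 640x480 field of view
  traj <- trajectory(x / params$calibration + cx_px,
                     y / params$calibration + cy_px,
                     fps = fps, calibration = params$calibration,
                     airborne = airborne, tail_rattle = tail_rattle,
                     t_s = fp$t)
  structure(list(trajectory = traj,
                 truth_bouts = arrange(bind_rows(truth, tr_bouts),
                                       .data$start_s),
                 schedule = schedule),
            class = "annotated_trajectory")
}

#' Simulate a cohort
#'
#' Simulates `n_animals` animals of one group over the requested sessions,
#' with per-animal sub-seeds derived from `seed` and sex labels assigned in
#' equal numbers. Session schedules are built with a fixed schedule seed
#' (`schedule_seed`), so different cohort seeds give different trajectories
#' under identical schedules.
#'
#' @inheritParams sim_params
#' @param n_animals Number of animals (>= 1).
#' @param sessions Character vector of sessions, e.g. `c("CD1", "CD2")`.
#' @param params A [sim_params()]; defaults to the group's shipped defaults.
#' @param seed Cohort seed driving all per-animal randomness.
#' @param schedule_seed Seed for the stimulus schedules (fixed by default so
#'   schedules are stable across cohort seeds).
#' @return A nested tibble with one row per animal-session: `animal_id`,
#'   `group`, `sex`, `session`, and list-columns `schedule`, `trajectory`,
#'   `truth_bouts`.
#' @export
simulate_cohort <- function(group, n_animals, sessions,
                            params = sim_params(group), seed = 1L,
                            schedule_seed = 20L) {
  if (length(sessions) < 1L) {
    stop_scsflight("`sessions` must name at least one session.",
                   "scsflight_input_error")
  }
  if (n_animals < 1L) {
    stop_scsflight("`n_animals` must be >= 1.", "scsflight_input_error")
  }
  scheds <- lapply(sessions, function(s)
    build_schedule(session_spec(s, group, seed = schedule_seed)))
  names(scheds) <- sessions
  sex <- rep(c("F", "M"), length.out = n_animals)
  rows <- list()
  for (a in seq_len(n_animals)) {
    for (si in seq_along(sessions)) {
      sim <- simulate_session(scheds[[si]], params,
                              animal_seed = sub_seed(seed, a * 131L + si))
      rows[[length(rows) + 1L]] <- tibble(
        animal_id = sprintf("%s_%02d", group, a),
        group = group, sex = sex[a], session = sessions[si],
        schedule = list(scheds[[si]]),
        trajectory = list(sim$trajectory),
        truth_bouts = list(sim$truth_bouts))
    }
  }
  bind_rows(rows)
}
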