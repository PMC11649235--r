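#' Bout tables
#'
#' All detectors return a bout table: a tibble with columns `behavior`
#' (`freeze`, `dart`, `jump`, `tail_rattle`), `start_s` and `end_s` (half-open
#' `[start_s, end_s)` in seconds), sorted and non-overlapping within a
#' behavior. A frame at timestamp `t` covers `[t, t + 1/fps)`, so a bout over
#' frames `i..j` spans `[t_i, t_j + 1/fps)`.
#'
#' @name bouts
NULL

new_bouts <- function(behavior, start_s, end_s) {
  tibble(behavior = behavior, start_s = start_s, end_s = end_s)
}

empty_bouts <- function() {
  tibble(behavior = character(), start_s = numeric(), end_s = numeric())
}

# maximal runs of a logical vector as (start index, end index) pairs
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect freezing bouts from a speed series
#'
#' Freezing is a complete cessation of movement lasting at least `min_dur`
#' seconds, operationalized on centroid speed: maximal runs of consecutive
#' frames with `v < eps` become bouts, and runs shorter than `min_dur` are
#' discarded.
#'
#' @param speed A `speed_series` from [compute_speed()].
#' @param eps Speed ceiling in cm/s under which a frame counts as motionless
#'   (default 0.5).
#' @param min_dur Minimum bout duration in seconds (default 1).
#' @return A [bouts] tibble with `behavior == "freeze"`.
#' @export
detect_freezing <- function(speed, eps = 0.5, min_dur = 1.0) {
  if (!is.numeric(eps) || eps <= 0) {
    stop_scsflight("`eps` must be positive.", "scsflight_input_error")
  }
  fps <- attr(speed, "fps")
  dt <- 1 / fps
  rr <- runs_of(speed$v_cms < eps)
  if (nrow(rr) == 0L) return(empty_bouts())
  start_s <- speed$t_s[rr[, "start"]]
  end_s <- speed$t_s[rr[, "end"]] + dt
  keep <- (end_s - start_s) >= min_dur - 1e-9
  if (!any(keep)) return(empty_bouts())
  new_bouts("freeze", start_s[keep], end_s[keep])
}

#' Detect dart bouts with a speed hysteresis rule
#'
#' A dart is a rapid burst of horizontal locomotion from rest back to rest.
#' The detector is a two-threshold hysteresis: it arms whenever speed is below
#' `v_stop`, opens a bout at the first subsequent frame where speed exceeds
#' `v_start`, and closes the bout at the last frame before speed returns below
#' `v_stop`. Bouts spanning fewer than `min_frames` frames are discarded (the
#' default 8 frames is 266 ms at 30 frames/s).
#'
#' @inheritParams detect_freezing
#' @param v_start Opening threshold (cm/s), default 10.
#' @param v_stop Closing/arming threshold (cm/s), default 4; must be below
#'   `v_start`.
#' @param min_frames Minimum bout length in frames, default 8.
#' @return A [bouts] tibble with `behavior == "dart"`.
#' @export
detect_darts <- function(speed, v_start = 10, v_stop = 4, min_frames = 8L) {
  if (!(v_start > v_stop && v_stop > 0)) {
    stop_scsflight("Need `v_start` > `v_stop` > 0.", "scsflight_input_error")
  }
  if (min_frames < 1L) {
    stop_scsflight("`min_frames` must be >= 1.", "scsflight_input_error")
  }
  fps <- attr(speed, "fps")
  dt <- 1 / fps
  v <- speed$v_cms
  n <- length(v)
  # zone-run scan (equivalent to a frame-by-frame state machine, but O(#runs)):
  # 0 = below v_stop (arms / closes), 2 = above v_start (opens when armed),
  # 1 = hysteresis band (no state change)
  z <- ifelse(v < v_stop, 0L, ifelse(v > v_start, 2L, 1L))
  r <- rle(z)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  starts <- integer(0); ends <- integer(0)
  armed <- FALSE
  open <- 0L
  for (k in seq_along(r$values)) {
    val <- r$values[k]
    if (open) {
      if (val == 0L) { # close at last frame before the return below v_stop
        starts <- c(starts, open); ends <- c(ends, run_start[k] - 1L)
        open <- 0L
        armed <- TRUE
      }
    } else {
      if (val == 0L) armed <- TRUE
      else if (val == 2L && armed) open <- run_start[k]
    }
  }
  if (open) { starts <- c(starts, open); ends <- c(ends, n) }
  if (!length(starts)) return(empty_bouts())
  keep <- (ends - starts + 1L) >= min_frames
  if (!any(keep)) return(empty_bouts())
  new_bouts("dart", speed$t_s[starts[keep]], speed$t_s[ends[keep]] + dt)
}

#' Extract jump bouts from the airborne annotation channel
#'
#' Escape jumps are scored as the period with all four paws off the floor and
#' arrive as a per-frame 0/1 `airborne` channel; maximal runs of 1 become jump
#' bouts. A jump's event time is its start.
#'
#' @param traj A [trajectory()] (an all-zero channel is allowed).
#' @return A [bouts] tibble with `behavior == "jump"`.
#' @export
extract_jumps <- function(traj) {
  extract_channel_bouts(traj, "airborne", "jump")
}

#' Extract tail-rattle bouts from the annotation channel
#' @inheritParams extract_jumps
#' @return A [bouts] tibble with `behavior == "tail_rattle"`.
#' @export
extract_tail_rattles <- function(traj) {
  extract_channel_bouts(traj, "tail_rattle", "tail_rattle")
}

extract_channel_bouts <- function(traj, channel, behavior) {
  stopifnot(inherits(traj, "trajectory"))
  dt <- 1 / traj_fps(traj)
  rr <- runs_of(traj[[channel]] == 1L)
  if (nrow(rr) == 0L) return(empty_bouts())
  new_bouts(behavior, traj$t_s[rr[, "start"]], traj$t_s[rr[, "end"]] + dt)
}

#' Run the full bout ethogram on one trajectory
#'
#' Convenience wrapper: computes speed, then freezing, dart, jump and
#' tail-rattle bouts, returned as one sorted bout table.
#'
#' @inheritParams extract_jumps
#' @inheritParams detect_freezing
#' @inheritParams detect_darts
#' @return A [bouts] tibble mixing the four behaviors.
#' @export
detect_bouts <- function(traj, eps = 0.5, min_dur = 1.0, v_start = 10,
                         v_stop = 4, min_frames = 8L) {
  sp <- compute_speed(traj)
  arrange(bind_rows(
    detect_freezing(sp, eps = eps, min_dur = min_dur),
    detect_darts(sp, v_start = v_start, v_stop = v_stop,
                 min_frames = min_frames),
    extract_jumps(traj),
    extract_tail_rattles(traj)
  ), .data$start_s, .data$behavior)
}

#' Read / write bout interval tables
#'
#' Delimited text with columns `behavior,start_s,end_s` (BED-like intervals in
#' seconds).
#'
#' @param bouts A [bouts] tibble.
#' @param path File path.
#' @export
write_bouts <- function(bouts, path) {
  readr::write_csv(bouts, path)
  invisible(path)
}

#' @rdname write_bouts
#' @export
read_bouts <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, col_types = "cdd")
}
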