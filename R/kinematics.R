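#' Construct a trajectory table
#'
#' A trajectory is the pipeline's raw input: one row per video frame with the
#' animal's centroid in pixels plus optional binary annotation channels
#' (`airborne` for manually scored escape jumps, `tail_rattle` for tail
#' rattling). Frame rate and the pixel-to-centimeter calibration coefficient
#' travel as attributes so downstream verbs need only the table.
#'
#' @param x,y Numeric centroid coordinates in pixels, one per frame.
#' @param fps Frame rate (frames per second), default 30.
#' @param calibration Centimeters per pixel (> 0). The default 1/15 matches a
#'   30 cm arena spanning about 450 px.
#' @param airborne,tail_rattle Optional 0/1 integer channels; default all 0.
#' @param t_s Optional per-frame timestamps (seconds); default `(0:(n-1))/fps`.
#' @return A tibble of class `trajectory` with columns
#'   `frame, t_s, x_px, y_px, airborne, tail_rattle`.
#' @export
trajectory <- function(x, y, fps = 30, calibration = 1 / 15,
                       airborne = NULL, tail_rattle = NULL, t_s = NULL) {
  n <- length(x)
  if (length(y) != n) {
    stop_scsflight("`x` and `y` must have equal length.", "scsflight_input_error")
  }
  if (!is.numeric(fps) || fps <= 0 || !is.numeric(calibration) || calibration <= 0) {
    stop_scsflight("`fps` and `calibration` must be positive.",
                   "scsflight_input_error")
  }
  if (is.null(t_s)) t_s <- (seq_len(n) - 1) / fps
  if (is.null(airborne)) airborne <- integer(n)
  if (is.null(tail_rattle)) tail_rattle <- integer(n)
  if (length(airborne) != n || length(tail_rattle) != n) {
    stop_scsflight("Annotation channel lengths must match the frame count.",
                   "scsflight_input_error")
  }
  out <- tibble(frame = seq_len(n) - 1L, t_s = t_s, x_px = as.numeric(x),
                y_px = as.numeric(y), airborne = as.integer(airborne),
                tail_rattle = as.integer(tail_rattle))
  structure(out, class = c("trajectory", class(out)),
            fps = fps, calibration = calibration)
}

#' Frame rate and calibration of a trajectory
#' @param traj A `trajectory`.
#' @return A single number.
#' @export
traj_fps <- function(traj) attr(traj, "fps")

#' @rdname traj_fps
#' @export
traj_calibration <- function(traj) attr(traj, "calibration")

#' Read / write tracking tables
#'
#' Tracking tables are delimited text with columns
#' `frame,t_s,x_px,y_px,airborne,tail_rattle` (the two annotation channels are
#' optional and default to all-zero). Timestamps must be uniform: gaps in the
#' frame numbering are rejected. `write_tracking()` stores `fps` and
#' `calibration` as a commented header line so the pair round-trips.
#'
#' @param path File path.
#' @param fps,calibration Overrides used when the file has no header line.
#' @return `read_tracking()` returns a [trajectory()].
#' @export
read_tracking <- function(path, fps = NULL, calibration = NULL) {
  hdr <- readLines(path, n = 1L)
  if (startsWith(hdr, "# scsflight_tracking")) {
    kv <- strsplit(strsplit(sub("^# scsflight_tracking ", "", hdr), " ")[[1]],
                   "=", fixed = TRUE)
    vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    if (is.null(fps)) fps <- as.numeric(vals[["fps"]])
    if (is.null(calibration)) calibration <- as.numeric(vals[["calibration"]])
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  req <- c("frame", "t_s", "x_px", "y_px")
  missing_col <- setdiff(req, names(df))
  if (length(missing_col)) {
    stop_scsflight(sprintf("Tracking table is missing required column(s): %s.",
                           paste(missing_col, collapse = ", ")),
                   "scsflight_format_error")
  }
  if (nrow(df) >= 2) {
    dt <- diff(df$t_s)
    if (any(dt <= 0) || diff(range(dt)) > 1e-6) {
      stop_scsflight("Tracking timestamps must be strictly increasing and uniform.",
                     "scsflight_format_error")
    }
    if (any(diff(df$frame) != 1L)) {
      stop_scsflight("Gap in frame numbering: frames must be consecutive.",
                     "scsflight_format_error")
    }
    if (is.null(fps)) fps <- 1 / stats::median(dt)
  }
  if (is.null(fps)) {
    stop_scsflight("`fps` not derivable from a single-frame file; pass it explicitly.",
                   "scsflight_format_error")
  }
  if (is.null(calibration)) calibration <- 1 / 15
  trajectory(df$x_px, df$y_px, fps = fps, calibration = calibration,
             airborne = df[["airborne"]], tail_rattle = df[["tail_rattle"]],
             t_s = df$t_s)
}

#' @rdname read_tracking
#' @param traj A [trajectory()].
#' @export
write_tracking <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  cat(sprintf("# scsflight_tracking fps=%.9g calibration=%.12g\n",
              traj_fps(traj), traj_calibration(traj)), file = path)
  readr::write_csv(as_tibble(traj), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Centroid speed series
#'
#' Converts per-frame pixel displacement to speed in cm/s:
#' `v[i] = calibration * ||p[i] - p[i-1]|| * fps` for `i >= 2`, and
#' `v[1] = v[2]` so the series has one value per frame. No smoothing is
#' applied.
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @return A tibble of class `speed_series` with columns `t_s`, `v_cms`,
#'   carrying the frame rate as an attribute.
#' @examples
#' tr <- trajectory(x = c(0, 1, 2, 3), y = c(0, 0, 0, 0), fps = 30,
#'                  calibration = 1 / 15)
#' compute_speed(tr)$v_cms  # 2 cm/s throughout
#' @export
compute_speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (n < 2) {
    stop_scsflight("Speed needs at least two frames.", "scsflight_input_error")
  }
  disp <- sqrt(diff(traj$x_px)^2 + diff(traj$y_px)^2)
  v <- c(NA_real_, disp * traj_calibration(traj) * traj_fps(traj))
  v[1] <- v[2]
  out <- tibble(t_s = traj$t_s, v_cms = v)
  structure(out, class = c("speed_series", class(out)), fps = traj_fps(traj))
}

#' Distance traveled in a time window
#'
#' Computes distance as the area under the speed curve after averaging speed
#' in 0.5 s bins: the window is partitioned into 0.5 s bins, and distance is
#' the sum over bins of (mean speed in bin) x (bin width), a trailing partial
#' bin contributing its actual width.
#'
#' @param speed A `speed_series` (from [compute_speed()]).
#' @param start,end Window bounds in seconds (half-open `[start, end)`).
#' @param bin_width Averaging bin in seconds (default 0.5).
#' @return Distance in cm.
#' @export
distance_traveled <- function(speed, start, end, bin_width = 0.5) {
  if (end <= start) {
    stop_scsflight("Empty window: `end` must exceed `start`.",
                   "scsflight_input_error")
  }
  edges <- seq(start, end, by = bin_width)
  if (abs(edges[length(edges)] - end) > 1e-9) edges <- c(edges, end)
  total <- 0
  for (b in seq_len(length(edges) - 1L)) {
    sel <- speed$t_s >= edges[b] & speed$t_s < edges[b + 1L]
    if (any(sel)) {
      total <- total + mean(speed$v_cms[sel]) * (edges[b + 1L] - edges[b])
    }
  }
  total
}

#' Mean speed within a window
#' @inheritParams distance_traveled
#' @return Mean of per-frame speeds with `start <= t < end` (cm/s); `NA` if the
#'   window holds no frames.
#' @export
mean_speed <- function(speed, start, end) {
  sel <- speed$t_s >= start & speed$t_s < end
  if (!any(sel)) return(NA_real_)
  mean(speed$v_cms[sel])
}
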