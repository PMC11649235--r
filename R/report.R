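#' Group mean +/- SEM summary of a metrics table
#'
#' @param metrics A [trial_metrics()] tibble (possibly many animals/sessions).
#' @param value Metric column to summarize (default `percent_freezing`).
#' @return A tibble with one row per (session, period, trial_index, group):
#'   `n`, `mean`, `sem`.
#' @export
summarize_metrics <- function(metrics, value = "percent_freezing") {
  metrics |>
    group_by(.data$session, .data$period, .data$trial_index, .data$group) |>
    summarise(n = dplyr::n(),
              mean = mean(.data[[value]], na.rm = TRUE),
              sem = stats::sd(.data[[value]], na.rm = TRUE) / sqrt(dplyr::n()),
              .groups = "drop") |>
    mutate(metric = value, .before = 1)
}

#' Write a report bundle from a metrics table
#'
#' Emits per-figure summary tables (group mean +/- SEM per trial and period
#' for each requested metric), statistical test tables for the requested
#' comparisons, and simple trial-curve plots. Deterministic given its inputs.
#'
#' @param metrics A [trial_metrics()] tibble.
#' @param comparisons A list of comparison requests; each element is a list
#'   with fields `name`, `test` (`"welch_t"`, `"anova1"` or `"anova2"`),
#'   `metric` (metric column), `period`, `session`, and for `welch_t`/`anova1`
#'   optionally `groups` (subset). Averages the metric per animal over trials
#'   before testing. An empty list writes summary tables only.
#' @param outdir Output directory (created if missing).
#' @param plots If `TRUE`, also writes PNG trial-curve figures.
#' @return Invisibly, the paths written.
#' @export
make_report <- function(metrics, comparisons = list(), outdir,
                        plots = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (val in intersect(c("percent_freezing", "activity_index", "jumps",
                          "darts", "distance_cm"), names(metrics))) {
    sm <- summarize_metrics(metrics, val)
    p <- file.path(outdir, sprintf("summary_%s.csv", val))
    readr::write_csv(sm, p)
    paths <- c(paths, p)
  }
  if (length(comparisons)) {
    res <- purrr::map(comparisons, function(cmp) {
      if (!cmp$test %in% c("welch_t", "anova1", "anova2")) {
        stop_scsflight(sprintf("Unknown test '%s' in comparison '%s'.",
                               cmp$test, cmp$name),
                       "scsflight_config_error")
      }
      d <- metrics[metrics$period == cmp$period &
                     metrics$session == cmp$session &
                     metrics$trial_index > 0, ]
      if (!is.null(cmp$groups)) d <- d[d$group %in% cmp$groups, ]
      if (cmp$test == "anova2") {
        out <- anova_twoway(d, .data[[cmp$metric]], trial_index, group)
        mutate(out, comparison = cmp$name, .before = 1)
      } else {
        per_animal <- d |>
          group_by(.data$animal_id, .data$group) |>
          summarise(value = mean(.data[[cmp$metric]], na.rm = TRUE),
                    .groups = "drop")
        fit <- if (cmp$test == "welch_t") {
          welch_t(per_animal, value, group)
        } else {
          anova_oneway(per_animal, value, group, tukey = isTRUE(cmp$tukey))
        }
        mutate(tidy(fit), comparison = cmp$name, .before = 1)
      }
    })
    p <- file.path(outdir, "tests.csv")
    readr::write_csv(bind_rows(res), p)
    paths <- c(paths, p)
  }
  if (plots) {
    for (val in intersect(c("percent_freezing", "activity_index"),
                          names(metrics))) {
      for (per in intersect(c("tone", "wn"), unique(metrics$period))) {
        gg <- plot_trial_curves(metrics, value = val, period = per)
        p <- file.path(outdir, sprintf("curve_%s_%s.png", val, per))
        ggplot2::ggsave(p, gg, width = 7, height = 4, dpi = 120)
        paths <- c(paths, p)
      }
    }
  }
  invisible(paths)
}

#' Trial-by-trial group mean curves
#'
#' Mean +/- SEM of a metric by trial, one line per group, faceted by session —
#' the standard way trial-wise freezing and activity curves are displayed.
#'
#' @inheritParams summarize_metrics
#' @param period Period to display (e.g. `"tone"` or `"wn"`).
#' @return A ggplot object.
#' @export
plot_trial_curves <- function(metrics, value = "percent_freezing",
                              period = "tone") {
  sm <- summarize_metrics(metrics[metrics$period == period &
                                    metrics$trial_index > 0, ], value)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$trial_index, y = .data$mean,
                                   color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.3) +
    ggplot2::facet_wrap(~session, nrow = 1) +
    ggplot2::labs(x = "Trial", y = value,
                  title = sprintf("%s during the %s period", value, period)) +
    ggplot2::theme_minimal()
}

#' Peri-stimulus event histogram plot
#'
#' @param bins Output of [bin_events()] (optionally with extra grouping
#'   columns bound on).
#' @return A ggplot object.
#' @export
plot_event_histogram <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin_start_s, y = .data$count)) +
    ggplot2::geom_col(width = diff(bins$bin_start_s[1:2]) * 0.9) +
    ggplot2::labs(x = "Time from window start (s)", y = "Events") +
    ggplot2::theme_minimal()
}

#' Raster of event times across the SCS, one row per trial
#'
#' @param events Tibble with `trial_index` and `rel_t_s` (event time relative
#'   to SCS onset).
#' @return A ggplot object.
#' @export
plot_event_raster <- function(events) {
  ggplot2::ggplot(events, ggplot2::aes(x = .data$rel_t_s,
                                       y = factor(.data$trial_index))) +
    ggplot2::geom_point(shape = 108, size = 3) +
    ggplot2::geom_vline(xintercept = 10, linetype = "dotted") +
    ggplot2::labs(x = "Time from SCS onset (s)", y = "Trial") +
    ggplot2::theme_minimal()
}

#' Timeline plot of a stimulus schedule
#'
#' @param object An `scs_schedule`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scs_schedule <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(xmin = .data$onset_s,
                                   xmax = .data$onset_s + .data$duration_s,
                                   ymin = 0, ymax = 1, fill = .data$kind)) +
    ggplot2::geom_rect() +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "Session time (s)", y = NULL,
                  title = sprintf("%s / %s schedule", object$spec$session,
                                  object$spec$group)) +
    ggplot2::theme_minimal()
}
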