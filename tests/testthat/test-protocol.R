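test_that("SCS pip trains have the published structure", {
  ev <- scs_events(0, "standard", 1)
  expect_equal(nrow(ev), 20)
  expect_equal(ev$kind[1], "tone_pip")
  expect_equal(ev$onset_s[1], 0)
  expect_equal(ev$kind[11], "wn_pip")
  expect_equal(ev$onset_s[11], 10)
  expect_true(all(ev$duration_s == 0.5))

  rev <- scs_events(0, "reversed", 1)
  expect_equal(rev$kind[1], "wn_pip")
  expect_equal(rev$kind[11], "tone_pip")
  expect_equal(rev$onset_s, ev$onset_s)

  ev3 <- scs_events(100, "standard", 3)
  expect_equal(ev3$onset_s[20], 119)
  expect_true(all(ev3$trial_index == 3L))

  expect_error(scs_events(-1, "standard", 1), class = "scsflight_input_error")
})

test_that("built-in schedules hit published totals with in-range ISIs for any seed", {
  combos <- expand.grid(
    session = c("PreExp", "CD1", "CD2", "Ext1", "Ext2"),
    group = c("PA", "UN", "SO", "PA_R", "UN_R"),
    seed = c(1L, 17L, 999L), stringsAsFactors = FALSE)
  totals <- c(PreExp = 590, CD1 = 820, CD2 = 820, Ext1 = 1910, Ext2 = 1910)
  for (i in seq_len(nrow(combos))) {
    spec <- session_spec(combos$session[i], combos$group[i], combos$seed[i])
    sch <- build_schedule(spec)
    expect_identical(sch$total_duration, unname(totals[combos$session[i]]))
    # stimulus blocks fit between baseline and tail exactly
    ev <- sch$events
    if (nrow(ev)) {
      expect_gte(min(ev$onset_s), spec$baseline)
      expect_lte(max(ev$onset_s + ev$duration_s), spec$total - spec$tail + 1e-9)
    }
    # every gap between consecutive stimulus blocks lies in the stated range
    blocks <- ev
    blocks$block <- ifelse(blocks$kind == "shock" & blocks$trial_index == 0,
                           paste0("shock", seq_len(nrow(blocks))),
                           paste0("scs", blocks$trial_index))
    if (spec$paired || spec$n_trials == 0 || spec$n_shocks == 0) {
      # gaps between SCS onsets (or shocks for SO)
      ons <- if (spec$n_trials > 0) sch$scs_onsets else
        ev$onset_s[ev$kind == "shock"]
      lens <- if (spec$n_trials > 0) 20 else 1
      gaps <- diff(ons) - lens
    } else {
      # unpaired: gaps between consecutive blocks of any kind
      starts <- sort(unique(c(sch$scs_onsets,
                              ev$onset_s[ev$kind == "shock" & ev$trial_index == 0])))
      ends <- vapply(starts, function(s)
        if (s %in% sch$scs_onsets) s + 20 else s + 1, 0)
      gaps <- starts[-1] - ends[-length(ends)]
    }
    if (length(gaps)) {
      expect_true(all(gaps >= spec$isi_range[1] - 1e-6),
                  label = sprintf("%s/%s ISIs above min", spec$session, spec$group))
      expect_true(all(gaps <= spec$isi_range[2] + 1e-6),
                  label = sprintf("%s/%s ISIs below max", spec$session, spec$group))
    }
  }
})

test_that("paired shocks co-terminate with the SCS", {
  for (g in c("PA", "PA_R")) {
    sch <- build_schedule(session_spec("CD1", g, seed = 4))
    shocks <- sch$events[sch$events$kind == "shock", ]
    expect_equal(nrow(shocks), 5)
    expect_equal(shocks$onset_s + shocks$duration_s - sch$scs_onsets,
                 rep(20, 5))
  }
})

test_that("unpaired schedules keep a guard gap and are not perfectly predictive", {
  for (seed in c(2L, 11L, 31L)) {
    sch <- build_schedule(session_spec("CD2", "UN", seed = seed))
    shocks <- sch$events$onset_s[sch$events$kind == "shock"]
    expect_equal(sch$events$trial_index[sch$events$kind == "shock"],
                 rep(0L, 5))
    for (on in sch$scs_onsets) {
      expect_false(any(shocks >= on & shocks < on + 40),
                   label = sprintf("no shock within SCS+guard at onset %.1f", on))
    }
  }
})

test_that("reversed and standard schedules share onsets, differing only in pip kinds", {
  a <- build_schedule(session_spec("CD2", "PA", seed = 9))
  b <- build_schedule(session_spec("CD2", "PA_R", seed = 9))
  expect_equal(a$events$onset_s, b$events$onset_s)
  expect_equal(a$scs_onsets, b$scs_onsets)
  pip_a <- a$events$kind[a$events$kind != "shock"]
  pip_b <- b$events$kind[b$events$kind != "shock"]
  expect_true(all(pip_a != pip_b))
})

test_that("CD1 and CD2 derive different stimulus timing from one seed", {
  a <- build_schedule(session_spec("CD1", "PA", seed = 7))
  b <- build_schedule(session_spec("CD2", "PA", seed = 7))
  expect_false(isTRUE(all.equal(a$scs_onsets, b$scs_onsets)))
})

test_that("schedule event counts and degenerate schedules are right", {
  cd2 <- build_schedule(session_spec("CD2", "PA", seed = 1))
  expect_equal(nrow(cd2$events), 105)  # 5 x 20 pips + 5 shocks

  empty <- build_schedule(custom_spec(baseline = 30, n_trials = 0,
                                      n_shocks = 0, tail = 20))
  expect_equal(nrow(empty$events), 0)
  expect_equal(empty$total_duration, 50)
})

test_that("infeasible ISI constraints raise a constraint error naming the deficit", {
  bad <- custom_spec(baseline = 10, n_trials = 3, isi_range = c(5, 6),
                     tail = 10, total = 500)
  expect_error(build_schedule(bad), "ISI range",
               class = "scsflight_constraint_error")
})

test_that("schedules round-trip through the event-table file format", {
  sch <- build_schedule(session_spec("PreExp", "UN_R", seed = 13))
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sch, path)
  back <- read_schedule(path)
  expect_equal(back$events, sch$events)
  expect_equal(back$scs_onsets, sch$scs_onsets)
  expect_equal(back$total_duration, sch$total_duration)
  expect_equal(back$spec$isi_range, sch$spec$isi_range)

  empty <- build_schedule(custom_spec(baseline = 30, n_trials = 0,
                                      n_shocks = 0, tail = 20))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_schedule(empty, p2)
  expect_equal(nrow(read_schedule(p2)$events), 0)
})
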