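fz <- function(starts, ends) tibble::tibble(behavior = "freeze",
                                            start_s = starts, end_s = ends)

test_that("period windows follow stimulus content, including reversed SCS", {
  pa <- build_schedule(session_spec("CD2", "PA", seed = 1))
  w <- period_windows(pa)
  expect_equal(sum(w$period == "baseline"), 1)
  for (per in c("pre_scs", "tone", "wn", "shock")) {
    expect_equal(sum(w$period == per & w$trial_index > 0), 5)
  }
  t1 <- w[w$trial_index == 1 & w$period %in% c("tone", "wn"), ]
  expect_equal(t1$period[order(t1$start_s)], c("tone", "wn"))
  expect_true(all(w$end_s[w$period %in% c("pre_scs", "tone", "wn")] -
                    w$start_s[w$period %in% c("pre_scs", "tone", "wn")] == 10))

  par <- build_schedule(session_spec("CD2", "PA_R", seed = 1))
  wr <- period_windows(par)
  r1 <- wr[wr$trial_index == 1 & wr$period %in% c("tone", "wn"), ]
  expect_equal(r1$period[order(r1$start_s)], c("wn", "tone"))

  ext <- period_windows(build_schedule(session_spec("Ext1", "UN", seed = 1)))
  expect_equal(sum(ext$period == "tone"), 16)
  expect_equal(sum(ext$period == "shock"), 0)
})

test_that("percent freezing is overlap-weighted and split-invariant", {
  expect_equal(percent_freezing(fz(0, 10), 0, 10), 100)
  expect_equal(percent_freezing(fz(numeric(0), numeric(0)), 0, 10), 0)
  # 5 s bout, half inside a 10 s window
  expect_equal(percent_freezing(fz(7.5, 12.5), 0, 10), 25)
  # splitting a bout anywhere changes nothing
  expect_equal(percent_freezing(fz(c(2, 4.3), c(4.3, 8)), 0, 10),
               percent_freezing(fz(2, 8), 0, 10))
  # additivity across disjoint subwindows (as absolute time)
  b <- fz(c(1, 6, 11), c(3, 9.5, 14))
  t_all <- percent_freezing(b, 0, 20) * 20
  t_sub <- percent_freezing(b, 0, 7) * 7 + percent_freezing(b, 7, 20) * 13
  expect_equal(t_all, t_sub)
  expect_error(percent_freezing(fz(0, 1), 5, 5), class = "scsflight_input_error")
})

test_that("the activity-index denominator pools pre-SCS speed with a floor", {
  sch <- build_schedule(session_spec("CD2", "PA", seed = 2))
  w <- period_windows(sch)
  n <- sch$total_duration * 30
  const3 <- speed_of(rep(3, n))
  d <- pre_scs_average_speed(const3, w)
  expect_equal(as.numeric(d), 3)
  expect_false(attr(d, "floored"))

  d0 <- pre_scs_average_speed(speed_of(rep(0, n)), w)
  expect_equal(as.numeric(d0), 0.1)
  expect_true(attr(d0, "floored"))

  expect_error(pre_scs_average_speed(const3, w[w$period == "tone", ]),
               class = "scsflight_input_error")
})

test_that("activity index = CS/pre-SCS speed ratio plus jumps in window", {
  sp <- speed_of(rep(10, 600))
  no_jumps <- tibble::tibble(behavior = character(), start_s = numeric(),
                             end_s = numeric())
  expect_equal(activity_index(sp, no_jumps, 0, 10, denom = 10), 1)
  j3 <- tibble::tibble(behavior = "jump", start_s = c(1, 5, 9.9),
                       end_s = c(1.3, 5.3, 10.2))
  expect_equal(activity_index(sp, j3, 0, 10, denom = 2), 8)
  expect_equal(activity_index(speed_of(rep(0, 600)), no_jumps, 0, 10, 2), 0)
  # jumps starting outside the window do not count
  expect_equal(activity_index(sp, j3, 0, 5, denom = 10), 2)
  # with no jumps the score is scale-invariant
  expect_equal(activity_index(speed_of(rep(30, 600)), no_jumps, 0, 10, 6),
               activity_index(speed_of(rep(10, 600)), no_jumps, 0, 10, 2))
  expect_error(activity_index(sp, j3, 0, 10, denom = 0),
               class = "scsflight_input_error")
})

test_that("peri-stimulus histograms bin bout starts half-open", {
  no_ev <- tibble::tibble(behavior = "jump", start_s = numeric(),
                          end_s = numeric())
  h0 <- bin_events(no_ev, 0, 10)
  expect_equal(nrow(h0), 10)
  expect_true(all(h0$count == 0))

  ev <- tibble::tibble(behavior = "jump", start_s = c(0, 9.5),
                       end_s = c(0.3, 9.8))
  expect_equal(bin_events(ev, 0, 10)$count, c(1, rep(0, 8), 1))

  # an event on a bin edge belongs to the later bin
  edge <- tibble::tibble(behavior = "jump", start_s = 3, end_s = 3.2)
  expect_equal(which(bin_events(edge, 0, 10)$count == 1), 4)

  expect_error(bin_events(ev, 0, 10, bin_width = 3),
               class = "scsflight_input_error")
})

test_that("difference scores compare first-k and last-k trial bins", {
  expect_equal(as.numeric(diff_score(rep(50, 16))), 0)
  series <- c(rep(80, 4), rep(60, 8), rep(40, 4))
  expect_equal(as.numeric(diff_score(series)), 40)
  expect_equal(as.numeric(diff_score(c(10, 30), k = 1)), -20)
  expect_equal(as.numeric(diff_score(series, orientation = "increase")), -40)
  expect_error(diff_score(rep(1, 7), k = 4), class = "scsflight_input_error")
})

test_that("pre-SCS vs CS differences are per-animal means over trials", {
  mk <- function(id, pre, cs) tibble::tibble(
    animal_id = id, session = "CD2", trial_index = rep(1:5, 2),
    period = rep(c("pre_scs", "tone"), each = 5),
    percent_freezing = c(pre, cs))
  m <- rbind(mk("a", rep(20, 5), rep(60, 5)), mk("b", rep(30, 5), rep(30, 5)))
  d <- pre_vs_cs_diff(m, "tone")
  expect_equal(d$diff[d$animal_id == "a"], 40)
  expect_equal(d$diff[d$animal_id == "b"], 0)

  bad <- mk("a", rep(20, 5), rep(60, 5))[-1, ]
  expect_error(pre_vs_cs_diff(bad, "tone"), class = "scsflight_input_error")
})

test_that("cohort percentages count animals with any bout start in the windows", {
  w <- tibble::tibble(start_s = c(0, 20), end_s = c(10, 30))
  mkb <- function(ts) tibble::tibble(behavior = "dart", start_s = ts,
                                     end_s = ts + 0.3)
  animals <- c(lapply(c(1, 2, 3, 4, 5), function(t) mkb(t)),
               lapply(1:15, function(i) mkb(15)))  # 15 dart outside windows
  expect_equal(cohort_percentage(animals, w, "dart"), 25)
  expect_equal(cohort_percentage(lapply(1:4, function(i) mkb(numeric(0))),
                                 w, "dart"), 0)
  expect_equal(cohort_percentage(lapply(1:4, function(i) mkb(5)), w, "dart"),
               100)
  expect_error(cohort_percentage(list(), w, "dart"),
               class = "scsflight_input_error")
})

test_that("cohort subsampling is seeded, distinct and size-checked", {
  ids <- sprintf("m%02d", 1:32)
  s1 <- subsample_cohort(ids, 20, seed = 9)
  s2 <- subsample_cohort(ids, 20, seed = 9)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 20)
  expect_setequal(subsample_cohort(ids, 32, seed = 1), ids)
  expect_error(subsample_cohort(ids, 40, seed = 1),
               class = "scsflight_input_error")
})

test_that("trial_metrics assembles a full per-window table", {
  sim <- simulate_session(build_schedule(session_spec("CD2", "PA", seed = 20)),
                          sim_params("PA"), animal_seed = 11)
  b <- detect_bouts(sim$trajectory)
  m <- trial_metrics(sim$trajectory, b, sim$schedule, animal_id = "m1",
                     sex = "F")
  w <- period_windows(sim$schedule)
  expect_equal(nrow(m), nrow(w))
  expect_true(all(m$percent_freezing >= 0 & m$percent_freezing <= 100))
  expect_true(all(m$jumps >= 0 & m$darts >= 0))
  expect_true(all(is.na(m$activity_index[!m$period %in% c("tone", "wn")])))
  expect_true(all(!is.na(m$activity_index[m$period %in% c("tone", "wn")])))
  expect_true(all(m$distance_cm >= 0))

  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics(m, path)
  back <- read_metrics(path)
  expect_equal(back$percent_freezing, m$percent_freezing)
})
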