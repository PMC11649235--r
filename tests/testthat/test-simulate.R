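pa_cd2 <- function(seed = 20L) build_schedule(session_spec("CD2", "PA", seed))

test_that("simulation is deterministic given (seed, animal_seed)", {
  p <- sim_params("PA")
  a <- simulate_session(pa_cd2(), p, animal_seed = 3)
  b <- simulate_session(pa_cd2(), p, animal_seed = 3)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$truth_bouts, b$truth_bouts)
  c <- simulate_session(pa_cd2(), p, animal_seed = 4)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("an all-freeze parameterization yields one session-long freeze bout", {
  p <- sim_params("PA")
  p$state_table <- dplyr::mutate(p$state_table, p_freeze = 1, p_locomote = 0,
                                 p_dart = 0, p_jump = 0)
  p$tail_rattle <- p$tail_rattle[0, ]
  sim <- simulate_session(pa_cd2(), p, animal_seed = 1)
  sp <- compute_speed(sim$trajectory)
  expect_true(all(sp$v_cms < p$eps))
  tb <- sim$truth_bouts
  expect_equal(nrow(tb), 1)
  expect_equal(tb$behavior, "freeze")
  expect_equal(tb$end_s - tb$start_s, sim$schedule$total_duration)
})

test_that("simulated positions stay inside the arena and speeds are non-negative", {
  p <- sim_params("PA")
  sim <- simulate_session(pa_cd2(), p, animal_seed = 9)
  r_px <- (p$arena_diameter / 2) / p$calibration
  d <- sqrt((sim$trajectory$x_px - 320)^2 + (sim$trajectory$y_px - 240)^2)
  expect_true(all(d <= r_px + 1e-9))
  expect_true(all(compute_speed(sim$trajectory)$v_cms >= 0))
})

test_that("truth bouts tile the session and airborne matches jump bouts", {
  sim <- simulate_session(pa_cd2(), sim_params("PA"), animal_seed = 2)
  tb <- sim$truth_bouts[sim$truth_bouts$behavior != "tail_rattle", ]
  expect_equal(tb$start_s[1], 0)
  expect_equal(tb$start_s[-1], tb$end_s[-nrow(tb)])
  expect_equal(tb$end_s[nrow(tb)], sim$schedule$total_duration)
  jumps <- tb[tb$behavior == "jump", ]
  tr <- sim$trajectory
  in_jump <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(jumps))) {
    in_jump <- in_jump | (tr$t_s >= jumps$start_s[i] - 1e-9 &
                            tr$t_s < jumps$end_s[i] - 1e-9)
  }
  expect_equal(tr$airborne == 1L, in_jump)
})

test_that("PA CD2 defaults put jumps in white noise, not tone (20 animals)", {
  co <- simulate_cohort("PA", 20, "CD2", seed = 5)
  w <- period_windows(co$schedule[[1]])
  n_in <- function(bouts, per) {
    ww <- w[w$period == per, ]
    sum(vapply(seq_len(nrow(ww)), function(i)
      sum(bouts$behavior == "jump" & bouts$start_s >= ww$start_s[i] &
            bouts$start_s < ww$end_s[i]), 0L))
  }
  wn <- sum(vapply(co$truth_bouts, n_in, 0L, per = "wn"))
  tone <- sum(vapply(co$truth_bouts, n_in, 0L, per = "tone"))
  expect_gt(wn, tone)
  expect_gt(wn, 0)
})

test_that("cohorts get equal sex split, per-animal seeds and stable schedules", {
  co <- simulate_cohort("PA", 32, "CD2", seed = 7)
  expect_equal(nrow(co), 32)
  expect_equal(sum(co$sex == "M"), 16)
  expect_equal(sum(co$sex == "F"), 16)
  expect_equal(dplyr::n_distinct(co$animal_id), 32)

  one <- simulate_cohort("UN", 1, "CD2", seed = 7)
  expect_equal(nrow(one), 1)

  a <- simulate_cohort("UN", 2, "CD2", seed = 1)
  b <- simulate_cohort("UN", 2, "CD2", seed = 2)
  expect_false(identical(a$trajectory[[1]], b$trajectory[[1]]))
  expect_identical(a$schedule[[1]]$events, b$schedule[[1]]$events)

  expect_error(simulate_cohort("PA", 4, character(0)),
               class = "scsflight_input_error")
  expect_error(simulate_cohort("PA", 0, "CD2"),
               class = "scsflight_input_error")
})

test_that("detectors recover simulated freeze and dart bouts with F1 >= 0.9", {
  f1s_f <- c(); f1s_d <- c()
  for (a in 1:3) {
    sim <- simulate_session(pa_cd2(), sim_params("PA"), animal_seed = 100 + a)
    sp <- compute_speed(sim$trajectory)
    tb <- sim$truth_bouts
    f1s_f <- c(f1s_f, bout_f1(tb[tb$behavior == "freeze", ],
                              detect_freezing(sp)))
    f1s_d <- c(f1s_d, bout_f1(tb[tb$behavior == "dart", ],
                              detect_darts(sp)))
  }
  expect_gte(mean(f1s_f), 0.9)
  expect_gte(mean(f1s_d), 0.9)
})

test_that("measured freezing converges to the configured occupancy", {
  # single-p quick check; the sweep over p is in the acceptance suite
  p <- sim_params("UN")
  p$state_table <- dplyr::mutate(p$state_table, p_freeze = 0.3,
                                 p_locomote = 0.7, p_dart = 0, p_jump = 0)
  p$tail_rattle <- p$tail_rattle[0, ]
  sched <- build_schedule(custom_spec(baseline = 30, n_trials = 2,
                                      isi_range = c(40, 60), tail = 20,
                                      session = "CD2", group = "UN"))
  fr <- vapply(1:12, function(a) {
    sim <- simulate_session(sched, p, animal_seed = a)
    percent_freezing(detect_freezing(compute_speed(sim$trajectory)),
                     0, sched$total_duration)
  }, 0)
  expect_lt(abs(mean(fr) - 30), 3)
})

test_that("unknown groups are rejected", {
  expect_error(sim_params("XX"))
})
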