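test_that("sensory channels are gated exactly by condition", {
  course <- generate_course(seed = 41)
  st <- vehicle_state(x = 5, y = 0.4)
  pND <- perceive(st, course, "ND", s_hint = 5)
  pVO <- perceive(st, course, "VO", s_hint = 5)
  pSS <- perceive(st, course, "SS", s_hint = 5)
  expect_true(is.finite(pND$near_deviation))
  expect_true(is.na(pND$audio_deviation))
  expect_true(is.na(pVO$near_deviation))
  expect_true(is.na(pVO$audio_deviation))
  expect_true(is.finite(pVO$far_curvature))
  expect_true(is.na(pSS$near_deviation))
  expect_true(is.finite(pSS$audio_deviation))
})

test_that("audio decoding noise decays monotonically with training", {
  p <- driver_params()
  sds <- vapply(0:39, function(t) sonolane:::audio_noise_sd(p, t), numeric(1))
  expect_true(all(diff(sds) < 0))
  expect_equal(sds[1], p$sigma_audio0)
  expect_gt(sds[40], p$sigma_audio_min)
  ws <- vapply(0:39, function(t) sonolane:::audio_weight(p, t), numeric(1))
  expect_true(all(diff(ws) > 0))
  expect_true(all(ws <= 1))
})

test_that("a zero-noise percept equals ground truth", {
  course <- generate_course(seed = 42)
  st <- vehicle_state(x = 30, y = -0.7, heading = 0.02)
  p <- perceive(st, course, "ND", params = quiet_params(), s_hint = 30)
  truth <- sonolane:::true_percept(course, st, 30)
  expect_equal(p$near_deviation, truth$deviation)
  expect_equal(p$heading_error, truth$heading_error)
  expect_equal(p$far_curvature, truth$far_curvature)
})

test_that("the steering law is an equilibrium at zero and corrects leftward drift rightward", {
  qp <- quiet_params()
  zero <- list(far_curvature = 0, near_deviation = 0, audio_deviation = NA,
               heading_error = 0)
  expect_equal(steer(zero, qp), 0)

  left <- list(far_curvature = 0, near_deviation = 0.5, audio_deviation = NA,
               heading_error = 0)
  expect_lt(steer(left, qp), 0)

  vp <- vehicle_params()
  curve <- list(far_curvature = 0.01, near_deviation = 0, audio_deviation = NA,
                heading_error = 0)
  expect_equal(steer(curve, qp),
               vp$steering_ratio * atan(vp$wheelbase * 0.01))
})

test_that("the compensatory loop recovers a 1 m offset within 10 s", {
  course <- generate_course(seed = 43, curv_range = c(1e-9, 2e-9))
  qp <- quiet_params()
  vp <- vehicle_params()
  st <- vehicle_state(x = 0, y = 1)  # 1 m left of a (numerically) straight road
  dev_trace <- numeric(600)
  s_hint <- 0
  for (i in 1:600) {
    pc <- sonolane:::true_percept(course, st, s_hint)
    s_hint <- pc$s_proj
    dev_trace[i] <- pc$deviation
    cmd <- -qp$k_comp * pc$deviation - qp$k_head * pc$heading_error
    st <- step_vehicle(st, cmd, vp)
  }
  expect_equal(dev_trace[1], 1, tolerance = 1e-6)
  expect_lt(abs(dev_trace[600]), 0.05)
})

test_that("participant sampling is deterministic, bounded and heterogeneous", {
  pop <- default_population()
  a <- sample_participant(123, 4, pop)
  b <- sample_participant(123, 4, pop)
  expect_identical(a, b)

  degenerate <- pop
  degenerate$jitter_sd <- 0
  fixed <- sample_participant(1, 1, degenerate)
  expect_equal(unlist(unclass(fixed)), setNames(pop$mean, pop$param))

  many <- sample_participants(55, 15)
  expect_identical(nrow(many), 15L)
  expect_identical(anyDuplicated(many$k_comp), 0L)
  for (j in seq_len(nrow(pop))) {
    expect_true(all(many[[pop$param[j]]] >= pop$lower[j] - 1e-12))
    expect_true(all(many[[pop$param[j]]] <= pop$upper[j] + 1e-12))
  }
})

test_that("compiled and R reference simulation paths agree at zero noise", {
  course <- generate_course(seed = 44)
  for (cond in c("ND", "SS", "VO")) {
    agent <- driver_agent(quiet_params(), cond)
    log_cpp <- simulate_trial(course, agent, duration = 10, seed = 77)
    set.seed(77)
    ctrl <- sonolane:::make_driver_controller(agent)
    log_r <- simulate_trial(course, ctrl, duration = 10, seed = NULL)
    expect_lt(max(abs(log_cpp$x - log_r$x)), 1e-9)
    expect_lt(max(abs(log_cpp$deviation - log_r$deviation)), 1e-9)
    expect_lt(max(abs(log_cpp$sw_angle - log_r$sw_angle)), 1e-9)
  }
})

test_that("SS agents log ear levels; others do not", {
  course <- generate_course(seed = 45)
  ss_log <- simulate_trial(course, driver_agent(condition = "SS"),
                           duration = 5, seed = 8)
  nd_log <- simulate_trial(course, driver_agent(condition = "ND"),
                           duration = 5, seed = 8)
  expect_true(all(is.finite(ss_log$level_L)))
  expect_equal(ss_log$level_L - ss_log$level_R, 50 * ss_log$deviation,
               tolerance = 1e-9)
  expect_true(all(is.na(nd_log$level_L)))
})

test_that("visual occlusion degrades lane-keeping accuracy at the population defaults", {
  n <- 15
  sdlp_by <- function(cond, trial_index) {
    vapply(seq_len(n), function(i) {
      pars <- sample_participant(900, i)
      co <- generate_course(seed = 5000 + i)
      log <- simulate_trial(co, driver_agent(pars, cond, trial_index),
                            duration = 60, seed = 6000 + 100 * trial_index + i)
      trial_sdlp(log)
    }, numeric(1))
  }
  nd0 <- sdlp_by("ND", 0)
  vo0 <- sdlp_by("VO", 0)
  expect_gt(mean(vo0), mean(nd0))

  # the auditory channel is exploited progressively across training
  ss_means <- vapply(c(0, 13, 26, 39),
                     function(t) mean(sdlp_by("SS", t)), numeric(1))
  expect_true(all(diff(ss_means) < 0))
  nd39 <- sdlp_by("ND", 39)
  expect_lt(abs(mean(sdlp_by("SS", 39)) - mean(nd39)) / mean(nd39), 0.2)
})

test_that("steering stability overlaps across conditions", {
  n <- 12
  swv_by <- function(cond) {
    vapply(seq_len(n), function(i) {
      pars <- sample_participant(901, i)
      co <- generate_course(seed = 7000 + i)
      log <- simulate_trial(co, driver_agent(pars, cond, 0),
                            duration = 60, seed = 8000 + i)
      trial_swv(log, co)
    }, numeric(1))
  }
  nd <- swv_by("ND"); vo <- swv_by("VO")
  d <- abs(mean(nd) - mean(vo)) / sqrt((var(nd) + var(vo)) / 2)
  expect_lt(d, 1)
})
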