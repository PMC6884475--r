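make_dev_log <- function(deviation, dt = 1 / 60, kind = "straight") {
  n <- length(deviation)
  log <- tibble::tibble(
    t = (seq_len(n) - 1) * dt, s_proj = seq_len(n),
    deviation = deviation, sw_angle = 0,
    segment_kind = rep_len(kind, n)
  )
  attr(log, "dt") <- dt
  log
}

test_that("SDLP matches closed forms on constructed deviation series", {
  expect_equal(trial_sdlp(make_dev_log(rep(0.8, 500))), 0)

  # sinusoid of amplitude A over whole periods: SD = A / sqrt(2)
  a <- 0.6
  t <- seq(0, 10, by = 1 / 60)[-601]
  expect_lt(abs(trial_sdlp(make_dev_log(a * sin(2 * pi * 0.5 * t))) -
                  a / sqrt(2)), 1e-3)

  expect_lt(abs(trial_sdlp(make_dev_log(rep(c(0, 1, 0, -1), 250))) -
                  1 / sqrt(2)), 1e-3)

  expect_error(trial_sdlp(make_dev_log(numeric(0))), "empty")
})

test_that("SDLP is shift-invariant and scale-equivariant; SWV is sign-symmetric", {
  set.seed(1)
  x <- rnorm(300)
  expect_equal(trial_sdlp(make_dev_log(x + 5)), trial_sdlp(make_dev_log(x)))
  expect_equal(trial_sdlp(make_dev_log(-2.5 * x)),
               2.5 * trial_sdlp(make_dev_log(x)))

  log <- two_curve_log()
  flipped <- log
  flipped$sw_angle <- -flipped$sw_angle
  attr(flipped, "dt") <- attr(log, "dt")
  expect_equal(trial_swv(flipped), trial_swv(log))
})

test_that("curve windows partition arc-projected records", {
  course <- generate_course(seed = 61)
  arcs <- course$segments[course$segments$kind == "arc", ]

  # one arc fully traversed -> exactly one window
  s <- seq(arcs$start_s[1] - 20, arcs$start_s[1] + arcs$length[1] + 20, by = 0.4)
  pose <- centerline_pose(course, s)
  log <- tibble::tibble(t = seq_along(s) * 1 / 60, s_proj = s,
                        deviation = 0, sw_angle = 0)
  w <- curve_windows(log, course)
  expect_identical(nrow(w), 1L)

  # trial ending mid-arc -> final window truncated at the trial end
  s2 <- seq(arcs$start_s[2] - 20, arcs$start_s[2] + arcs$length[2] / 2, by = 0.4)
  log2 <- tibble::tibble(t = seq_along(s2) * 1 / 60, s_proj = s2,
                         deviation = 0, sw_angle = 0)
  w2 <- curve_windows(log2, course)
  expect_identical(nrow(w2), 1L)
  expect_equal(w2$t_end, max(log2$t))

  # bookkeeping identity: union of windows = all arc records
  log3 <- simulate_trial(course, driver_agent(condition = "ND"),
                         duration = 30, seed = 3)
  w3 <- curve_windows(log3, course)
  expect_identical(sum(w3$i_end - w3$i_start + 1L),
                   sum(log3$segment_kind == "arc"))
})

test_that("SWV reduces to hand values on constructed logs", {
  # two windows with per-window maximum velocities 2 and 4 deg/s
  expect_equal(trial_swv(two_curve_log()), 3, tolerance = 1e-6)

  # constant steering everywhere -> 0
  flat <- two_curve_log()
  flat$sw_angle <- rep(0.3, nrow(flat))
  attr(flat, "dt") <- 0.1
  expect_equal(trial_swv(flat), 0)

  # no curve window -> missing, not zero
  none <- two_curve_log()
  none$segment_kind <- "straight"
  expect_true(is.na(trial_swv(none)))

  # single window with constant rate r -> r (deg/s)
  n <- 100
  one <- tibble::tibble(
    t = (seq_len(n) - 1) * 0.1, s_proj = seq_len(n),
    deviation = 0,
    sw_angle = (seq_len(n) - 1) * 0.1 * (5 * pi / 180),
    segment_kind = rep(c("straight", "arc"), each = 50)
  )
  attr(one, "dt") <- 0.1
  expect_equal(trial_swv(one), 5, tolerance = 1e-9)
})

test_that("trial_metrics bundles both metrics with curve counts", {
  course <- generate_course(seed = 62)
  log <- simulate_trial(course, driver_agent(condition = "ND"),
                        duration = 30, seed = 4)
  m <- trial_metrics(log, course)
  expect_named(m, c("sdlp", "swv", "n_curves", "off_road"))
  expect_identical(m$n_curves, nrow(curve_windows(log, course)))
  expect_gt(m$sdlp, 0)
  expect_gt(m$swv, 0)
  expect_false(m$off_road)
})
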