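test_that("generated segments respect ranges, alternation and contiguity", {
  course <- big_course()
  seg <- course$segments
  expect_gt(nrow(seg), 1000)

  straights <- seg[seg$kind == "straight", ]
  arcs <- seg[seg$kind == "arc", ]
  expect_true(all(straights$length >= 50 & straights$length <= 150))
  expect_true(all(straights$curvature == 0))
  expect_true(all(abs(arcs$curvature) >= 1 / 180 &
                    abs(arcs$curvature) <= 1 / 80))
  expect_true(all(arcs$length >= 50 & arcs$length <= 150))

  # strict straight/arc alternation and alternating bend direction
  expect_true(all(seg$kind[-1] != seg$kind[-nrow(seg)]))
  signs <- sign(arcs$curvature)
  expect_true(all(signs[-1] == -signs[-length(signs)]))

  # contiguity and total length
  expect_equal(seg$start_s, cumsum(c(0, seg$length))[seq_len(nrow(seg))])
  expect_equal(course$total_length, sum(seg$length))
  expect_gte(course$total_length, 110000)
})

test_that("course generation is seed-deterministic", {
  a <- generate_course(seed = 7)
  b <- generate_course(seed = 7)
  expect_identical(write_course_json(a), write_course_json(b))
  expect_false(identical(write_course_json(a),
                         write_course_json(generate_course(seed = 8))))
})

test_that("course generation rejects invalid parameters", {
  expect_error(generate_course(1, total_length = -5), "total_length")
  expect_error(generate_course(1, curv_range = c(1 / 80, 1 / 180)),
               "curv_range")
  expect_error(generate_course(1, straight_range = c(0, 150)),
               "straight_range")
})

test_that("centerline pose matches numerical integration of the path", {
  course <- generate_course(seed = 2)
  # oracle: midpoint-rule integration of dx/ds = cos(heading),
  # dy/ds = sin(heading), with heading taken from the exact integral of
  # the piecewise-constant curvature profile
  ds <- 1e-3
  s_grid <- seq(0, course$total_length, by = ds)
  s_mid <- s_grid[-1] - ds / 2
  seg <- course$segments
  h_at_start <- cumsum(c(0, seg$curvature * seg$length))
  idx <- pmin(pmax(findInterval(s_mid, seg$start_s), 1), nrow(seg))
  h_mid <- h_at_start[idx] + seg$curvature[idx] * (s_mid - seg$start_s[idx])
  x_int <- cumsum(cos(h_mid) * ds)
  y_int <- cumsum(sin(h_mid) * ds)

  probe_idx <- round(seq(1, length(s_grid) - 1, length.out = 200))
  pose <- centerline_pose(course, s_grid[probe_idx + 1])
  expect_lt(max(abs(pose$x - x_int[probe_idx])), 1e-6)
  expect_lt(max(abs(pose$y - y_int[probe_idx])), 1e-6)

  # heading advances by curvature * arc length within an arc
  arc <- course$segments[course$segments$kind == "arc", ][1, ]
  h1 <- centerline_pose(course, arc$start_s + 10)$heading
  h2 <- centerline_pose(course, arc$start_s + 40)$heading
  expect_equal(h2 - h1, arc$curvature * 30, tolerance = 1e-12)

  expect_equal(unlist(centerline_pose(course, 0)[, c("x", "y", "heading")]),
               c(x = 0, y = 0, heading = 0))
  expect_error(centerline_pose(course, course$total_length + 1), "outside")
  expect_error(centerline_pose(course, -0.5), "outside")
})

test_that("lateral deviation is zero on the centerline and recovers normal offsets", {
  course <- generate_course(seed = 3)
  s <- seq(0, course$total_length, length.out = 200)
  pose <- centerline_pose(course, s)
  on_line <- lateral_deviation(course, pose$x, pose$y, s_hint = s)
  expect_lt(max(abs(on_line$deviation)), 1e-9)
  expect_lt(max(abs(on_line$s_proj - s)), 1e-6)

  # round trip: displace along the local left normal by d, recover d
  for (d in c(-1.5, -0.3, 0.4, 1.2)) {
    px <- pose$x - d * sin(pose$heading)
    py <- pose$y + d * cos(pose$heading)
    back <- lateral_deviation(course, px, py, s_hint = s)
    expect_lt(max(abs(back$deviation - d)), 1e-6)
  }
})

test_that("arc projection agrees with brute-force nearest-point search", {
  course <- generate_course(seed = 4)
  arc <- course$segments[course$segments$kind == "arc", ][2, ]
  s0 <- arc$start_s + arc$length / 2
  pose <- centerline_pose(course, s0)
  # outward normal of the bend = away from the arc centre
  outward <- -sign(arc$curvature)
  px <- pose$x - outward * 0.5 * sin(pose$heading)
  py <- pose$y + outward * 0.5 * cos(pose$heading)

  # oracle: dense sampling of the centerline
  s_dense <- seq(max(0, s0 - 30), min(course$total_length, s0 + 30), by = 1e-4)
  dense <- centerline_pose(course, s_dense)
  dist2 <- (dense$x - px)^2 + (dense$y - py)^2
  i_best <- which.min(dist2)

  res <- lateral_deviation(course, px, py, s_hint = s0)
  expect_equal(res$s_proj, s_dense[i_best], tolerance = 1e-3)
  expect_equal(abs(res$deviation), 0.5, tolerance = 1e-9)
  expect_equal(sign(res$deviation), outward)
})

test_that("off-road points error by default and flag on request", {
  course <- generate_course(seed = 5)
  pose <- centerline_pose(course, 10)
  px <- pose$x - 20 * sin(pose$heading)
  py <- pose$y + 20 * cos(pose$heading)
  expect_error(lateral_deviation(course, px, py, s_hint = 10), "off-road")
  flagged <- lateral_deviation(course, px, py, s_hint = 10,
                               off_road = "flag")
  expect_true(flagged$off_road)
  expect_equal(flagged$deviation, 20, tolerance = 1e-6)
})

test_that("JSON serialization round-trips the course geometry", {
  course <- generate_course(seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_course_json(course, path)
  back <- read_course_json(path)
  expect_equal(back$segments$length, course$segments$length)
  expect_equal(back$segments$curvature, course$segments$curvature)
  expect_equal(back$lane_width, course$lane_width)
  pose_a <- centerline_pose(course, 777)
  pose_b <- centerline_pose(back, 777)
  expect_equal(pose_a$x, pose_b$x, tolerance = 1e-9)
})
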