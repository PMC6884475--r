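#' Vehicle parameters for the kinematic bicycle model
#'
#' The simulated vehicle is a kinematic bicycle (no slip, no lateral tire
#' dynamics): adequate for constant-speed driving at 80 km/h on curvature
#' below 1/80 m^-1, and fully deterministic. The road-wheel angle is the
#' steering-wheel angle divided by `steering_ratio`; steering commands are
#' clamped to `sw_max` and slew-limited to `sw_rate_max`.
#'
#' @param wheelbase Wheelbase in metres (default 2.7).
#' @param steering_ratio Steering-wheel to road-wheel ratio (default 15).
#' @param sw_max Maximum steering-wheel angle in rad (default `2 * pi`).
#' @param sw_rate_max Maximum steering-wheel rate in rad/s (default `2 * pi`).
#' @return A `vehicle_params` list.
#' @export
vehicle_params <- function(wheelbase = 2.7, steering_ratio = 15,
                           sw_max = 2 * pi, sw_rate_max = 2 * pi) {
  for (nm in c("wheelbase", "steering_ratio", "sw_max", "sw_rate_max")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  structure(list(wheelbase = wheelbase, steering_ratio = steering_ratio,
                 sw_max = sw_max, sw_rate_max = sw_rate_max),
            class = "vehicle_params")
}

#' Initial vehicle state
#'
#' @param x,y Position in metres.
#' @param heading Heading in rad.
#' @param speed Speed in m/s (constant within a trial; default 80 km/h).
#' @param sw_angle Steering-wheel angle in rad.
#' @return A `vehicle_state` list.
#' @export
vehicle_state <- function(x = 0, y = 0, heading = 0,
                          speed = 80 / 3.6, sw_angle = 0) {
  stopifnot_scalar_number(speed, "speed", positive = TRUE)
  structure(list(x = x, y = y, heading = heading, speed = speed,
                 sw_angle = sw_angle),
            class = "vehicle_state")
}

#' Advance the vehicle one time step
#'
#' Semi-implicit Euler update of the kinematic bicycle: the commanded
#' steering-wheel angle is slew-limited and clamped, the heading advances by
#' `v * tan(delta) / wheelbase * dt` with `delta = sw / steering_ratio`, and
#' the position then advances `v * dt` along the updated heading, so the
#' per-step displacement norm is exactly `v * dt`.
#'
#' @param state A `vehicle_state`.
#' @param sw_command Commanded steering-wheel angle in rad.
#' @param params A [vehicle_params()] list.
#' @param dt Time step in seconds (default 1/60).
#' @return The updated `vehicle_state`.
#' @examples
#' s <- vehicle_state()
#' step_vehicle(s, sw_command = 0.1, vehicle_params())
#' @export
step_vehicle <- function(state, sw_command, params = vehicle_params(),
                         dt = 1 / 60) {
  stopifnot(inherits(state, "vehicle_state"))
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  if (!is.numeric(sw_command) || length(sw_command) != 1L ||
      !is.finite(sw_command)) {
    stop("`sw_command` must be a single finite number", call. = FALSE)
  }
  dmax <- params$sw_rate_max * dt
  sw <- state$sw_angle + clamp(sw_command - state$sw_angle, -dmax, dmax)
  sw <- clamp(sw, -params$sw_max, params$sw_max)
  delta <- sw / params$steering_ratio
  heading <- state$heading + state$speed * tan(delta) / params$wheelbase * dt
  vehicle_state(
    x = state$x + state$speed * cos(heading) * dt,
    y = state$y + state$speed * sin(heading) * dt,
    heading = heading, speed = state$speed, sw_angle = sw
  )
}

# Ground-truth percept handed to function controllers: the projection of the
# current pose plus road geometry at and ahead of the foot point.
true_percept <- function(course, state, s_hint, preview_time = 1) {
  pr <- lateral_deviation(course, state$x, state$y, s_hint = s_hint,
                          off_road = "flag")
  here <- centerline_pose(course, pr$s_proj)
  s_ahead <- min(pr$s_proj + state$speed * preview_time,
                 course$total_length)
  ahead <- centerline_pose(course, s_ahead)
  list(
    deviation = pr$deviation, s_proj = pr$s_proj,
    heading_error = wrap_angle(state$heading - here$heading),
    curvature = here$curvature, far_curvature = ahead$curvature,
    off_road = pr$off_road
  )
}

finish_trial_log <- function(t, x, y, s_proj, deviation, sw_angle, heading,
                             course, dt, levels = NULL, off_road = FALSE) {
  n <- length(t)
  sw_velocity <- numeric(n)
  if (n >= 3) {
    sw_velocity[2:(n - 1)] <- (sw_angle[3:n] - sw_angle[1:(n - 2)]) / (2 * dt)
  }
  if (n >= 2) {
    sw_velocity[1] <- (sw_angle[2] - sw_angle[1]) / dt
    sw_velocity[n] <- (sw_angle[n] - sw_angle[n - 1]) / dt
  }
  seg_kind <- course$segments$kind[segment_index(course, s_proj)]
  log <- tibble::tibble(
    t = t, x = x, y = y, s_proj = s_proj, deviation = deviation,
    sw_angle = sw_angle, sw_velocity = sw_velocity,
    level_L = if (is.null(levels)) NA_real_ else levels$left,
    level_R = if (is.null(levels)) NA_real_ else levels$right,
    segment_kind = seg_kind
  )
  attr(log, "heading") <- heading
  attr(log, "dt") <- dt
  attr(log, "off_road") <- off_road
  attr(log, "truncated") <- FALSE
  class(log) <- c("trial_log", class(log))
  log
}

#' Run one closed-loop driving trial
#'
#' Simulates the vehicle travelling the course at constant speed under a
#' steering policy, one record per simulation step. The policy is either a
#' [driver_agent()] (the synthetic participant model, simulated in compiled
#' code) or an R function `f(t, state, percept)` returning a steering-wheel
#' command in rad, where `percept` is the ground-truth projection (fields
#' `deviation`, `s_proj`, `heading_error`, `curvature`, `far_curvature`).
#'
#' The vehicle starts on the centerline at `s = 0`, heading tangent,
#' steering angle 0. If the vehicle strays beyond three lane widths from the
#' centre the trial is flagged off-road but continues, as human trials did.
#'
#' @param course A `road_course`.
#' @param controller A `driver_agent` or an R function (see Details).
#' @param duration Trial duration in seconds (default 60).
#' @param dt Simulation time step in seconds (default 1/60).
#' @param params A [vehicle_params()] list.
#' @param seed Integer seed for the controller's noise streams (optional for
#'   function controllers).
#' @param speed_kmh Constant vehicle speed in km/h (default 80).
#' @param encoder An [encoder_params()] list (used for the auditory channel
#'   and the logged ear levels of sensory-substitution agents).
#' @return A `trial_log` tibble with `ceiling(duration / dt)` rows and
#'   columns `t`, `x`, `y`, `s_proj`, `deviation`, `sw_angle`,
#'   `sw_velocity`, `level_L`, `level_R`, `segment_kind`; attributes
#'   `off_road`, `truncated`, `dt` and `heading`.
#' @examples
#' course <- generate_course(seed = 1)
#' agent <- driver_agent(condition = "ND")
#' log <- simulate_trial(course, agent, duration = 5, seed = 42)
#' head(log)
#' @export
simulate_trial <- function(course, controller, duration = 60, dt = 1 / 60,
                           params = vehicle_params(), seed = NULL,
                           speed_kmh = 80, encoder = encoder_params()) {
  stopifnot(inherits(course, "road_course"))
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  n <- ceiling(duration / dt)
  v <- speed_kmh / 3.6
  if (inherits(controller, "driver_agent")) {
    return(simulate_trial_agent(course, controller, n, dt, params, seed, v,
                                encoder))
  }
  if (!is.function(controller)) {
    stop("`controller` must be a driver_agent or a function(t, state, percept)",
         call. = FALSE)
  }
  with_seed(seed, {
    state <- vehicle_state(speed = v)
    t <- (seq_len(n) - 1) * dt
    x <- numeric(n); y <- numeric(n); s_proj <- numeric(n)
    deviation <- numeric(n); sw_angle <- numeric(n); heading <- numeric(n)
    any_off <- FALSE
    s_hint <- 0
    for (i in seq_len(n)) {
      pc <- true_percept(course, state, s_hint)
      s_hint <- pc$s_proj
      any_off <- any_off || pc$off_road
      cmd <- controller(t[i], state, pc)
      dmax <- params$sw_rate_max * dt
      sw <- state$sw_angle + clamp(cmd - state$sw_angle, -dmax, dmax)
      sw <- clamp(sw, -params$sw_max, params$sw_max)
      x[i] <- state$x; y[i] <- state$y
      s_proj[i] <- pc$s_proj; deviation[i] <- pc$deviation
      sw_angle[i] <- sw; heading[i] <- state$heading
      delta <- sw / params$steering_ratio
      h1 <- state$heading + v * tan(delta) / params$wheelbase * dt
      state <- vehicle_state(x = state$x + v * cos(h1) * dt,
                             y = state$y + v * sin(h1) * dt,
                             heading = h1, speed = v, sw_angle = sw)
    }
    finish_trial_log(t, x, y, s_proj, deviation, sw_angle, heading, course,
                     dt, off_road = any_off)
  })
}

# Fast path: the two-level driver agent simulated in C++.
simulate_trial_agent <- function(course, agent, n, dt, params, seed, v,
                                 encoder) {
  p <- agent$params
  sigma_audio <- audio_noise_sd(p, agent$trial_index)
  w_audio <- audio_weight(p, agent$trial_index)
  cond_code <- match(agent$condition, c("ND", "VO", "SS")) - 1L
  seg <- course$segments
  run <- function() {
    sim_trial_cpp(
      seg$kind == "arc", seg$length, seg$curvature, seg$start_s,
      seg$x0, seg$y0, seg$h0, course$total_length, course$lane_width,
      params$wheelbase, params$steering_ratio, params$sw_max,
      params$sw_rate_max,
      p$k_ant, p$k_comp, p$k_head, p$preview_time, p$reaction_delay,
      p$sigma_visual, sigma_audio, w_audio, p$sigma_curv, p$sigma_heading,
      p$sigma_motor, p$noise_tau, p$tau_ant, p$tau_motor,
      encoder$base_level, encoder$gain, encoder$clamp_floor,
      encoder$clamp_ceiling,
      cond_code, as.integer(n), dt, v
    )
  }
  m <- with_seed(seed, run())
  levels <- NULL
  if (agent$condition == "SS") {
    levels <- encode_deviation(m[, "deviation"], encoder)
  }
  finish_trial_log(m[, "t"], m[, "x"], m[, "y"], m[, "s_proj"],
                   m[, "deviation"], m[, "sw_angle"], m[, "heading"],
                   course, dt, levels = levels,
                   off_road = attr(m, "off_road"))
}

#' Write a trial log to CSV
#'
#' @param log A `trial_log` tibble from [simulate_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}
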