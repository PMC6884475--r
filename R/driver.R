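#' Parameters of the two-level synthetic driver
#'
#' The synthetic participant steers with two superposed processes, following
#' the classical two-level account of human steering: an *anticipatory*
#' (feedforward) term driven by previewed road curvature about
#' `preview_time` seconds ahead, which governs steering stability, and a
#' *compensatory* (feedback) term driven by an estimate of lateral deviation
#' from the proximal road or, for sensory-substitution agents, from the
#' decoded binaural levels, which governs lane-keeping accuracy. A
#' heading-error term keeps the vehicle aligned with the road even when no
#' deviation estimate is available (visual occlusion).
#'
#' Sensory noise on each channel is an Ornstein-Uhlenbeck process with time
#' constant `noise_tau` and stationary SD given by the corresponding
#' `sigma_*`: perceptual estimation error drifts over roughly a second
#' rather than re-randomizing at the 60 Hz simulation rate. Audio-decoding
#' noise shrinks with practice,
#' `sigma_audio(t) = sigma_audio_min + (sigma_audio0 - sigma_audio_min) *
#' exp(-learn_rate * t)` over training trials `t = 0, 1, ...`.
#'
#' @param k_ant Anticipatory gain: steering-wheel rad per rad of required
#'   road-wheel angle (1 = perfectly calibrated feedforward).
#' @param k_comp Compensatory gain, steering-wheel rad per metre of
#'   estimated deviation.
#' @param k_head Heading-error gain, steering-wheel rad per rad.
#' @param preview_time Curvature preview horizon in seconds (default 1).
#' @param reaction_delay Sensorimotor delay in seconds, implemented as a
#'   fixed-length command delay line (default 0.2).
#' @param sigma_visual Stationary SD (m) of the visual deviation estimate.
#' @param sigma_audio0,sigma_audio_min Initial and asymptotic SD (m) of the
#'   audio deviation estimate.
#' @param learn_rate Per-trial exponential learning rate for the audio
#'   channel.
#' @param sigma_curv Stationary SD (1/m) of the previewed-curvature
#'   estimate.
#' @param sigma_heading Stationary SD (rad) of the heading-error estimate.
#' @param sigma_motor Stationary SD (rad) of steering execution noise.
#' @param noise_tau Time constant (s) of the sensory noise processes.
#' @param tau_ant Time constant (s) of the first-order lag smoothing the
#'   anticipatory feedforward. With the default 0.8 s the smoothing lag
#'   cancels most of the 1 s preview lead, so curve-entry steering is both
#'   correctly timed (net lead about equal to the reaction delay) and
#'   human-like smooth rather than stepwise.
#' @param tau_motor Time constant (s) of the motor-noise process (fast
#'   tremor-like drift rather than 60 Hz white noise).
#' @return A `driver_params` list.
#' @export
driver_params <- function(k_ant = 1, k_comp = 0.15, k_head = 3,
                          preview_time = 1, reaction_delay = 0.2,
                          sigma_visual = 0.10, sigma_audio0 = 0.85,
                          sigma_audio_min = 0.12, learn_rate = 0.09,
                          sigma_curv = 0.0008, sigma_heading = 0.003,
                          sigma_motor = 0.02, noise_tau = 1,
                          tau_ant = 0.8, tau_motor = 0.1) {
  p <- list(k_ant = k_ant, k_comp = k_comp, k_head = k_head,
            preview_time = preview_time, reaction_delay = reaction_delay,
            sigma_visual = sigma_visual, sigma_audio0 = sigma_audio0,
            sigma_audio_min = sigma_audio_min, learn_rate = learn_rate,
            sigma_curv = sigma_curv, sigma_heading = sigma_heading,
            sigma_motor = sigma_motor, noise_tau = noise_tau,
            tau_ant = tau_ant, tau_motor = tau_motor)
  bad <- names(p)[vapply(p, function(v) !is.numeric(v) || length(v) != 1 ||
                           !is.finite(v) || v < 0, logical(1))]
  if (length(bad)) {
    stop("driver parameters must be single non-negative numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$sigma_audio_min > p$sigma_audio0) {
    stop("`sigma_audio_min` must not exceed `sigma_audio0`", call. = FALSE)
  }
  for (nm in c("noise_tau", "tau_ant", "tau_motor")) {
    if (p[[nm]] <= 0) stop(sprintf("`%s` must be positive", nm), call. = FALSE)
  }
  structure(p, class = "driver_params")
}

# Audio-decoding noise SD after `trial_index` training trials.
audio_noise_sd <- function(params, trial_index) {
  params$sigma_audio_min +
    (params$sigma_audio0 - params$sigma_audio_min) *
    exp(-params$learn_rate * trial_index)
}

# Reliability-proportional weight on the audio deviation estimate: early in
# training the channel is noisy and the agent leans on it only weakly
# (behaving almost like a visually occluded driver), converging to full
# reliance as decoding precision approaches its asymptote.
audio_weight <- function(params, trial_index) {
  sd_now <- audio_noise_sd(params, trial_index)
  if (sd_now <= 0) return(1)
  min(params$sigma_audio_min / sd_now, 1)
}

#' Construct a driver agent for one trial
#'
#' Binds driver parameters to a sensory condition and training-trial index.
#' Conditions gate the sensory channels: `ND` (normal driving) has the
#' near-road visual deviation estimate, `VO` (visual occlusion) has neither
#' deviation estimate (steering falls back on heading and curvature
#' preview), and `SS` (sensory substitution) decodes deviation from the
#' binaural levels with a precision that improves across training trials.
#'
#' @param params A [driver_params()] list.
#' @param condition `"ND"`, `"VO"` or `"SS"`.
#' @param trial_index Zero-based training-trial index driving the audio
#'   learning curve (ignored outside `SS`).
#' @return A `driver_agent` list.
#' @export
driver_agent <- function(params = driver_params(),
                         condition = c("ND", "VO", "SS"),
                         trial_index = 0) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "driver_params"))
  stopifnot(trial_index >= 0)
  structure(list(params = params, condition = condition,
                 trial_index = trial_index),
            class = "driver_agent")
}

#' Sample a percept for the current vehicle state
#'
#' Draws one noisy percept: previewed far-road curvature, heading error,
#' and — depending on condition — a visual (`ND`) or decoded-audio (`SS`)
#' deviation estimate. Channels unavailable under the condition are `NA`.
#' Noise here is drawn from the stationary distribution of the agent's
#' noise processes; within a closed-loop trial the same magnitudes evolve
#' as correlated processes (see [driver_params()]).
#'
#' @param state A `vehicle_state`.
#' @param course A `road_course`.
#' @param condition `"ND"`, `"VO"` or `"SS"`.
#' @param trial_index Zero-based training-trial index.
#' @param params A [driver_params()] list.
#' @param encoder An [encoder_params()] list.
#' @param s_hint Arc-position hint for the centerline projection.
#' @return A list with fields `far_curvature`, `near_deviation`,
#'   `audio_deviation`, `heading_error`, `s_proj`.
#' @export
perceive <- function(state, course, condition = c("ND", "VO", "SS"),
                     trial_index = 0, params = driver_params(),
                     encoder = encoder_params(), s_hint = 0) {
  condition <- match.arg(condition)
  pc <- true_percept(course, state, s_hint, params$preview_time)
  near <- NA_real_
  audio <- NA_real_
  if (condition == "ND") {
    near <- pc$deviation + rnorm(1, 0, params$sigma_visual)
  }
  if (condition == "SS") {
    dec <- decode_levels(encode_deviation(pc$deviation, encoder), encoder)
    audio <- dec$deviation + rnorm(1, 0, audio_noise_sd(params, trial_index))
  }
  list(
    far_curvature = pc$far_curvature + rnorm(1, 0, params$sigma_curv),
    near_deviation = near,
    audio_deviation = audio,
    heading_error = pc$heading_error + rnorm(1, 0, params$sigma_heading),
    s_proj = pc$s_proj
  )
}

#' Two-level steering law
#'
#' Combines the anticipatory feedforward (steering-wheel equivalent of the
#' previewed curvature), the compensatory deviation feedback (negative
#' feedback: a leftward deviation commands a rightward correction), and the
#' heading-error feedback, plus white motor noise. The best available
#' deviation estimate is used: visual if present, else audio, else zero.
#'
#' @param percept A percept as returned by [perceive()].
#' @param params A [driver_params()] list.
#' @param vehicle A [vehicle_params()] list (supplies wheelbase and
#'   steering ratio for the feedforward calibration).
#' @return Steering-wheel command in rad (before the vehicle's clamping and
#'   slew limiting).
#' @export
steer <- function(percept, params = driver_params(),
                  vehicle = vehicle_params()) {
  dev_est <- if (is.finite(percept$near_deviation %||% NA_real_)) {
    percept$near_deviation
  } else if (is.finite(percept$audio_deviation %||% NA_real_)) {
    percept$audio_deviation
  } else {
    0
  }
  ff <- params$k_ant * vehicle$steering_ratio *
    atan(vehicle$wheelbase * percept$far_curvature)
  ff - params$k_comp * dev_est - params$k_head * percept$heading_error +
    rnorm(1, 0, params$sigma_motor)
}

#' Default driver-agent population
#'
#' Per-parameter population mean, between-participant jitter SD and
#' truncation bounds used to sample individual synthetic participants.
#' Means are the [driver_params()] defaults; jitter SDs are roughly 10-15%
#' of the mean for gains and noise magnitudes, reflecting stable individual
#' differences in steering style and perceptual precision.
#'
#' @return A tibble with columns `param`, `mean`, `jitter_sd`, `lower`,
#'   `upper`.
#' @export
default_population <- function() {
  d <- unclass(driver_params())
  means <- unlist(d)
  rel <- c(k_ant = 0.03, k_comp = 0.12, k_head = 0.10, preview_time = 0.10,
           reaction_delay = 0.10, sigma_visual = 0.15, sigma_audio0 = 0.15,
           sigma_audio_min = 0.15, learn_rate = 0.15, sigma_curv = 0.15,
           sigma_heading = 0.15, sigma_motor = 0.15, noise_tau = 0,
           tau_ant = 0.10, tau_motor = 0)
  tibble::tibble(
    param = names(means),
    mean = unname(means),
    jitter_sd = unname(means * rel[names(means)]),
    lower = pmax(unname(means) * 0.4, 1e-6),
    upper = unname(means) * 2.5
  )
}

#' Sample one synthetic participant's driver parameters
#'
#' Draws each parameter from a normal distribution centred on the
#' population mean with the population jitter SD, truncated (clipped) at
#' the validity bounds. Deterministic given `(group_seed,
#' participant_index)`.
#'
#' @param group_seed Integer seed shared by a participant group.
#' @param participant_index 1-based participant index within the group.
#' @param population A population spec as from [default_population()].
#' @return A [driver_params()] list.
#' @export
sample_participant <- function(group_seed, participant_index,
                               population = default_population()) {
  stopifnot(all(c("param", "mean", "jitter_sd", "lower", "upper") %in%
                  names(population)))
  seed <- derive_seed(group_seed, "participant", participant_index)
  draws <- with_seed(seed, {
    rnorm(nrow(population), population$mean, population$jitter_sd)
  })
  draws <- clamp(draws, population$lower, population$upper)
  vals <- as.list(setNames(draws, population$param))
  if (vals$sigma_audio_min > vals$sigma_audio0) {
    vals$sigma_audio_min <- vals$sigma_audio0
  }
  do.call(driver_params, vals)
}

#' Sample a group of synthetic participants
#'
#' @param group_seed Integer seed shared by the group.
#' @param n Number of participants.
#' @param population A population spec as from [default_population()].
#' @return A tibble with one row per participant: `participant_index` plus
#'   one column per driver parameter.
#' @export
sample_participants <- function(group_seed, n,
                                population = default_population()) {
  purrr::map_dfr(seq_len(n), function(i) {
    p <- sample_participant(group_seed, i, population)
    tibble::tibble(participant_index = i, !!!unclass(p))
  })
}

# R reference controller for a driver agent: replicates the compiled fast
# path (same noise-draw order, OU updates, delay line) so the two can be
# compared exactly at zero noise.
make_driver_controller <- function(agent, vehicle = vehicle_params(),
                                   encoder = encoder_params(), dt = 1 / 60) {
  p <- agent$params
  cond <- agent$condition
  sig_aud <- audio_noise_sd(p, agent$trial_index)
  w_aud <- audio_weight(p, agent$trial_index)
  rho <- exp(-dt / p$noise_tau)
  q <- sqrt(1 - rho^2)
  rho_m <- exp(-dt / p$tau_motor)
  q_m <- sqrt(1 - rho_m^2)
  lag_ant <- 1 - exp(-dt / p$tau_ant)
  # rnorm(1) * sd rather than rnorm(1, 0, sd): keeps the RNG stream in
  # lockstep with the compiled path even when an sd is exactly zero
  ou <- c(vis = rnorm(1) * p$sigma_visual, aud = rnorm(1) * sig_aud,
          curv = rnorm(1) * p$sigma_curv, head = rnorm(1) * p$sigma_heading,
          motor = rnorm(1) * p$sigma_motor)
  ff_state <- 0
  delay_n <- round(p$reaction_delay / dt)
  buffer <- numeric(max(delay_n, 1))
  head_i <- 1L
  function(t, state, percept) {
    ou["vis"] <<- rho * ou["vis"] + q * rnorm(1) * p$sigma_visual
    ou["aud"] <<- rho * ou["aud"] + q * rnorm(1) * sig_aud
    ou["curv"] <<- rho * ou["curv"] + q * rnorm(1) * p$sigma_curv
    ou["head"] <<- rho * ou["head"] + q * rnorm(1) * p$sigma_heading
    ou["motor"] <<- rho_m * ou["motor"] + q_m * rnorm(1) * p$sigma_motor
    dev_est <- 0
    if (cond == "ND") {
      dev_est <- percept$deviation + ou[["vis"]]
    } else if (cond == "SS") {
      dec <- decode_levels(encode_deviation(percept$deviation, encoder),
                           encoder)
      dev_est <- w_aud * (dec$deviation + ou[["aud"]])
    }
    far <- percept$far_curvature + ou[["curv"]]
    herr <- percept$heading_error + ou[["head"]]
    ff_target <- p$k_ant * vehicle$steering_ratio *
      atan(vehicle$wheelbase * far)
    ff_state <<- ff_state + lag_ant * (ff_target - ff_state)
    raw <- ff_state - p$k_comp * dev_est - p$k_head * herr + ou[["motor"]]
    if (delay_n == 0) return(raw)
    out <- buffer[head_i]
    buffer[head_i] <<- raw
    head_i <<- if (head_i == delay_n) 1L else head_i + 1L
    out
  }
}
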