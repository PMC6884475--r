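# Shared fixtures and small oracles, built in code at test time.

clamp_to_unit <- function(x) pmin(pmax(x, -1), 1)

# A long course with many segments for distributional checks.
big_course <- function(seed = 11, total_length = 110000) {
  generate_course(seed = seed, total_length = total_length)
}

# Zero-noise driver parameters (deterministic closed loop).
quiet_params <- function(...) {
  driver_params(sigma_visual = 0, sigma_audio0 = 0, sigma_audio_min = 0,
                sigma_curv = 0, sigma_heading = 0, sigma_motor = 0, ...)
}

# 6-participant fixture for the mixed ANOVA, with F values frozen from an
# independent reference fit (stats::aov with an Error(participant/phase)
# stratum) on these exact numbers.
anova_fixture <- function() {
  tibble::tibble(
    participant = rep(sprintf("p%d", 1:6), each = 2),
    group = rep(c("A", "A", "B", "B", "C", "C"), each = 2),
    phase = rep(c("first", "last"), 6),
    value = c(1.0, 1.2, 0.8, 1.1, 2.0, 1.5, 1.7, 1.3, 0.9, 0.95, 1.1, 1.4)
  )
}
anova_fixture_expected <- list(
  f_group = 6.849180327869, f_phase = 0.030303030303,
  f_interaction = 21.484848484848
)

# Hand-built two-curve trial log: steering ramps at 2 deg/s inside the
# first arc window and 4 deg/s inside the second, constant elsewhere.
# Expected SWV = mean(2, 4) = 3 deg/s.
two_curve_log <- function(dt = 0.1) {
  n <- 50
  kind <- rep("straight", n)
  kind[11:20] <- "arc"
  kind[31:40] <- "arc"
  rate <- numeric(n)
  rate[11:20] <- 2 * pi / 180   # rad/s
  rate[31:40] <- 4 * pi / 180
  sw <- cumsum(c(0, rate[-n] * dt))
  log <- tibble::tibble(
    t = (seq_len(n) - 1) * dt,
    s_proj = seq_len(n),
    deviation = 0,
    sw_angle = sw,
    segment_kind = kind
  )
  attr(log, "dt") <- dt
  log
}

# Synthetic metrics table with a built-in group x phase interaction on
# sdlp, for exercising the full analysis pipeline without driving trials.
synthetic_metrics <- function(seed = 99, n_per_group = 15) {
  set.seed(seed)
  rows <- list()
  for (g in c("ND", "VO", "SS")) {
    for (i in seq_len(n_per_group)) {
      pid <- sprintf("%s%02d", g, i)
      base <- 0.3 + rnorm(1, 0, 0.03)
      sdlp_by <- function(session, trial) {
        bump <- if (session == "training" && g != "ND") {
          if (g == "VO") 0.5 else 0.5 * exp(-0.1 * (trial - 1))
        } else {
          0
        }
        base + bump + rnorm(1, 0, 0.04)
      }
      for (session in c("pretest", "training", "posttest")) {
        n_tr <- if (session == "training") 5 else 2
        for (trial in seq_len(n_tr)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            participant = pid, group = g, session = session, trial = trial,
            sdlp = sdlp_by(session, trial),
            swv = 90 + rnorm(1, 0, 8),
            n_curves = 6L, off_road = FALSE
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
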