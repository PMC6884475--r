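#' Experiment configuration
#'
#' Bundles every tunable of the full study protocol: three groups (ND, VO,
#' SS) of `n_per_group` synthetic participants, each performing
#' `n_pretest` normal-vision pretest trials, `n_training` trials under the
#' group's condition, and `n_posttest` normal-vision posttest trials, all
#' one-minute closed-loop drives at 80 km/h with a 1/60 s step on a fresh
#' seeded course per trial.
#'
#' @param master_seed Integer master seed; every participant, trial and
#'   course derives its own stream from it via [derive_seed()].
#' @param dt Simulation time step in seconds.
#' @param trial_duration Trial length in seconds.
#' @param speed_kmh Constant vehicle speed in km/h.
#' @param n_pretest,n_training,n_posttest Trials per session.
#' @param n_per_group Participants per group.
#' @param course Course-generation arguments passed to [generate_course()]
#'   (excluding `seed`).
#' @param vehicle A [vehicle_params()] list.
#' @param encoder An [encoder_params()] list.
#' @param population A population spec as from [default_population()].
#' @param keep_logs Keep every per-trial log in the result (memory-heavy;
#'   default `FALSE`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(master_seed = 1, dt = 1 / 60, trial_duration = 60,
                       speed_kmh = 80, n_pretest = 5, n_training = 40,
                       n_posttest = 5, n_per_group = 15,
                       course = list(), vehicle = vehicle_params(),
                       encoder = encoder_params(),
                       population = default_population(),
                       keep_logs = FALSE) {
  for (nm in c("dt", "trial_duration", "speed_kmh")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  counts <- c(n_pretest = n_pretest, n_training = n_training,
              n_posttest = n_posttest, n_per_group = n_per_group)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("trial and group counts must be positive integers", call. = FALSE)
  }
  structure(list(master_seed = master_seed, dt = dt,
                 trial_duration = trial_duration, speed_kmh = speed_kmh,
                 n_pretest = n_pretest, n_training = n_training,
                 n_posttest = n_posttest, n_per_group = n_per_group,
                 course = course, vehicle = vehicle, encoder = encoder,
                 population = population, keep_logs = keep_logs),
            class = "sim_config")
}

#' Run the full simulated experiment
#'
#' Executes the complete protocol for all three groups and analyses the
#' resulting metrics table with [analyze_experiment()]. Pretest and
#' posttest trials always run under full vision (condition ND) regardless
#' of group; training trials run under the group's condition, with
#' sensory-substitution agents' audio precision improving across the
#' training trials. Each trial drives a freshly generated course seeded
#' from the master seed, so no course is ever repeated or memorized.
#' Fully reproducible: the same `master_seed` yields an identical metrics
#' table.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `metrics.csv` and
#'   `results.json` there.
#' @param progress Print per-group progress lines.
#' @return An `lk_experiment` list with `metrics` (tibble: `participant`,
#'   `group`, `session`, `trial`, `sdlp`, `swv`, `n_curves`, `off_road`),
#'   `analysis` (an `lk_analysis`), `config`, and `logs` when
#'   `config$keep_logs` is `TRUE`.
#' @examples
#' \donttest{
#' cfg <- sim_config(master_seed = 1, n_per_group = 2, n_pretest = 1,
#'                   n_training = 2, n_posttest = 1)
#' exp <- run_experiment(cfg)
#' head(exp$metrics)
#' }
#' @export
run_experiment <- function(config = sim_config(), out_dir = NULL,
                           progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  groups <- c("ND", "VO", "SS")
  sessions <- list(pretest = config$n_pretest,
                   training = config$n_training,
                   posttest = config$n_posttest)
  logs <- if (config$keep_logs) list() else NULL
  rows <- list()
  for (g in groups) {
    if (progress) message("group ", g)
    pop_seed <- derive_seed(config$master_seed, "population", g)
    for (i in seq_len(config$n_per_group)) {
      params <- sample_participant(pop_seed, i, config$population)
      pid <- sprintf("%s%02d", g, i)
      for (session in names(sessions)) {
        for (trial in seq_len(sessions[[session]])) {
          condition <- if (session == "training") g else "ND"
          trial_index <- if (session == "training") trial - 1 else 0
          trial_seed <- derive_seed(config$master_seed, g, i, session, trial)
          course <- do.call(generate_course, c(
            list(seed = derive_seed(trial_seed, "course")),
            config$course
          ))
          agent <- driver_agent(params, condition, trial_index)
          log <- simulate_trial(course, agent,
                                duration = config$trial_duration,
                                dt = config$dt, params = config$vehicle,
                                seed = derive_seed(trial_seed, "drive"),
                                speed_kmh = config$speed_kmh,
                                encoder = config$encoder)
          m <- trial_metrics(log, course)
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble::tibble(participant = pid, group = g,
                           session = session, trial = trial), m
          )
          if (config$keep_logs) logs[[paste(pid, session, trial)]] <- log
        }
      }
    }
  }
  metrics <- dplyr::bind_rows(rows)
  analysis <- analyze_experiment(metrics)
  out <- structure(list(metrics = metrics, analysis = analysis,
                        config = config, logs = logs),
                   class = "lk_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(metrics),
                     file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write_results_json(analysis, file.path(out_dir, "results.json"))
  }
  out
}

#' @export
print.lk_experiment <- function(x, ...) {
  cat(sprintf("<lk_experiment> %d metric rows (%d participants)\n",
              nrow(x$metrics), length(unique(x$metrics$participant))))
  s <- condition_summary(x$metrics)
  print(as.data.frame(s), digits = 3)
  invisible(x)
}

#' Per-condition summary of key protocol trials
#'
#' Group means (and SDs) of SDLP and SWV at the four trials entering the
#' inferential analyses: first and last training trial, last pretest trial
#' and first posttest trial.
#'
#' @param metrics A metrics table from [run_experiment()].
#' @return A tibble with one row per group x slice.
#' @export
condition_summary <- function(metrics) {
  n_training <- max(metrics$trial[metrics$session == "training"])
  n_pretest <- max(metrics$trial[metrics$session == "pretest"])
  slices <- tibble::tribble(
    ~slice, ~session, ~trial,
    "pretest_last", "pretest", n_pretest,
    "training_first", "training", 1,
    "training_last", "training", n_training,
    "posttest_first", "posttest", 1
  )
  purrr::map_dfr(seq_len(nrow(slices)), function(j) {
    m <- metrics[metrics$session == slices$session[j] &
                   metrics$trial == slices$trial[j], ]
    m |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        slice = slices$slice[j],
        mean_sdlp = mean(.data$sdlp), sd_sdlp = sd(.data$sdlp),
        mean_swv = mean(.data$swv, na.rm = TRUE),
        sd_swv = sd(.data$swv, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::relocate("slice")
  })
}

#' @export
tidy.lk_experiment <- function(x, ...) tidy(x$analysis)

#' @export
glance.lk_experiment <- function(x, ...) {
  tibble::tibble(
    n_participants = length(unique(x$metrics$participant)),
    n_trials = nrow(x$metrics),
    n_off_road = sum(x$metrics$off_road),
    master_seed = x$config$master_seed
  )
}
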