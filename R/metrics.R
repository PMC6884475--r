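#' Standard deviation of lateral position (SDLP)
#'
#' The lane-keeping *accuracy* metric: the standard deviation of the signed
#' lateral-deviation series over the whole trial (sample SD; at 3600
#' records per trial the 1/N vs 1/(N-1) distinction is negligible). Lower
#' is better.
#'
#' @param log A `trial_log` from [simulate_trial()], or any data frame with
#'   a `deviation` column.
#' @return SDLP in metres.
#' @export
trial_sdlp <- function(log) {
  stopifnot(is.data.frame(log), "deviation" %in% names(log))
  if (nrow(log) == 0) stop("empty trial log", call. = FALSE)
  sd(log$deviation)
}

#' Curve-negotiation windows of a trial
#'
#' Maximal time intervals during which the vehicle's centerline projection
#' lies within an arc (bend) segment. Windows are ordered and
#' non-overlapping; a trial ending mid-bend yields a final window truncated
#' at the trial end.
#'
#' @param log A `trial_log`.
#' @param course The `road_course` the trial was driven on (defaults to the
#'   course attached to the log).
#' @return A tibble with columns `t_start`, `t_end`, `i_start`, `i_end`
#'   (record indices, inclusive).
#' @export
curve_windows <- function(log, course = NULL) {
  stopifnot(is.data.frame(log), "s_proj" %in% names(log))
  if (!is.null(course)) {
    stopifnot(inherits(course, "road_course"))
    is_arc <- course$segments$kind[segment_index(course, log$s_proj)] == "arc"
  } else {
    stopifnot("segment_kind" %in% names(log))
    is_arc <- log$segment_kind == "arc"
  }
  r <- rle(is_arc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(
    t_start = log$t[starts[keep]],
    t_end = log$t[ends[keep]],
    i_start = as.integer(starts[keep]),
    i_end = as.integer(ends[keep])
  )
}

#' Steering-wheel velocity during curve negotiation (SWV)
#'
#' The steering *stability* metric: within each curve-negotiation window,
#' the maximum absolute steering-wheel velocity (central finite difference
#' of the steering-wheel angle at the simulation rate, converted to
#' degrees/second), averaged across all curves in the trial. Lower is
#' better. Returns `NA` when the trial contains no curve window.
#'
#' @inheritParams curve_windows
#' @return Mean per-curve maximum steering-wheel velocity in deg/s, or
#'   `NA_real_` if no curve was negotiated.
#' @export
trial_swv <- function(log, course = NULL) {
  stopifnot(is.data.frame(log), "sw_angle" %in% names(log))
  w <- curve_windows(log, course)
  if (nrow(w) == 0) return(NA_real_)
  dt <- attr(log, "dt") %||% (if (nrow(log) > 1) log$t[2] - log$t[1] else 1)
  n <- nrow(log)
  vel <- numeric(n)
  if (n >= 3) vel[2:(n - 1)] <- (log$sw_angle[3:n] - log$sw_angle[1:(n - 2)]) / (2 * dt)
  if (n >= 2) {
    vel[1] <- (log$sw_angle[2] - log$sw_angle[1]) / dt
    vel[n] <- (log$sw_angle[n] - log$sw_angle[n - 1]) / dt
  }
  vel_deg <- abs(vel) * 180 / pi
  maxima <- purrr::map2_dbl(w$i_start, w$i_end,
                            function(a, b) max(vel_deg[a:b]))
  mean(maxima)
}

#' Both driving-performance metrics for one trial
#'
#' @inheritParams curve_windows
#' @return A one-row tibble: `sdlp` (m), `swv` (deg/s, `NA` if no curve),
#'   `n_curves`, `off_road`.
#' @examples
#' course <- generate_course(seed = 1)
#' log <- simulate_trial(course, driver_agent(condition = "ND"),
#'                       duration = 10, seed = 3)
#' trial_metrics(log, course)
#' @export
trial_metrics <- function(log, course = NULL) {
  w <- curve_windows(log, course)
  tibble::tibble(
    sdlp = trial_sdlp(log),
    swv = trial_swv(log, course),
    n_curves = nrow(w),
    off_road = isTRUE(attr(log, "off_road"))
  )
}
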