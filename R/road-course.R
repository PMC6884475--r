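#' Procedurally generate a winding road course
#'
#' Builds a course of alternating straight sections and circular bends, the
#' road geometry used throughout the lane-keeping simulation. Bend curvature
#' magnitudes are drawn uniformly from `curv_range` (default 1/180 to
#' 1/80 m^-1) with strictly alternating sign (left/right), straight lengths
#' uniformly from `straight_range` (default 50 to 150 m). Segments are
#' appended until `total_length` is reached; the last segment may overshoot.
#'
#' @param seed Integer seed; identical seeds give identical courses.
#' @param total_length Minimum course length in metres (default 1500).
#' @param curv_range Length-2 numeric, curvature magnitude range in 1/m.
#' @param straight_range Length-2 numeric, straight-section length range in m.
#' @param bend_length_range Length-2 numeric, bend arc-length range in m.
#' @param lane_width Lane width in metres (default 3.5).
#' @return A `road_course` object: a list with `lane_width`, `total_length`
#'   and `segments`, a tibble with one row per segment (`kind`, `length`,
#'   `curvature`, `start_s`) plus the precomputed start pose of each segment
#'   (`x0`, `y0`, `h0`).
#' @examples
#' course <- generate_course(seed = 1)
#' course$segments
#' @export
generate_course <- function(seed,
                            total_length = 1500,
                            curv_range = c(1 / 180, 1 / 80),
                            straight_range = c(50, 150),
                            bend_length_range = c(50, 150),
                            lane_width = 3.5) {
  stopifnot_scalar_number(total_length, "total_length", positive = TRUE)
  check_range <- function(r, name, positive = TRUE) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("`%s` must be a non-inverted numeric range", name), call. = FALSE)
    }
    if (positive && r[1] <= 0) {
      stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
    }
  }
  check_range(curv_range, "curv_range")
  check_range(straight_range, "straight_range")
  check_range(bend_length_range, "bend_length_range")
  stopifnot_scalar_number(lane_width, "lane_width", positive = TRUE)

  with_seed(seed, {
    kind <- character()
    len <- numeric()
    curv <- numeric()
    sign_next <- sample(c(-1, 1), 1)
    s <- 0
    straight_next <- TRUE
    while (s < total_length) {
      if (straight_next) {
        l <- runif(1, straight_range[1], straight_range[2])
        kind <- c(kind, "straight")
        curv <- c(curv, 0)
      } else {
        l <- runif(1, bend_length_range[1], bend_length_range[2])
        kind <- c(kind, "arc")
        curv <- c(curv, sign_next * runif(1, curv_range[1], curv_range[2]))
        sign_next <- -sign_next
      }
      len <- c(len, l)
      s <- s + l
      straight_next <- !straight_next
    }
    new_road_course(kind, len, curv, lane_width)
  })
}

# Assemble a road_course from raw segment vectors, precomputing the start
# pose of each segment so pose queries are O(1) after segment lookup.
new_road_course <- function(kind, length, curvature, lane_width) {
  n <- base::length(kind)
  start_s <- cumsum(c(0, length))[seq_len(n)]
  x0 <- numeric(n); y0 <- numeric(n); h0 <- numeric(n)
  x <- 0; y <- 0; h <- 0
  for (i in seq_len(n)) {
    x0[i] <- x; y0[i] <- y; h0[i] <- h
    if (curvature[i] == 0) {
      x <- x + length[i] * cos(h)
      y <- y + length[i] * sin(h)
    } else {
      k <- curvature[i]
      h1 <- h + k * length[i]
      x <- x + (sin(h1) - sin(h)) / k
      y <- y - (cos(h1) - cos(h)) / k
      h <- h1
    }
  }
  structure(
    list(
      lane_width = lane_width,
      total_length = sum(length),
      segments = tibble::tibble(
        kind = kind, length = length, curvature = curvature,
        start_s = start_s, x0 = x0, y0 = y0, h0 = h0
      )
    ),
    class = "road_course"
  )
}

#' @export
print.road_course <- function(x, ...) {
  n_arc <- sum(x$segments$kind == "arc")
  cat(sprintf(
    "<road_course> %.1f m, %d segments (%d bends), lane width %.1f m\n",
    x$total_length, nrow(x$segments), n_arc, x$lane_width
  ))
  invisible(x)
}

segment_index <- function(course, s) {
  # findInterval's all.inside would cap at n - 1; clamp manually so queries
  # within the last segment (and at s = total_length) resolve to it
  idx <- findInterval(s, course$segments$start_s)
  pmin(pmax(idx, 1L), nrow(course$segments))
}

#' Pose of the lane centerline at arc-position s
#'
#' Closed-form evaluation of the piecewise straight/circular centerline.
#' Within an arc of curvature kappa the heading advances by `kappa * ds`;
#' position and heading are continuous across segment joints.
#'
#' @param course A `road_course`.
#' @param s Numeric vector of arc positions in metres, within
#'   `[0, total_length]`.
#' @return A tibble with columns `s`, `x`, `y`, `heading` (rad) and
#'   `curvature` (1/m).
#' @examples
#' course <- generate_course(seed = 1)
#' centerline_pose(course, c(0, 100, 500))
#' @export
centerline_pose <- function(course, s) {
  stopifnot(inherits(course, "road_course"))
  if (any(!is.finite(s)) || any(s < 0) || any(s > course$total_length + 1e-9)) {
    stop("`s` outside the course [0, total_length]", call. = FALSE)
  }
  seg <- course$segments[segment_index(course, s), ]
  ds <- s - seg$start_s
  k <- seg$curvature
  straight <- k == 0
  heading <- seg$h0 + k * ds
  x <- ifelse(straight,
              seg$x0 + ds * cos(seg$h0),
              seg$x0 + (sin(heading) - sin(seg$h0)) / ifelse(straight, 1, k))
  y <- ifelse(straight,
              seg$y0 + ds * sin(seg$h0),
              seg$y0 - (cos(heading) - cos(seg$h0)) / ifelse(straight, 1, k))
  tibble::tibble(s = s, x = x, y = y, heading = heading, curvature = k)
}

# Nearest point on one segment to (px, py): returns c(s_proj, deviation, dist).
# Deviation sign: positive = left of centerline in the direction of travel.
project_on_segment <- function(course, i, px, py) {
  seg <- course$segments[i, ]
  if (seg$curvature == 0) {
    u <- (px - seg$x0) * cos(seg$h0) + (py - seg$y0) * sin(seg$h0)
    u <- clamp(u, 0, seg$length)
    fx <- seg$x0 + u * cos(seg$h0)
    fy <- seg$y0 + u * sin(seg$h0)
    h <- seg$h0
  } else {
    k <- seg$curvature
    cx <- seg$x0 - sin(seg$h0) / k
    cy <- seg$y0 + cos(seg$h0) / k
    phi0 <- atan2(seg$y0 - cy, seg$x0 - cx)
    phi <- atan2(py - cy, px - cx)
    u <- wrap_angle(phi - phi0) / k
    u <- clamp(u, 0, seg$length)
    h <- seg$h0 + k * u
    fx <- cx + cos(phi0 + k * u) / abs(k)
    fy <- cy + sin(phi0 + k * u) / abs(k)
  }
  dev <- -sin(h) * (px - fx) + cos(h) * (py - fy)
  dist <- sqrt((px - fx)^2 + (py - fy)^2)
  c(s_proj = seg$start_s + u, deviation = dev, dist = dist)
}

#' Signed lateral deviation from the lane centerline
#'
#' Projects one or more planar points onto the course centerline and returns
#' the signed perpendicular offset (positive = left of centre in the
#' direction of travel) together with the arc-position of the foot point.
#' The search is seeded at `s_hint` and restricted to segments within
#' `window` metres of it; ties at segment joints resolve to the smaller
#' `s_proj`.
#'
#' @param course A `road_course`.
#' @param x,y Numeric vectors of point coordinates in metres.
#' @param s_hint Arc-position hint in metres (default 0) seeding the local
#'   search; recycled across points.
#' @param window Half-width in metres of the search window around `s_hint`
#'   (default 250).
#' @param sanity_k Points farther than `sanity_k * lane_width` from the
#'   centerline are off-road.
#' @param off_road `"error"` (default) to fail on off-road points, `"flag"`
#'   to return them with `off_road = TRUE`.
#' @return A tibble with columns `deviation`, `s_proj` and `off_road`.
#' @examples
#' course <- generate_course(seed = 1)
#' p <- centerline_pose(course, 120)
#' lateral_deviation(course, p$x, p$y, s_hint = 100)
#' @export
lateral_deviation <- function(course, x, y, s_hint = 0, window = 250,
                              sanity_k = 3, off_road = c("error", "flag")) {
  stopifnot(inherits(course, "road_course"))
  off_road <- match.arg(off_road)
  n <- length(x)
  stopifnot(length(y) == n)
  s_hint <- rep_len(s_hint, n)
  dev <- numeric(n); s_proj <- numeric(n); flag <- logical(n)
  starts <- course$segments$start_s
  ends <- starts + course$segments$length
  for (j in seq_len(n)) {
    cand <- which(ends >= s_hint[j] - window & starts <= s_hint[j] + window)
    if (length(cand) == 0) cand <- seq_len(nrow(course$segments))
    best <- NULL
    for (i in cand) {
      p <- project_on_segment(course, i, x[j], y[j])
      if (is.null(best) ||
          p["dist"] < best["dist"] - 1e-12 ||
          (abs(p["dist"] - best["dist"]) <= 1e-12 && p["s_proj"] < best["s_proj"])) {
        best <- p
      }
    }
    dev[j] <- best[["deviation"]]
    s_proj[j] <- best[["s_proj"]]
    flag[j] <- abs(dev[j]) > sanity_k * course$lane_width
  }
  if (off_road == "error" && any(flag)) {
    stop(sprintf("%d point(s) beyond %.1f m of the centerline (off-road)",
                 sum(flag), sanity_k * course$lane_width), call. = FALSE)
  }
  tibble::tibble(deviation = dev, s_proj = s_proj, off_road = flag)
}

#' Serialize a road course to JSON
#'
#' Writes the segment table (`kind`, `length`, `curvature`, `start_s`) and
#' lane width; start poses are recomputed on read so the JSON is minimal.
#'
#' @param course A `road_course`.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @seealso [read_course_json()]
#' @export
write_course_json <- function(course, path = NULL) {
  stopifnot(inherits(course, "road_course"))
  obj <- list(
    lane_width = course$lane_width,
    segments = course$segments[, c("kind", "length", "curvature", "start_s")]
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Read a road course from JSON
#'
#' @param path File path or a JSON string produced by [write_course_json()].
#' @return A `road_course`.
#' @export
read_course_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new_road_course(obj$segments$kind, obj$segments$length,
                  obj$segments$curvature, obj$lane_width)
}
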