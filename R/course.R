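# Procedural generation of the scrolling course: 48-px-high straight
# segments at one of five angles, goal points on every corner, and the
# optimal polyline joining the goals.

#' Allowed segment angles (degrees from the horizontal axis)
#'
#' 90 is vertical; angles below 90 displace the line rightward as it
#' descends, angles above 90 leftward, so {30,150} and {45,135} are mirror
#' pairs.
#' @export
COURSE_ANGLES <- c(30, 45, 90, 135, 150)

#' Segment height in pixels
#' @export
SEGMENT_HEIGHT <- 48

#' Horizontal displacement of one segment
#'
#' @param angle_deg segment angle in degrees, measured from the horizontal
#'   axis.
#' @param height vertical extent of the segment (px).
#' @return signed horizontal displacement `height / tan(angle_deg)`;
#'   exactly 0 for 90 degrees.
#' @export
segment_dx <- function(angle_deg, height = SEGMENT_HEIGHT) {
  ifelse(angle_deg == 90, 0, height / tan(angle_deg * pi / 180))
}

#' Generate a random course
#'
#' Draws `n_segments` segment angles uniformly from `angles`; any candidate
#' whose segment would leave `x_bounds` is resampled.  Geometry is kept
#' real-valued; rounding to integer pixels happens only in rendering or
#' trace output.
#'
#' @param n_segments number of 48-px segments (>= 0).
#' @param seed optional integer seed; when given the course is a pure
#'   function of the arguments.  When `NULL` the current RNG stream is
#'   used.
#' @param x_bounds admissible horizontal range (px) for the whole line.
#' @param start_x horizontal position of the course start (px); must lie
#'   within `x_bounds`.
#' @param angles candidate angle set (degrees); defaults to the canonical
#'   five.
#' @param max_tries resampling attempts per segment before the bounds are
#'   declared unsatisfiable.
#' @return an object of class `lf_course` with elements `segments`
#'   (data.frame: index, angle_deg, start_x, end_x, y0, y1, height),
#'   `breaks_y`/`breaks_x` (junction coordinates), `goals` (data.frame with
#'   x, y), `x_bounds`, `start_x`, and `seed`.
#' @export
generate_course <- function(n_segments, seed = NULL,
                            x_bounds = c(40, 260),
                            start_x = mean(x_bounds),
                            angles = COURSE_ANGLES,
                            max_tries = 1000L) {
  stopifnot(length(x_bounds) == 2L, x_bounds[1] < x_bounds[2],
            n_segments >= 0)
  if (start_x < x_bounds[1] || start_x > x_bounds[2])
    stop("start_x (", start_x, ") lies outside x_bounds [",
         x_bounds[1], ", ", x_bounds[2], "]")
  if (!all(angles %in% COURSE_ANGLES))
    stop("angles must be a subset of {", paste(COURSE_ANGLES, collapse = ", "), "}")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  n_segments <- as.integer(n_segments)
  ang <- numeric(n_segments)
  xs <- numeric(n_segments + 1L)
  xs[1L] <- start_x
  for (k in seq_len(n_segments)) {
    tries <- 0L
    repeat {
      a <- if (length(angles) == 1L) angles else sample(angles, 1L)
      x_next <- xs[k] + segment_dx(a)
      if (x_next >= x_bounds[1] && x_next <= x_bounds[2]) break
      tries <- tries + 1L
      if (tries >= max_tries)
        stop("x_bounds unsatisfiable at segment ", k,
             ": every candidate angle leaves [",
             x_bounds[1], ", ", x_bounds[2], "] from x = ", xs[k])
    }
    ang[k] <- a
    xs[k + 1L] <- x_next
  }
  new_course(ang, xs, x_bounds, start_x, seed)
}

# Assemble the lf_course object from angle sequence and junction xs.
new_course <- function(ang, xs, x_bounds, start_x, seed = NULL) {
  n <- length(ang)
  breaks_y <- seq(0, by = SEGMENT_HEIGHT, length.out = n + 1L)
  segments <- data.frame(
    index = seq_len(n),
    angle_deg = ang,
    start_x = xs[seq_len(n)],
    end_x = xs[seq_len(n) + 1L],
    y0 = breaks_y[seq_len(n)],
    y1 = breaks_y[seq_len(n) + 1L],
    height = rep(SEGMENT_HEIGHT, n)
  )
  # goals: course start, every junction where the angle changes, course end
  corner <- if (n >= 2L) which(ang[-n] != ang[-1L]) else integer(0)
  idx <- sort(unique(c(0L, corner, n)))   # junction indices in 0..n
  goals <- data.frame(x = xs[idx + 1L], y = breaks_y[idx + 1L])
  structure(
    list(segments = segments, breaks_y = breaks_y, breaks_x = xs,
         goals = goals, x_bounds = x_bounds, start_x = start_x,
         seed = seed),
    class = "lf_course")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.lf_course <- function(x, ...) {
  n <- nrow(x$segments)
  cat("<lf_course> ", n, " segments (", n * SEGMENT_HEIGHT, " px), ",
      nrow(x$goals), " goals, x in [",
      x$x_bounds[1], ", ", x$x_bounds[2], "]\n", sep = "")
  invisible(x)
}

course_extent <- function(course) {
  SEGMENT_HEIGHT * nrow(course$segments)
}

check_y <- function(course, y) {
  ext <- course_extent(course)
  if (any(y < 0 | y > ext))
    stop("y outside course extent [0, ", ext, "]")
}

#' Horizontal position of the drawn line at depth y
#'
#' Continuous piecewise-linear interpolation within the segment containing
#' `y`; at a junction it equals the shared endpoint of both adjoining
#' segments.
#'
#' @param course an `lf_course`.
#' @param y course depth (px), in `[0, 48 * n_segments]`; vectorized.
#' @return line x (px).
#' @export
line_x_at <- function(course, y) {
  check_y(course, y)
  approx(course$breaks_y, course$breaks_x, xout = y, method = "linear",
         ties = "ordered")$y
}

#' Goal points of a course
#'
#' One goal at every junction where the incoming and outgoing angles
#' differ, plus the course start and end; ordered by y.
#'
#' @param course an `lf_course`.
#' @return data.frame with columns `x`, `y` (y a multiple of 48).
#' @export
goals_of <- function(course) course$goals

#' Horizontal position of the optimal line at depth y
#'
#' The optimal line is the polyline joining successive goals in y-order --
#' the shortest path through the corner goals.  With goals on every corner
#' it coincides with the drawn centerline.
#'
#' @inheritParams line_x_at
#' @return optimal x (px).
#' @export
optimal_x_at <- function(course, y) {
  check_y(course, y)
  g <- course$goals
  approx(g$y, g$x, xout = y, method = "linear", ties = "ordered")$y
}

#' Is the vehicle overlapping the line?
#'
#' True iff the horizontal offset between the vehicle center and the line
#' at the vehicle's row does not exceed `vehicle_radius + line_width / 2`
#' (inclusive at the boundary).  This is the bit behind the task's warning
#' display.
#'
#' @param vehicle_x vehicle center x (px).
#' @param course an `lf_course`.
#' @param row the vehicle's row in course coordinates (px): its fixed
#'   screen row plus the scroll offset.
#' @param geometry a [vehicle_geometry()].
#' @return logical.
#' @export
is_on_line <- function(vehicle_x, course, row, geometry = vehicle_geometry()) {
  check_y(course, row)
  abs(vehicle_x - line_x_at(course, row)) <=
    geometry$vehicle_radius + geometry$line_width / 2
}

#' Serialize a course to JSON
#'
#' Stores the seed, bounds, start and the angle sequence; the geometry is
#' reconstructed deterministically on load, so trials are exactly
#' reproducible across machines.
#'
#' @param course an `lf_course`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
course_to_json <- function(course, path = NULL) {
  doc <- list(seed = course$seed,
              x_bounds = course$x_bounds,
              start_x = course$start_x,
              angles = course$segments$angle_deg)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Deserialize a course from JSON
#'
#' @param x a file path or JSON string produced by [course_to_json()].
#' @return an `lf_course` identical to the serialized one.
#' @export
course_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x)
  ang <- as.numeric(doc$angles)
  # accumulate sequentially so the floating-point junctions are
  # bit-identical to the generated ones
  xs <- numeric(length(ang) + 1L)
  xs[1L] <- doc$start_x
  for (k in seq_along(ang)) xs[k + 1L] <- xs[k] + segment_dx(ang[k])
  if (any(xs < doc$x_bounds[1] - 1e-9 | xs > doc$x_bounds[2] + 1e-9))
    stop("serialized course violates its own x_bounds")
  new_course(ang, xs, as.numeric(doc$x_bounds), doc$start_x,
             if (is.null(doc$seed)) NULL else doc$seed)
}
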