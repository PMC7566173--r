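# The discrete-time task environment: 48 Hz command channel with
# stochastic success, 24 px/s scrolling, 40 ms screen updates, auto
# controller, and space-bar mode toggling.  These R functions are the
# reference semantics of one environment step; full trials run through the
# compiled event engine (see run_trial).

#' Vehicle and screen geometry
#'
#' The original environment's vehicle size, line width and screen size are
#' not printed in the task description; these defaults are plausible
#' values for a 300-px window and are all configurable.
#'
#' @param vehicle_radius vehicle circle radius (px).
#' @param line_width drawn line width (px).
#' @param vehicle_row the vehicle's fixed row, expressed as the course
#'   depth (px) that coincides with the vehicle at t = 0.
#' @param screen_width screen width (px); the vehicle center is clamped to
#'   `[0, screen_width]`.
#' @return a list of class `lf_geometry`.
#' @export
vehicle_geometry <- function(vehicle_radius = 10, line_width = 5,
                             vehicle_row = 0, screen_width = 300) {
  stopifnot(vehicle_radius > 0, line_width > 0, vehicle_row >= 0,
            screen_width > 0)
  structure(list(vehicle_radius = vehicle_radius, line_width = line_width,
                 vehicle_row = vehicle_row, screen_width = screen_width),
            class = "lf_geometry")
}

#' Environment configuration
#'
#' Defaults are the task's printed constants: the line scrolls at 24
#' pixels per second, the screen updates every 40 ms, commands are sampled
#' at 48 Hz (so the vehicle can move at most 2 px per scrolled line
#' pixel), and a trial lasts 40 s.  `ca` and `cm` are the probabilities
#' that a command issued in auto / manual mode is actually applied.
#'
#' @param ca auto command success probability in `[0, 1]`.
#' @param cm manual command success probability in `[0, 1]`.
#' @param scroll_speed line scroll speed (px/s).
#' @param frame_dt screen update period (s).
#' @param command_rate command sampling rate (commands/s).
#' @param trial_duration trial length (s).
#' @param geometry a [vehicle_geometry()].
#' @param initial_mode `"manual"` or `"auto"`.
#' @return a list of class `lf_env_config`.
#' @export
env_config <- function(ca = 0.5, cm = 0.5, scroll_speed = 24,
                       frame_dt = 0.040, command_rate = 48,
                       trial_duration = 40,
                       geometry = vehicle_geometry(),
                       initial_mode = c("manual", "auto")) {
  initial_mode <- match.arg(initial_mode)
  stopifnot(ca >= 0, ca <= 1, cm >= 0, cm <= 1,
            scroll_speed > 0, frame_dt > 0, command_rate > 0,
            trial_duration > 0, inherits(geometry, "lf_geometry"))
  structure(list(ca = ca, cm = cm, scroll_speed = scroll_speed,
                 frame_dt = frame_dt, command_rate = command_rate,
                 trial_duration = trial_duration, geometry = geometry,
                 initial_mode = initial_mode),
            class = "lf_env_config")
}

# Minimum course extent a config needs: the row swept during the trial.
required_extent <- function(config) {
  config$geometry$vehicle_row +
    config$trial_duration * config$scroll_speed
}

#' Initialize an environment state for one trial
#'
#' The vehicle starts centered on the line at its row, in the configured
#' initial mode, with no held keys and zero counters.
#'
#' @param config an [env_config()].
#' @param course an `lf_course`; must extend past the row swept during the
#'   trial.
#' @return a list of class `lf_env_state` with fields `t`, `vehicle_x`,
#'   `scroll_offset`, `mode`, `held_keys`, `on_line`, `switch_count`,
#'   `frames_on_line`, `frames_total`.
#' @export
init_trial <- function(config, course) {
  need <- required_extent(config)
  if (course_extent(course) < need)
    stop("course too short: extent ", course_extent(course),
         " px < required ", need, " px")
  row0 <- config$geometry$vehicle_row
  structure(list(
    t = 0, vehicle_x = line_x_at(course, row0), scroll_offset = 0,
    mode = config$initial_mode, held_keys = character(0),
    on_line = TRUE, switch_count = 0L,
    frames_on_line = 0L, frames_total = 0L,
    geometry = config$geometry), class = "lf_env_state")
}

#' Auto controller command
#'
#' If the vehicle center is more than half a pixel off the optimal line at
#' its row, the controller commands a 1-px correction toward it; otherwise
#' straight.
#'
#' @param state an `lf_env_state` in auto mode.
#' @param course an `lf_course`.
#' @return a list `(direction, source)` with direction one of
#'   `"left"`, `"straight"`, `"right"`.
#' @export
auto_command <- function(state, course) {
  stopifnot(state$mode == "auto")
  row <- state$geometry$vehicle_row + state$scroll_offset
  opt <- optimal_x_at(course, row)
  dir <- if (state$vehicle_x < opt - 0.5) "right"
         else if (state$vehicle_x > opt + 0.5) "left"
         else "straight"
  list(direction = dir, source = "auto")
}

#' Advance the environment by one command tick
#'
#' Advances the clock by `1 / command_rate`, the scroll by
#' `scroll_speed / command_rate` (0.5 px at the defaults), determines the
#' intended command (auto controller output in auto mode, held keys in
#' manual mode), and applies a left/right command with probability `ca`
#' (auto) or `cm` (manual): success moves the vehicle 1 px, clamped to the
#' screen; straight and failed commands leave it unchanged.  One uniform
#' draw is consumed for every non-straight command.
#'
#' @param state an `lf_env_state`.
#' @param config an [env_config()].
#' @param course an `lf_course`.
#' @return the advanced state.
#' @export
command_tick <- function(state, config, course) {
  state$t <- state$t + 1 / config$command_rate
  state$scroll_offset <- state$scroll_offset +
    config$scroll_speed / config$command_rate
  dir <- if (state$mode == "auto") {
    auto_command(state, course)$direction
  } else {
    if ("left" %in% state$held_keys) "left"
    else if ("right" %in% state$held_keys) "right"
    else "straight"
  }
  if (dir != "straight") {
    p <- if (state$mode == "auto") config$ca else config$cm
    if (runif(1) < p) {
      step <- if (dir == "left") -1 else 1
      state$vehicle_x <- min(max(state$vehicle_x + step, 0),
                             config$geometry$screen_width)
    }
  }
  state
}

#' Toggle the control mode (space-bar press)
#'
#' Flips the mode, increments the switch counter and empties the held
#' keys (the model releases keys before pressing space).
#'
#' @param state an `lf_env_state`.
#' @return the toggled state.
#' @export
toggle_mode <- function(state) {
  state$mode <- if (state$mode == "auto") "manual" else "auto"
  state$switch_count <- state$switch_count + 1L
  state$held_keys <- character(0)
  state
}

#' Screen-update bookkeeping
#'
#' Evaluates the on-line predicate at the current scroll offset,
#' increments the frame counters, and latches the warning bit that
#' perception consumes.
#'
#' @param state an `lf_env_state`.
#' @param config an [env_config()].
#' @param course an `lf_course`.
#' @return the updated state.
#' @export
frame_update <- function(state, config, course) {
  row <- state$geometry$vehicle_row + state$scroll_offset
  state$on_line <- is_on_line(state$vehicle_x, course, row, config$geometry)
  state$frames_total <- state$frames_total + 1L
  if (state$on_line) state$frames_on_line <- state$frames_on_line + 1L
  state
}
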