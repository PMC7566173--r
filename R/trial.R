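# Running one trial: the unified event schedule (command ticks, frame
# updates, production firings, motor completions) for a cognitive model
# or a scripted baseline agent.

#' Run one trial
#'
#' Runs the event-driven engine for `trial_duration` seconds and returns
#' the three behavioral indices: `performance` (fraction of frames the
#' vehicle overlapped the line), `auto_use_ratio` (fraction of trial time
#' in auto mode) and `n_switches` (space presses).
#'
#' `agent` is either an [build_model()] object (the cognitive model) or
#' one of the scripted agents: `"auto_only"` (auto controller for the
#' whole trial, no cognition), `"do_nothing"` (no commands, stays in the
#' initial mode), `"hold_left"` / `"hold_right"` (one key held from t = 0
#' in manual mode).
#'
#' @param agent an `lf_model` or a scripted-agent name.
#' @param config an [env_config()].
#' @param course an `lf_course`; when `NULL` a course long enough for the
#'   trial is generated from the current RNG stream, with bounds placed
#'   50 px inside the screen.
#' @param seed optional integer seed; seeds course generation and every
#'   stochastic element of the trial.
#' @param trace logical; when `TRUE` the result carries a time-ordered
#'   event trace (fires, rewards, motor completions, toggles, frames) and
#'   a per-reward utility log.
#' @return a list of class `lf_trial`.
#' @export
run_trial <- function(agent, config = env_config(), course = NULL,
                      seed = NULL, trace = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  scripted <- is.character(agent)
  if (scripted)
    agent <- match.arg(agent, c("auto_only", "do_nothing",
                                "hold_left", "hold_right"))
  else if (!inherits(agent, "lf_model"))
    stop("agent must be an lf_model or a scripted-agent name")

  geom <- config$geometry
  if (is.null(course)) {
    n_seg <- ceiling(required_extent(config) / SEGMENT_HEIGHT) + 2L
    margin <- min(50, geom$screen_width / 4)
    course <- generate_course(n_seg,
                              x_bounds = c(margin, geom$screen_width - margin))
  }
  if (course_extent(course) < required_extent(config))
    stop("course too short: extent ", course_extent(course),
         " px < required ", required_extent(config), " px")

  initial_mode <- config$initial_mode
  held_init <- 0L
  if (scripted) {
    if (agent == "auto_only") initial_mode <- "auto"
    if (agent == "hold_left") { initial_mode <- "manual"; held_init <- 1L }
    if (agent == "hold_right") { initial_mode <- "manual"; held_init <- 2L }
  }

  model <- if (scripted) build_model() else agent
  cfg <- list(
    ca = config$ca, cm = config$cm, scroll_speed = config$scroll_speed,
    frame_dt = config$frame_dt, command_rate = config$command_rate,
    trial_duration = config$trial_duration,
    vehicle_radius = geom$vehicle_radius, line_width = geom$line_width,
    screen_width = geom$screen_width, vehicle_row = geom$vehicle_row,
    initial_mode = if (initial_mode == "auto") 1L else 0L,
    agent = if (scripted) 0L else 1L,
    held_init = held_init,
    smdp = model$rewarding == "smdp",
    gating = model$conflict == "gating",
    allow_to_auto = !isTRUE(model$manual_only),
    alpha = model$learning$alpha,
    egs = model$conflict_p$s,
    initial_utility = model$learning$initial_utility,
    reward_online = model$reward$reward_online,
    reward_offline = model$reward$reward_offline,
    max_vehicle_speed = model$reward$max_vehicle_speed,
    firing_time = model$motor$firing_time,
    prep_time = model$motor$prep_time,
    exec_time = model$motor$exec_time,
    align_tol = model$align_tol,
    goal_nearest_abs = isTRUE(model$goal_nearest_abs),
    trace = isTRUE(trace))

  res <- run_trial_engine(course$breaks_y, course$breaks_x,
                          course$goals$y, course$goals$x, cfg)
  res$agent <- if (scripted) agent else
    paste0(model$conflict, "-", model$rewarding)
  res$course <- course
  res$seed <- seed
  class(res) <- "lf_trial"
  res
}

#' @export
print.lf_trial <- function(x, ...) {
  cat(sprintf(
    "<lf_trial> agent = %s | performance = %.3f | auto use = %.3f | switches = %d\n",
    x$agent, x$performance, x$auto_use_ratio, x$n_switches))
  invisible(x)
}

#' Write a trial trace as JSON lines
#'
#' One event per line: time, type, payload.  The trial must have been run
#' with `trace = TRUE`.
#'
#' @param trial an `lf_trial`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(trial, path) {
  if (is.null(trial$trace)) stop("trial was run without trace = TRUE")
  tr <- trial$trace
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(tr))) {
    rec <- list(time = tr$time[i], type = tr$event[i])
    if (!is.na(tr$detail[i])) rec$detail <- tr$detail[i]
    if (!is.na(tr$value[i])) rec$value <- tr$value[i]
    rec$vehicle_x <- tr$vehicle_x[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
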