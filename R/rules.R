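# The task model: the 11-rule perception/action cycle, the two rewarding
# schemes (fixed online/offline rewards vs semi-Markov reward summation),
# and the gate comparing self-confidence against trust.

#' Canonical rule names
#'
#' The model runs on 11 production rules.  `FindVehicle` has on-line and
#' off-line condition branches that share one name and one utility and
#' differ only in which reward they trigger, so it counts once.
#' @export
RULE_NAMES <- c("FindVehicle", "FindGoal", "KeepA", "ToManual", "PressSpace",
                "KeepM", "ToAuto", "ToLeft", "ToRight", "LtoS", "RtoS")

#' Reward parameters
#'
#' The default scheme pays a fixed reward when the vehicle is perceived on
#' the line and zero off it.  The semi-Markov scheme instead approximates
#' the vehicle's travel distance since the previous reward: on line,
#' `max_vehicle_speed * duration`; off line, the absolute displacement of
#' the perceived vehicle position.
#'
#' @param reward_online fixed on-line reward (default scheme).
#' @param reward_offline fixed off-line reward (default scheme).
#' @param max_vehicle_speed maximum vehicle speed (px/s), the command rate
#'   times 1 px.
#' @param gamma time discount rate of the reward summation; fixed at 1
#'   (the sums are undiscounted).
#' @return a list of class `lf_reward_params`.
#' @export
reward_params <- function(reward_online = 10, reward_offline = 0,
                          max_vehicle_speed = 48, gamma = 1) {
  stopifnot(max_vehicle_speed > 0, gamma > 0, gamma <= 1)
  structure(list(reward_online = reward_online,
                 reward_offline = reward_offline,
                 max_vehicle_speed = max_vehicle_speed,
                 gamma = gamma), class = "lf_reward_params")
}

#' Build a task model
#'
#' Composes the canonical production set with one of four variants:
#' rewarding `"default"` (fixed 10/0) or `"smdp"` (reward summation over
#' the interval since the last reward), and conflict `"default"` or
#' `"gating"` (the mode-switch rules additionally require the gate
#' condition: self-confidence `SC`, the utility of `KeepM`, is compared
#' with trust `T`, the utility of `KeepA`; `ToAuto` needs `SC <= T`,
#' `ToManual` needs `SC >= T`, both inclusive).
#'
#' @param rewarding `"default"` or `"smdp"`.
#' @param conflict `"default"` or `"gating"`.
#' @param learning a [learning_params()].
#' @param conflict_p a [conflict_params()].
#' @param reward a [reward_params()].
#' @param motor a [motor_params()].
#' @param temporal a [temporal_params()].
#' @param manual_only drop the `ToAuto` rule (the manual-only baseline
#'   model).
#' @param align_tol alignment tolerance (px): goal and vehicle closer than
#'   this count as aligned in the manual rule conditions.
#' @return a list of class `lf_model` with a `rules` data.frame (name,
#'   utility) and the parameter sets.
#' @export
build_model <- function(rewarding = c("default", "smdp"),
                        conflict = c("default", "gating"),
                        learning = learning_params(),
                        conflict_p = conflict_params(),
                        reward = reward_params(),
                        motor = motor_params(),
                        temporal = temporal_params(),
                        manual_only = FALSE,
                        align_tol = 2) {
  rewarding <- match.arg(rewarding)
  conflict <- match.arg(conflict)
  stopifnot(align_tol >= 0)
  rules <- data.frame(name = RULE_NAMES,
                      utility = rep(learning$initial_utility,
                                    length(RULE_NAMES)))
  structure(list(rules = rules, rewarding = rewarding, conflict = conflict,
                 learning = learning, conflict_p = conflict_p,
                 reward = reward, motor = motor, temporal = temporal,
                 manual_only = manual_only, align_tol = align_tol),
            class = "lf_model")
}

#' @export
print.lf_model <- function(x, ...) {
  cat("<lf_model> ", nrow(x$rules), " rules; rewarding = ", x$rewarding,
      ", conflict = ", x$conflict,
      if (x$manual_only) ", manual-only" else "", "\n", sep = "")
  invisible(x)
}

#' The four model variants
#'
#' @return data.frame with columns `label`, `rewarding`, `conflict`
#'   enumerating Default-Default, Default-SMDP, Gating-Default and
#'   Gating-SMDP.
#' @export
model_variants <- function() {
  data.frame(
    label = c("Default-Default", "Default-SMDP",
              "Gating-Default", "Gating-SMDP"),
    rewarding = c("default", "smdp", "default", "smdp"),
    conflict = c("default", "default", "gating", "gating"))
}

#' Is the gate open for a mode switch?
#'
#' `to_auto` requires `SC <= T`; `to_manual` requires `SC >= T` (both
#' inclusive, so at equality both switches are possible and ordinary
#' conflict resolution decides).
#'
#' @param direction `"to_auto"` or `"to_manual"`.
#' @param sc self-confidence: the utility of `KeepM`.
#' @param t trust: the utility of `KeepA`.
#' @return logical.
#' @export
gate_open <- function(direction = c("to_auto", "to_manual"), sc, t) {
  direction <- match.arg(direction)
  if (direction == "to_auto") sc <= t else sc >= t
}

#' Fixed reward of the default scheme
#'
#' @param on_line logical: was the vehicle perceived on the line?
#' @param params a [reward_params()].
#' @return the reward (10 on line, 0 off line at the defaults).
#' @export
default_reward <- function(on_line, params = reward_params()) {
  if (on_line) params$reward_online else params$reward_offline
}

#' Semi-Markov reward: approximate travel distance since the last reward
#'
#' On line the model credits the maximum possible travel,
#' `max_vehicle_speed * duration_est`; off line it credits the observed
#' displacement `|vposi_now - vposi_prev|` of the perceived vehicle
#' position.  The exact travel distance is unknowable to the model because
#' the vehicle is only perceived when `FindVehicle` fires.
#'
#' @param on_line logical.
#' @param duration_est estimated time since the last reward (s), `>= 0`.
#' @param vposi_now,vposi_prev perceived vehicle x now and at the last
#'   reward (px).
#' @param params a [reward_params()].
#' @return the reward.
#' @export
smdp_reward <- function(on_line, duration_est, vposi_now, vposi_prev,
                        params = reward_params()) {
  if (duration_est < 0) stop("duration_est must be >= 0")
  if (on_line) params$max_vehicle_speed * duration_est
  else abs(vposi_now - vposi_prev)
}

#' Eligible rules for a buffer snapshot
#'
#' The condition table of the whole rule set, isolated here so the
#' reconstruction of the five manual rules' conditions can be revised in
#' one place.  The perception phase is keyed off the goal buffer: with no
#' perceived vehicle only `FindVehicle` matches; with a vehicle but no
#' goal only `FindGoal`.  In the motor phase the mode determines the
#' conflict set: in auto, `KeepA` and (gate permitting) `ToManual`.  In
#' manual the five rules carry mutually exclusive conditions over the
#' perceived goal side (left / aligned within the tolerance / right) and
#' the current move-command, so exactly one of them matches a given
#' situation and competes (gate permitting) with `ToAuto`: `ToLeft` when
#' the goal is left and no command is active, `ToRight` symmetrically,
#' `LtoS` when a left command is active but the goal is no longer left,
#' `RtoS` symmetrically, and `KeepM` otherwise (aligned with no command,
#' or the active command already points at the goal).  During a mode
#' switch only `PressSpace` matches, and only once the motor module is
#' free.
#'
#' @param model an `lf_model`.
#' @param buffers list with elements `mode` ("auto"/"manual"),
#'   `vehicle_x` (perceived; `NULL` before `FindVehicle`), `goal_x`
#'   (perceived; `NULL` before `FindGoal`), `held_keys` (character),
#'   `switching` (logical), `motor_idle` (logical).
#' @return character vector of eligible rule names (possibly empty: the
#'   engine idles until the next buffer change).
#' @export
eligible_rules <- function(model, buffers) {
  mode <- buffers$mode
  if (isTRUE(buffers$switching))
    return(if (isTRUE(buffers$motor_idle)) "PressSpace" else character(0))
  if (is.null(buffers$vehicle_x)) return("FindVehicle")
  if (is.null(buffers$goal_x)) return("FindGoal")
  u <- setNames(model$rules$utility, model$rules$name)
  gated <- function(direction) {
    model$conflict != "gating" || gate_open(direction, u[["KeepM"]], u[["KeepA"]])
  }
  if (mode == "auto") {
    el <- "KeepA"
    if (gated("to_manual")) el <- c(el, "ToManual")
    return(el)
  }
  held <- buffers$held_keys %||% character(0)
  tol <- model$align_tol
  goal_left <- buffers$goal_x < buffers$vehicle_x - tol
  goal_right <- buffers$goal_x > buffers$vehicle_x + tol
  el <- if ("left" %in% held) {
    if (goal_left) "KeepM" else "LtoS"
  } else if ("right" %in% held) {
    if (goal_right) "KeepM" else "RtoS"
  } else {
    if (goal_left) "ToLeft" else if (goal_right) "ToRight" else "KeepM"
  }
  if (!model$manual_only && gated("to_auto")) el <- c(el, "ToAuto")
  el
}

`%||%` <- function(a, b) if (is.null(a)) b else a
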