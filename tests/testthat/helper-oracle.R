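# Brute-force fixed-step reference simulator.
#
# Advances a trial millisecond by millisecond on an integer clock and
# applies the full task semantics (command channel, screen updates, rule
# firings, motor module, rewards, gating) with plain R data structures.
# It shares no scheduling code with the compiled event engine; agreement
# of the two traces, event for event, is the scheduler correctness check.
# Every interval in the configuration must be an integer number of
# milliseconds, which is why oracle comparisons use a 50 Hz command
# channel instead of the production 48 Hz.
#
# Randomness is drawn from R's RNG with the same discipline as the
# engine: one uniform per non-straight command, one per tie-break among
# utility maxima (egs = 0), one per eligible rule when egs > 0.

oracle_run <- function(course, cfg) {
  as_ms <- function(x) {
    m <- round(x * 1000)
    stopifnot(abs(x * 1000 - m) < 1e-9)
    as.integer(m)
  }
  tick_ms <- as_ms(1 / cfg$command_rate)
  frame_ms <- as_ms(cfg$frame_dt)
  fire_ms <- as_ms(cfg$firing_time)
  prep_ms <- as_ms(cfg$prep_time)
  exec_ms <- as_ms(cfg$exec_time)
  dur_ms <- as_ms(cfg$trial_duration)
  band <- cfg$vehicle_radius + cfg$line_width / 2

  line_at <- function(row) approx(course$breaks_y, course$breaks_x,
                                  xout = row, ties = "ordered")$y
  opt_at <- function(row) approx(course$goals$y, course$goals$x,
                                 xout = row, ties = "ordered")$y

  rules <- c("FindVehicle", "FindGoal", "KeepA", "ToManual", "PressSpace",
             "KeepM", "ToAuto", "ToLeft", "ToRight", "LtoS", "RtoS")
  U <- setNames(rep(cfg$initial_utility, 11), rules)
  fired <- setNames(rep(FALSE, 11), rules)

  veh <- line_at(cfg$vehicle_row)
  mode <- cfg$initial_mode                    # 0 manual, 1 auto
  held_l <- cfg$held_init == 1; held_r <- cfg$held_init == 2
  intent_l <- held_l; intent_r <- held_r
  on_line <- abs(veh - line_at(cfg$vehicle_row)) <= band + 1e-9
  last_reward_ms <- 0L; vposi_prev <- veh
  perc_vx <- NA_real_; perc_gx <- NA_real_
  phase <- "VEHICLE"; in_flight <- NA_character_; effect_ms <- NA_integer_
  queue <- character(0)
  motor_busy <- FALSE; motor_done <- NA_integer_
  cur_op <- NA_character_; last_move <- NA_character_
  gcur <- 1L
  switch_count <- 0L; frames_on <- 0L; frames_total <- 0L
  auto_ms <- 0L; mode_since <- 0L

  tr_time <- numeric(0); tr_ev <- character(0); tr_det <- character(0)
  tr_val <- numeric(0); tr_vx <- numeric(0)
  log_ev <- function(ms, ev, det, val) {
    tr_time[length(tr_time) + 1L] <<- ms / 1000
    tr_ev[length(tr_ev) + 1L] <<- ev
    tr_det[length(tr_det) + 1L] <<- det
    tr_val[length(tr_val) + 1L] <<- val
    tr_vx[length(tr_vx) + 1L] <<- veh
  }

  motor_try_start <- function(ms) {
    if (motor_busy || !length(queue)) return()
    cur_op <<- queue[1L]
    queue <<- queue[-1L]
    p <- if (identical(cur_op, last_move)) 0L else prep_ms
    motor_done <<- ms + p + exec_ms
    last_move <<- cur_op
    motor_busy <<- TRUE
  }
  enqueue <- function(op, ms) {
    queue[length(queue) + 1L] <<- op
    motor_try_start(ms)
  }

  select_rule <- function(el) {
    if (length(el) == 1L) return(el)
    if (cfg$egs == 0) {
      tied <- el[U[el] == max(U[el])]
      if (length(tied) == 1L) return(tied)
      u <- runif(1)
      return(tied[min(floor(u * length(tied)) + 1, length(tied))])
    }
    u <- runif(length(el))
    el[which.max(U[el] + cfg$egs * log(u / (1 - u)))]
  }

  maybe_select <- function(ms) {
    if (cfg$agent != 1L || !is.na(in_flight)) return()
    el <- switch(phase,
      VEHICLE = "FindVehicle",
      GOAL = "FindGoal",
      MOTOR = {
        if (mode == 1L) {
          e <- "KeepA"
          if (!cfg$gating || U[["KeepM"]] >= U[["KeepA"]]) e <- c(e, "ToManual")
          e
        } else {
          gl <- perc_gx < perc_vx - cfg$align_tol
          gr <- perc_gx > perc_vx + cfg$align_tol
          situ <- if (intent_l) { if (gl) "KeepM" else "LtoS" }
            else if (intent_r) { if (gr) "KeepM" else "RtoS" }
            else if (gl) "ToLeft" else if (gr) "ToRight" else "KeepM"
          e <- situ
          if (cfg$allow_to_auto &&
              (!cfg$gating || U[["KeepM"]] <= U[["KeepA"]])) e <- c(e, "ToAuto")
          e
        }
      },
      SWITCH = if (!motor_busy && !length(queue)) "PressSpace" else character(0),
      WAIT = character(0))
    if (!length(el)) return()
    in_flight <<- select_rule(el)
    effect_ms <<- ms + fire_ms
  }

  clear_goal <- function() { perc_vx <<- NA_real_; perc_gx <<- NA_real_ }

  rule_effect <- function(ms) {
    r <- in_flight
    in_flight <<- NA_character_; effect_ms <<- NA_integer_
    fired[[r]] <<- TRUE
    log_ev(ms, "fire", r, NA_real_)
    if (r == "FindVehicle") {
      perc_vx <<- veh
      R <- if (on_line) {
        if (cfg$smdp) cfg$max_vehicle_speed * (ms - last_reward_ms) / 1000
        else cfg$reward_online
      } else {
        if (cfg$smdp) abs(veh - vposi_prev) else cfg$reward_offline
      }
      for (nm in rules[fired]) U[[nm]] <<- U[[nm]] + cfg$alpha * (R - U[[nm]])
      fired[] <<- FALSE
      last_reward_ms <<- ms
      log_ev(ms, "reward", NA_character_, R)
      vposi_prev <<- perc_vx
      phase <<- "GOAL"
    } else if (r == "FindGoal") {
      row <- cfg$vehicle_row + cfg$scroll_speed * ms / 1000
      while (gcur <= nrow(course$goals) && course$goals$y[gcur] <= row + 1e-9)
        gcur <<- gcur + 1L
      stopifnot(gcur <= nrow(course$goals))
      perc_gx <<- course$goals$x[gcur]
      phase <<- "MOTOR"
    } else if (r %in% c("KeepA", "KeepM")) {
      clear_goal(); phase <<- "VEHICLE"
    } else if (r == "ToLeft") {
      enqueue("press_left", ms); intent_l <<- TRUE
      clear_goal(); phase <<- "VEHICLE"
    } else if (r == "ToRight") {
      enqueue("press_right", ms); intent_r <<- TRUE
      clear_goal(); phase <<- "VEHICLE"
    } else if (r == "LtoS") {
      enqueue("release_left", ms); intent_l <<- FALSE
      clear_goal(); phase <<- "VEHICLE"
    } else if (r == "RtoS") {
      enqueue("release_right", ms); intent_r <<- FALSE
      clear_goal(); phase <<- "VEHICLE"
    } else if (r %in% c("ToAuto", "ToManual")) {
      if (intent_l) { enqueue("release_left", ms); intent_l <<- FALSE }
      if (intent_r) { enqueue("release_right", ms); intent_r <<- FALSE }
      phase <<- "SWITCH"
    } else if (r == "PressSpace") {
      enqueue("space", ms)
      phase <<- "WAIT"
    }
  }

  motor_complete <- function(ms) {
    op <- cur_op
    motor_busy <<- FALSE; motor_done <<- NA_integer_
    if (op == "press_left") held_l <<- TRUE
    else if (op == "press_right") held_r <<- TRUE
    else if (op == "release_left") held_l <<- FALSE
    else if (op == "release_right") held_r <<- FALSE
    else if (op == "space") {
      if (mode == 1L) auto_ms <<- auto_ms + (ms - mode_since)
      mode <<- 1L - mode; mode_since <<- ms
      switch_count <<- switch_count + 1L
      held_l <<- held_r <<- intent_l <<- intent_r <<- FALSE
      if (cfg$agent == 1L) { clear_goal(); phase <<- "VEHICLE" }
      log_ev(ms, "toggle", NA_character_, as.numeric(mode))
    }
    log_ev(ms, "motor", op, NA_real_)
    motor_try_start(ms)
  }

  do_tick <- function(ms) {
    cmd <- 0L
    if (mode == 1L) {
      opt <- opt_at(cfg$vehicle_row + cfg$scroll_speed * ms / 1000)
      if (veh < opt - 0.5) cmd <- 1L else if (veh > opt + 0.5) cmd <- -1L
    } else {
      if (held_l) cmd <- -1L else if (held_r) cmd <- 1L
    }
    if (cmd != 0L) {
      u <- runif(1)
      p <- if (mode == 1L) cfg$ca else cfg$cm
      if (u < p) veh <<- min(max(veh + cmd, 0), cfg$screen_width)
    }
  }

  do_frame <- function(ms) {
    row <- cfg$vehicle_row + cfg$scroll_speed * ms / 1000
    on_line <<- abs(veh - line_at(row)) <= band + 1e-9
    frames_total <<- frames_total + 1L
    if (on_line) frames_on <<- frames_on + 1L
    log_ev(ms, "frame", NA_character_, as.numeric(on_line))
  }

  maybe_select(0L)
  for (ms in seq_len(dur_ms)) {
    if (ms %% tick_ms == 0L) do_tick(ms)
    if (ms %% frame_ms == 0L) do_frame(ms)
    if (motor_busy && !is.na(motor_done) && ms == motor_done) motor_complete(ms)
    if (!is.na(in_flight) && ms == effect_ms) rule_effect(ms)
    maybe_select(ms)
  }
  if (mode == 1L) auto_ms <- auto_ms + dur_ms - mode_since

  list(trace = data.frame(time = tr_time, event = tr_ev, detail = tr_det,
                          value = tr_val, vehicle_x = tr_vx,
                          stringsAsFactors = FALSE),
       performance = frames_on / frames_total,
       auto_use_ratio = auto_ms / dur_ms,
       n_switches = switch_count,
       utilities = U)
}

# Build the engine-style configuration list for the oracle from the
# package-level objects, mirroring run_trial()'s assembly.
oracle_cfg <- function(config, model = build_model(), agent = 1L,
                       held_init = 0L, initial_mode = NULL) {
  g <- config$geometry
  list(ca = config$ca, cm = config$cm, scroll_speed = config$scroll_speed,
       frame_dt = config$frame_dt, command_rate = config$command_rate,
       trial_duration = config$trial_duration,
       vehicle_radius = g$vehicle_radius, line_width = g$line_width,
       screen_width = g$screen_width, vehicle_row = g$vehicle_row,
       initial_mode = if (is.null(initial_mode))
         as.integer(config$initial_mode == "auto") else initial_mode,
       agent = agent, held_init = held_init,
       smdp = model$rewarding == "smdp", gating = model$conflict == "gating",
       allow_to_auto = !isTRUE(model$manual_only),
       alpha = model$learning$alpha, egs = model$conflict_p$s,
       initial_utility = model$learning$initial_utility,
       reward_online = model$reward$reward_online,
       reward_offline = model$reward$reward_offline,
       max_vehicle_speed = model$reward$max_vehicle_speed,
       firing_time = model$motor$firing_time,
       prep_time = model$motor$prep_time,
       exec_time = model$motor$exec_time,
       align_tol = model$align_tol)
}
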