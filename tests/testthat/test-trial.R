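# Whole-trial properties of the event-driven engine.

expect_traces_equal <- function(eng, orc) {
  a <- eng$trace
  o <- orc$trace
  expect_identical(nrow(a), nrow(o))
  n <- nrow(a)
  expect_true(all(abs(a$time - o$time) < 1e-6))
  expect_identical(a$event, o$event)
  expect_identical(is.na(a$detail), is.na(o$detail))
  expect_identical(a$detail[!is.na(a$detail)], o$detail[!is.na(o$detail)])
  expect_true(all(abs(a$vehicle_x - o$vehicle_x) < 1e-9))
  val_ok <- is.na(a$value) == is.na(o$value)
  expect_true(all(val_ok))
  idx <- !is.na(a$value)
  expect_true(all(abs(a$value[idx] - o$value[idx]) < 1e-9))
  expect_equal(eng$performance, orc$performance, tolerance = 1e-12)
  expect_equal(eng$auto_use_ratio, orc$auto_use_ratio, tolerance = 1e-9)
  expect_identical(as.integer(eng$n_switches), as.integer(orc$n_switches))
  expect_equal(unclass(eng$utilities), orc$utilities, tolerance = 1e-9)
}

test_that("the event-driven trace equals the fixed-step reference, event for event", {
  cases <- list(
    list(model = build_model("default", "default"),
         env = toy_env(ca = 0.8, cm = 0.8), course_seed = 3, seed = 101),
    list(model = build_model("smdp", "gating"),
         env = toy_env(ca = 1, cm = 0.6), course_seed = 5, seed = 202),
    list(model = build_model("smdp", "default"),
         env = toy_env(ca = 0.5, cm = 0.5, initial_mode = "auto"),
         course_seed = 8, seed = 303))
  for (cs in cases) {
    co <- generate_course(4, seed = cs$course_seed, x_bounds = c(60, 240))
    eng <- run_trial(cs$model, cs$env, course = co, seed = cs$seed,
                     trace = TRUE)
    set.seed(cs$seed)
    orc <- oracle_run(co, oracle_cfg(cs$env, cs$model))
    expect_traces_equal(eng, orc)
  }
})

test_that("identical seeds reproduce identical trials", {
  m <- build_model("smdp", "gating")
  a <- run_trial(m, env_config(ca = 0.5, cm = 0.5), seed = 7, trace = TRUE)
  b <- run_trial(m, env_config(ca = 0.5, cm = 0.5), seed = 7, trace = TRUE)
  expect_identical(a$trace, b$trace)
  expect_identical(a$utilities, b$utilities)
  expect_identical(a$performance, b$performance)
})

test_that("mode time is conserved and switches match trace toggles", {
  m <- build_model("smdp", "gating")
  for (s in c(11, 12, 13)) {
    tr <- run_trial(m, env_config(ca = 0.4, cm = 0.6), seed = s, trace = TRUE)
    expect_gte(tr$performance, 0); expect_lte(tr$performance, 1)
    expect_gte(tr$auto_use_ratio, 0); expect_lte(tr$auto_use_ratio, 1)
    toggles <- subset(tr$trace, event == "toggle")
    expect_identical(nrow(toggles), as.integer(tr$n_switches))
    # reconstruct auto time from the toggle sequence (trials start manual)
    bounds <- c(0, toggles$time, 40)
    modes <- rep(c(0, 1), length.out = length(bounds) - 1)  # 0 manual
    auto_time <- sum(diff(bounds)[modes == 1])
    expect_equal(auto_time + sum(diff(bounds)[modes == 0]), 40,
                 tolerance = 1e-9)
    expect_equal(tr$auto_use_ratio, auto_time / 40, tolerance = 1e-9)
  }
})

test_that("every mode toggle follows key releases and a space press", {
  m <- build_model("default", "default")
  tr <- run_trial(m, env_config(ca = 0.4, cm = 0.4), seed = 21, trace = TRUE)
  expect_gt(tr$n_switches, 0)
  trc <- tr$trace
  toggle_i <- which(trc$event == "toggle")
  for (i in toggle_i) {
    before <- trc[seq_len(i - 1), ]
    # the switch intention: last ToAuto/ToManual firing before the toggle
    sw <- max(which(before$event == "fire" &
                      before$detail %in% c("ToAuto", "ToManual")))
    ps <- max(which(before$event == "fire" & before$detail == "PressSpace"))
    expect_gt(ps, sw)
    # all key releases requested by the switch complete before PressSpace
    seg <- before[sw:ps, ]
    rel <- which(seg$event == "motor" & grepl("release", seg$detail))
    if (length(rel)) expect_true(max(rel) < nrow(seg))
    # the space press completes exactly at the toggle
    space <- which(trc$event == "motor" & trc$detail == "space")
    expect_true(any(abs(trc$time[space] - trc$time[i]) < 1e-9))
  }
})

test_that("self-confidence moves only in manual episodes and trust only in auto", {
  m <- build_model("smdp", "gating")
  for (s in c(31, 32)) {
    tr <- run_trial(m, env_config(ca = 0.5, cm = 0.5), seed = s, trace = TRUE)
    ul <- tr$utility_log
    toggles <- subset(tr$trace, event == "toggle")$time
    # mode at time t (trials start in manual mode)
    mode_at <- function(t) {
      if (!length(toggles)) return("manual")
      k <- sum(toggles < t - 1e-9)
      if (k %% 2 == 0) "manual" else "auto"
    }
    sc <- ul$utilities[, "KeepM"]
    tt <- ul$utilities[, "KeepA"]
    sc_changes <- which(abs(diff(sc)) > 1e-12) + 1L
    tt_changes <- which(abs(diff(tt)) > 1e-12) + 1L
    expect_true(all(vapply(ul$time[sc_changes], mode_at, "") == "manual"))
    expect_true(all(vapply(ul$time[tt_changes], mode_at, "") == "auto"))
  }
})

test_that("with perfect automation the gated model locks into auto", {
  # on a vertical course with Ca = 1 nothing ever goes off line in auto,
  # so trust never falls; once trust exceeds self-confidence the model
  # must stay in auto for the rest of the trial
  m <- build_model("smdp", "gating")
  cfg <- env_config(ca = 1, cm = 0.5, initial_mode = "auto")
  co <- straight_course()
  ok <- logical(200)
  for (i in seq_len(200)) {
    tr <- run_trial(m, cfg, course = co, seed = 5000 + i, trace = TRUE)
    ul <- tr$utility_log
    toggles <- subset(tr$trace, event == "toggle")$time
    above <- which(ul$utilities[, "KeepA"] > ul$utilities[, "KeepM"])
    ok[i] <- if (!length(above)) TRUE else {
      # in-auto time at which trust first exceeds self-confidence
      tau <- ul$time[above[1]]
      !any(toggles > tau)
    }
  }
  expect_gte(mean(ok), 0.95)
})

test_that("malformed agents are rejected", {
  expect_error(run_trial("not_an_agent"), "arg")
  expect_error(run_trial(list()), "lf_model")
})
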