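// Event-driven trial engine.
//
// One 40-s trial interleaves three clocks: the command channel (default
// 48 Hz), the screen update (default 40 ms) and the production system
// (50 ms firings plus motor preparation/execution).  The engine advances
// from event to event; at equal times the fixed priority is
// command tick < frame update < motor completion < rule effect, and two
// times closer than 1e-9 s count as equal (genuinely distinct events in
// any admissible configuration are at least 1/240 s apart).
//
// All randomness flows through R's RNG (unif_rand), so a single
// set.seed() in R reproduces the whole trial, and an R-level fixed-step
// simulation sharing the same draw discipline consumes an identical
// stream: one uniform per non-straight command, one per tie-break among
// utility maxima, one per eligible rule when the noise scale is positive.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double TEPS = 1e-9;

enum Rule { R_FINDVEH = 0, R_FINDGOAL, R_KEEPA, R_TOMANUAL, R_PRESSSPACE,
            R_KEEPM, R_TOAUTO, R_TOLEFT, R_TORIGHT, R_LTOS, R_RTOS,
            N_RULES };
static const char* RULE_NM[N_RULES] = {
  "FindVehicle", "FindGoal", "KeepA", "ToManual", "PressSpace",
  "KeepM", "ToAuto", "ToLeft", "ToRight", "LtoS", "RtoS" };

enum Phase { P_VEHICLE, P_GOAL, P_MOTOR, P_SWITCH, P_WAIT };
enum Op { OP_PRESS_L = 0, OP_PRESS_R, OP_REL_L, OP_REL_R, OP_SPACE, OP_NONE };
static const char* OP_NM[5] = {
  "press_left", "press_right", "release_left", "release_right", "space" };

// trace event codes
enum Ev { EV_FIRE = 0, EV_REWARD, EV_MOTOR, EV_TOGGLE, EV_FRAME };
static const char* EV_NM[5] = { "fire", "reward", "motor", "toggle", "frame" };

// Piecewise-linear interpolation with a moving cursor (queries are
// nondecreasing in course depth over a trial).
struct Interp {
  std::vector<double> y, x;
  size_t cur;
  Interp(NumericVector yy, NumericVector xx)
    : y(yy.begin(), yy.end()), x(xx.begin(), xx.end()), cur(0) {}
  double at(double q) {
    if (q < y.front() - TEPS || q > y.back() + TEPS)
      stop("row outside course extent: generate the course long enough for the trial");
    if (cur > y.size() - 2) cur = y.size() - 2;
    while (cur > 0 && q < y[cur]) --cur;
    while (cur < y.size() - 2 && q > y[cur + 1]) ++cur;
    double f = (q - y[cur]) / (y[cur + 1] - y[cur]);
    return x[cur] + f * (x[cur + 1] - x[cur]);
  }
};

struct Trace {
  std::vector<double> time, value, vx;
  std::vector<int> ev, detail;
  bool on;
  void add(double t, int e, int d, double v, double veh) {
    if (!on) return;
    time.push_back(t); ev.push_back(e); detail.push_back(d);
    value.push_back(v); vx.push_back(veh);
  }
};

// [[Rcpp::export]]
List run_trial_engine(NumericVector line_y, NumericVector line_x,
                      NumericVector goal_y, NumericVector goal_x,
                      List cfg) {
  // --- configuration ------------------------------------------------
  const double ca = as<double>(cfg["ca"]);
  const double cm = as<double>(cfg["cm"]);
  const double scroll = as<double>(cfg["scroll_speed"]);
  const double frame_dt = as<double>(cfg["frame_dt"]);
  const double rate = as<double>(cfg["command_rate"]);
  const double duration = as<double>(cfg["trial_duration"]);
  const double radius = as<double>(cfg["vehicle_radius"]);
  const double lwidth = as<double>(cfg["line_width"]);
  const double screen_w = as<double>(cfg["screen_width"]);
  const double row0 = as<double>(cfg["vehicle_row"]);
  int mode = as<int>(cfg["initial_mode"]);        // 0 manual, 1 auto
  const int agent = as<int>(cfg["agent"]);        // 0 scripted, 1 model
  const int held_init = as<int>(cfg["held_init"]); // 0 none, 1 left, 2 right
  const bool smdp = as<bool>(cfg["smdp"]);
  const bool gating = as<bool>(cfg["gating"]);
  const bool allow_to_auto = as<bool>(cfg["allow_to_auto"]);
  const double alpha = as<double>(cfg["alpha"]);
  const double egs = as<double>(cfg["egs"]);
  const double u0 = as<double>(cfg["initial_utility"]);
  const double reward_on = as<double>(cfg["reward_online"]);
  const double reward_off = as<double>(cfg["reward_offline"]);
  const double max_speed = as<double>(cfg["max_vehicle_speed"]);
  const double firing = as<double>(cfg["firing_time"]);
  const double prep = as<double>(cfg["prep_time"]);
  const double exec = as<double>(cfg["exec_time"]);
  const double tol = as<double>(cfg["align_tol"]);
  const bool goal_nearest_abs = as<bool>(cfg["goal_nearest_abs"]);
  const double online_margin = radius + lwidth / 2.0;

  Interp line(line_y, line_x), optline(goal_y, goal_x);
  const std::vector<double> gy(goal_y.begin(), goal_y.end());
  const std::vector<double> gx(goal_x.begin(), goal_x.end());

  Trace tr; tr.on = as<bool>(cfg["trace"]);
  std::vector<double> ulog_t; std::vector<double> ulog_u; // utilities at rewards

  // --- state --------------------------------------------------------
  double vehicle_x = line.at(row0);
  const double start_x = vehicle_x;
  bool held_l = (held_init == 1), held_r = (held_init == 2);
  bool intent_l = held_l, intent_r = held_r;
  int switch_count = 0;
  long frames_on = 0, frames_total = 0;
  double auto_time = 0.0, mode_since = 0.0;
  bool on_line = std::fabs(vehicle_x - line.at(row0)) <= online_margin + TEPS;

  double U[N_RULES];
  bool fired[N_RULES];
  for (int i = 0; i < N_RULES; ++i) { U[i] = u0; fired[i] = false; }
  double last_reward_t = 0.0, vposi_prev = vehicle_x;
  double perc_vx = NA_REAL, perc_gx = NA_REAL;
  size_t gcur = 0;

  Phase phase = P_VEHICLE;
  int rule_in_flight = -1;
  double effect_time = R_PosInf;

  std::vector<int> mqueue; size_t mhead = 0;
  bool motor_busy = false; double motor_until = R_PosInf;
  int cur_op = OP_NONE, last_move = OP_NONE;

  const long n_ticks = lround(duration * rate);
  const long n_frames = lround(duration / frame_dt);
  long tick_i = 1, frame_i = 1;

  // --- helpers ------------------------------------------------------
  auto motor_try_start = [&](double t) {
    if (motor_busy || mhead >= mqueue.size()) return;
    cur_op = mqueue[mhead];
    double p = (cur_op == last_move) ? 0.0 : prep;
    motor_until = t + p + exec;
    last_move = cur_op;
    motor_busy = true;
  };
  auto enqueue = [&](int op, double t) {
    mqueue.push_back(op);
    motor_try_start(t);
  };

  auto select_among = [&](const std::vector<int>& el) -> int {
    if (el.size() == 1) return el[0];
    if (egs == 0.0) {
      double mx = U[el[0]];
      for (size_t i = 1; i < el.size(); ++i) if (U[el[i]] > mx) mx = U[el[i]];
      std::vector<int> tied;
      for (size_t i = 0; i < el.size(); ++i) if (U[el[i]] == mx) tied.push_back(el[i]);
      if (tied.size() == 1) return tied[0];
      double u = unif_rand();
      size_t k = (size_t)(u * tied.size());
      if (k >= tied.size()) k = tied.size() - 1;
      return tied[k];
    }
    double best = R_NegInf; int sel = el[0];
    for (size_t i = 0; i < el.size(); ++i) {
      double u = unif_rand();
      double v = U[el[i]] + egs * std::log(u / (1.0 - u));
      if (v > best) { best = v; sel = el[i]; }
    }
    return sel;
  };

  auto maybe_select = [&](double t) {
    if (agent != 1 || rule_in_flight >= 0) return;
    std::vector<int> el;
    switch (phase) {
    case P_VEHICLE: el.push_back(R_FINDVEH); break;
    case P_GOAL:    el.push_back(R_FINDGOAL); break;
    case P_MOTOR:
      if (mode == 1) {
        el.push_back(R_KEEPA);
        if (!gating || U[R_KEEPM] >= U[R_KEEPA]) el.push_back(R_TOMANUAL);
      } else {
        // exactly one of the five manual rules matches a given
        // (goal side x current command) situation; it competes with ToAuto
        bool goal_left = perc_gx < perc_vx - tol;
        bool goal_right = perc_gx > perc_vx + tol;
        int situ;
        if (intent_l) situ = goal_left ? R_KEEPM : R_LTOS;
        else if (intent_r) situ = goal_right ? R_KEEPM : R_RTOS;
        else situ = goal_left ? R_TOLEFT : (goal_right ? R_TORIGHT : R_KEEPM);
        el.push_back(situ);
        if (allow_to_auto && (!gating || U[R_KEEPM] <= U[R_KEEPA]))
          el.push_back(R_TOAUTO);
      }
      break;
    case P_SWITCH:
      if (!motor_busy && mhead >= mqueue.size()) el.push_back(R_PRESSSPACE);
      break;
    case P_WAIT: break;
    }
    if (el.empty()) return;       // engine idles until the next change
    rule_in_flight = select_among(el);
    effect_time = t + firing;
  };

  auto apply_reward_now = [&](double t, double R) {
    for (int i = 0; i < N_RULES; ++i) {
      if (fired[i]) { U[i] += alpha * (R - U[i]); fired[i] = false; }
    }
    last_reward_t = t;
    tr.add(t, EV_REWARD, -1, R, vehicle_x);
    if (tr.on) {
      ulog_t.push_back(t);
      for (int i = 0; i < N_RULES; ++i) ulog_u.push_back(U[i]);
    }
  };

  auto rule_effect = [&](double t) {
    int r = rule_in_flight;
    rule_in_flight = -1; effect_time = R_PosInf;
    fired[r] = true;
    tr.add(t, EV_FIRE, r, NA_REAL, vehicle_x);
    switch (r) {
    case R_FINDVEH: {
      perc_vx = vehicle_x;
      double R;
      if (on_line) R = smdp ? max_speed * (t - last_reward_t) : reward_on;
      else R = smdp ? std::fabs(perc_vx - vposi_prev) : reward_off;
      apply_reward_now(t, R);
      vposi_prev = perc_vx;
      phase = P_GOAL;
      break;
    }
    case R_FINDGOAL: {
      double row = row0 + scroll * t;
      while (gcur < gy.size() && gy[gcur] <= row + TEPS) ++gcur;
      if (gcur >= gy.size())
        stop("no goal ahead of the vehicle row: course exhausted");
      if (goal_nearest_abs && gcur > 0 &&
          row - gy[gcur - 1] < gy[gcur] - row)
        perc_gx = gx[gcur - 1];
      else
        perc_gx = gx[gcur];
      phase = P_MOTOR;
      break;
    }
    case R_KEEPA:
    case R_KEEPM:
      perc_vx = NA_REAL; perc_gx = NA_REAL; phase = P_VEHICLE;
      break;
    case R_TOLEFT:
      enqueue(OP_PRESS_L, t); intent_l = true;
      perc_vx = NA_REAL; perc_gx = NA_REAL; phase = P_VEHICLE;
      break;
    case R_TORIGHT:
      enqueue(OP_PRESS_R, t); intent_r = true;
      perc_vx = NA_REAL; perc_gx = NA_REAL; phase = P_VEHICLE;
      break;
    case R_LTOS:
      enqueue(OP_REL_L, t); intent_l = false;
      perc_vx = NA_REAL; perc_gx = NA_REAL; phase = P_VEHICLE;
      break;
    case R_RTOS:
      enqueue(OP_REL_R, t); intent_r = false;
      perc_vx = NA_REAL; perc_gx = NA_REAL; phase = P_VEHICLE;
      break;
    case R_TOAUTO:
    case R_TOMANUAL:
      if (intent_l) { enqueue(OP_REL_L, t); intent_l = false; }
      if (intent_r) { enqueue(OP_REL_R, t); intent_r = false; }
      phase = P_SWITCH;
      break;
    case R_PRESSSPACE:
      enqueue(OP_SPACE, t);
      phase = P_WAIT;
      break;
    }
  };

  auto motor_complete = [&](double t) {
    int op = cur_op;
    motor_busy = false; motor_until = R_PosInf;
    ++mhead;
    switch (op) {
    case OP_PRESS_L: held_l = true; break;
    case OP_PRESS_R: held_r = true; break;
    case OP_REL_L:   held_l = false; break;
    case OP_REL_R:   held_r = false; break;
    case OP_SPACE:
      if (mode == 1) auto_time += t - mode_since;
      mode = 1 - mode; mode_since = t;
      ++switch_count;
      held_l = held_r = intent_l = intent_r = false;
      if (agent == 1) { perc_vx = NA_REAL; perc_gx = NA_REAL; phase = P_VEHICLE; }
      tr.add(t, EV_TOGGLE, -1, (double)mode, vehicle_x);
      break;
    }
    tr.add(t, EV_MOTOR, op, NA_REAL, vehicle_x);
    motor_try_start(t);
  };

  auto do_tick = [&](double t) {
    int cmd = 0; // -1 left, +1 right
    if (mode == 1) {
      double opt = optline.at(row0 + scroll * t);
      if (vehicle_x < opt - 0.5) cmd = 1;
      else if (vehicle_x > opt + 0.5) cmd = -1;
    } else {
      if (held_l) cmd = -1; else if (held_r) cmd = 1;
    }
    if (cmd != 0) {
      double u = unif_rand();
      double p = (mode == 1) ? ca : cm;
      if (u < p) {
        vehicle_x += cmd;
        if (vehicle_x < 0) vehicle_x = 0;
        if (vehicle_x > screen_w) vehicle_x = screen_w;
      }
    }
  };

  auto do_frame = [&](double t) {
    double row = row0 + scroll * t;
    on_line = std::fabs(vehicle_x - line.at(row)) <= online_margin + TEPS;
    ++frames_total;
    if (on_line) ++frames_on;
    tr.add(t, EV_FRAME, -1, on_line ? 1.0 : 0.0, vehicle_x);
  };

  // --- main loop ----------------------------------------------------
  maybe_select(0.0);
  while (true) {
    double tt = (tick_i <= n_ticks) ? (double)tick_i / rate : R_PosInf;
    double tf = (frame_i <= n_frames) ? (double)frame_i * frame_dt : R_PosInf;
    double tm = motor_busy ? motor_until : R_PosInf;
    double te = (rule_in_flight >= 0) ? effect_time : R_PosInf;
    double tmin = std::min(std::min(tt, tf), std::min(tm, te));
    if (!R_finite(tmin) || tmin > duration + TEPS) break;
    double tcur;
    if (tt <= tmin + TEPS) { tcur = tt; do_tick(tt); ++tick_i; }
    else if (tf <= tmin + TEPS) { tcur = tf; do_frame(tf); ++frame_i; }
    else if (tm <= tmin + TEPS) { tcur = tm; motor_complete(tm); }
    else { tcur = te; rule_effect(te); }
    maybe_select(tcur);
  }
  if (mode == 1) auto_time += duration - mode_since;

  // --- results ------------------------------------------------------
  NumericVector util(N_RULES);
  for (int i = 0; i < N_RULES; ++i) util[i] = U[i];
  util.names() = CharacterVector(RULE_NM, RULE_NM + N_RULES);

  List out = List::create(
    _["performance"] = frames_total > 0 ? (double)frames_on / frames_total : NA_REAL,
    _["auto_use_ratio"] = auto_time / duration,
    _["n_switches"] = switch_count,
    _["frames_on_line"] = (double)frames_on,
    _["frames_total"] = (double)frames_total,
    _["scrolled"] = (double)n_ticks * scroll / rate,
    _["vehicle_x"] = vehicle_x,
    _["displacement"] = vehicle_x - start_x,
    _["utilities"] = util);

  if (tr.on) {
    CharacterVector evs(tr.ev.size()), det(tr.ev.size());
    for (size_t i = 0; i < tr.ev.size(); ++i) {
      evs[i] = EV_NM[tr.ev[i]];
      int d = tr.detail[i];
      if (tr.ev[i] == EV_FIRE) det[i] = RULE_NM[d];
      else if (tr.ev[i] == EV_MOTOR) det[i] = OP_NM[d];
      else det[i] = NA_STRING;
    }
    out["trace"] = DataFrame::create(
      _["time"] = wrap(tr.time), _["event"] = evs, _["detail"] = det,
      _["value"] = wrap(tr.value), _["vehicle_x"] = wrap(tr.vx),
      _["stringsAsFactors"] = false);
    size_t nr = ulog_t.size();
    NumericMatrix um(nr, N_RULES);
    for (size_t i = 0; i < nr; ++i)
      for (int j = 0; j < N_RULES; ++j) um(i, j) = ulog_u[i * N_RULES + j];
    colnames(um) = CharacterVector(RULE_NM, RULE_NM + N_RULES);
    out["utility_log"] = List::create(_["time"] = wrap(ulog_t),
                                      _["utilities"] = um);
  }
  return out;
}
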