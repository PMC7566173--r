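# Production-system machinery: noisy-utility conflict resolution,
# reward-triggered utility learning, motor latencies, and subjective
# duration estimation.  These are the reference (R-level) semantics; the
# compiled event engine applies the identical rules inside a trial.

#' Conflict-resolution parameters
#'
#' Selection among eligible rules is a noisy max: independent logistic
#' noise of scale `s` (ACT-R's `egs`) is added to each utility and the
#' argmax fires.  With `s = 0` this is a strict argmax with a uniform
#' random tie-break among the maxima.  The selection probabilities are
#' approximated by a Boltzmann softmax with temperature `sqrt(2) * s`.
#'
#' @param s utility noise scale, `>= 0`.
#' @return a list of class `lf_conflict_params`.
#' @export
conflict_params <- function(s = 0) {
  stopifnot(s >= 0)
  structure(list(s = s), class = "lf_conflict_params")
}

#' Utility-learning parameters
#'
#' Each reward event updates every production that has fired since the
#' previous reward by the delta rule `U <- U + alpha * (R - U)` (the
#' Q-learning form).  `time_discount_in_propagation` optionally subtracts
#' the time elapsed between a production's firing and the reward from the
#' propagated reward (ACT-R's official variant); the default is the plain
#' delta rule.
#'
#' @param alpha learning rate in `(0, 1]`.
#' @param initial_utility starting utility for every rule.
#' @param time_discount_in_propagation logical; see above.
#' @return a list of class `lf_learning_params`.
#' @export
learning_params <- function(alpha = 0.2, initial_utility = 5,
                            time_discount_in_propagation = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, is.finite(initial_utility))
  structure(list(alpha = alpha, initial_utility = initial_utility,
                 time_discount_in_propagation = time_discount_in_propagation),
            class = "lf_learning_params")
}

#' Motor-module timing parameters
#'
#' A key press, key release or space punch costs a feature-preparation
#' time (skipped when the movement repeats the previous one) plus an
#' execution time; requests to a busy module queue.  Every rule firing
#' takes `firing_time`.  The defaults mimic ACT-R 6 punch-style timings.
#'
#' @param prep_time movement preparation time (s).
#' @param exec_time execution time per press/release (s).
#' @param firing_time production firing time (s).
#' @return a list of class `lf_motor_params`.
#' @export
motor_params <- function(prep_time = 0.050, exec_time = 0.100,
                         firing_time = 0.050) {
  stopifnot(prep_time >= 0, exec_time >= 0, firing_time >= 0)
  structure(list(prep_time = prep_time, exec_time = exec_time,
                 firing_time = firing_time), class = "lf_motor_params")
}

#' Temporal-module parameters
#'
#' Subjective duration is either the exact elapsed time (`noiseless`,
#' the default, which keeps semi-Markov rewards reproducible) or the sum
#' of ACT-R-style ticks whose lengths grow geometrically
#' (`start_tick * multiplier^k`), each optionally perturbed by logistic
#' noise of scale `noise_b * multiplier * tick`.
#'
#' @param start_tick first tick length (s), `> 0`.
#' @param multiplier per-tick growth factor, `>= 1`.
#' @param noise_b tick noise scale.
#' @param noiseless logical; exact elapsed time when `TRUE`.
#' @return a list of class `lf_temporal_params`.
#' @export
temporal_params <- function(start_tick = 0.011, multiplier = 1.1,
                            noise_b = 0.015, noiseless = TRUE) {
  stopifnot(start_tick > 0, multiplier >= 1, noise_b >= 0)
  structure(list(start_tick = start_tick, multiplier = multiplier,
                 noise_b = noise_b, noiseless = noiseless),
            class = "lf_temporal_params")
}

#' Select one production among the eligible set
#'
#' Implements noisy-utility conflict resolution.  With `s = 0` the rule
#' with the highest utility fires, ties broken uniformly at random (one
#' uniform draw).  With `s > 0` each eligible utility receives independent
#' logistic noise of scale `s` (one uniform draw per eligible rule, in
#' order) and the argmax fires.
#'
#' @param utilities numeric vector of utilities of the eligible rules.
#' @param s noise scale (`egs`).
#' @return the index of the selected rule within `utilities`.
#' @export
select_production <- function(utilities, s = 0) {
  stopifnot(length(utilities) >= 1, all(is.finite(utilities)), s >= 0)
  if (length(utilities) == 1L) return(1L)
  if (s == 0) {
    mx <- max(utilities)
    tied <- which(utilities == mx)
    if (length(tied) == 1L) return(tied)
    u <- runif(1)
    return(tied[min(floor(u * length(tied)) + 1, length(tied))])
  }
  u <- runif(length(utilities))
  noisy <- utilities + s * log(u / (1 - u))
  which.max(noisy)
}

#' Closed-form selection probabilities of the noisy max
#'
#' Exact `P(rule i fires)` under independent logistic noise of scale `s`,
#' evaluated by numerical integration; for two alternatives this is close
#' to (but not identical with) the softmax with temperature
#' `sqrt(2) * s`, which [softmax_probs()] returns.
#'
#' @param utilities numeric utilities.
#' @param s noise scale, `> 0`.
#' @return vector of selection probabilities summing to 1.
#' @export
selection_probs <- function(utilities, s) {
  stopifnot(s > 0)
  n <- length(utilities)
  vapply(seq_len(n), function(i) {
    stats::integrate(function(x) {
      dens <- stats::dlogis(x, utilities[i], s)
      for (j in seq_len(n)[-i])
        dens <- dens * stats::plogis(x, utilities[j], s)
      dens
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' Softmax approximation to the selection probabilities
#'
#' `exp(U_i / (sqrt(2) s)) / sum_j exp(U_j / (sqrt(2) s))`, the standard
#' closed form used to describe noisy-utility conflict resolution.
#'
#' @inheritParams selection_probs
#' @export
softmax_probs <- function(utilities, s) {
  stopifnot(s > 0)
  z <- utilities / (sqrt(2) * s)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Apply a reward to the productions fired since the last reward
#'
#' Every production named in `fired` is updated once:
#' `U <- U + alpha * (R - U)`.  With
#' `time_discount_in_propagation = TRUE` the propagated reward for a
#' production is reduced by the time between its firing and the reward.
#'
#' @param utilities named numeric vector of rule utilities.
#' @param fired character vector of rule names fired since the previous
#'   reward (duplicates are collapsed).
#' @param reward the reward value R.
#' @param params a [learning_params()].
#' @param reward_time,fired_times optional times (s) used only by the
#'   time-discount variant; `fired_times` must be named like `fired`.
#' @return the updated utility vector.
#' @export
apply_reward <- function(utilities, fired, reward, params = learning_params(),
                         reward_time = NULL, fired_times = NULL) {
  stopifnot(is.finite(reward))
  fired <- unique(fired)
  if (!all(fired %in% names(utilities)))
    stop("unknown production(s): ",
         paste(setdiff(fired, names(utilities)), collapse = ", "))
  for (f in fired) {
    r <- reward
    if (isTRUE(params$time_discount_in_propagation)) {
      if (is.null(reward_time) || is.null(fired_times))
        stop("time discount requires reward_time and fired_times")
      r <- reward - (reward_time - fired_times[[f]])
    }
    utilities[[f]] <- utilities[[f]] + params$alpha * (r - utilities[[f]])
  }
  utilities
}

#' Closed-form utility after n identical rewards
#'
#' `U_n = R + (1 - alpha)^n (U_0 - R)`, the fixed-point form of the delta
#' rule iterated n times with the same reward.
#'
#' @param u0 initial utility.
#' @param reward the repeated reward R.
#' @param alpha learning rate.
#' @param n number of reward events.
#' @export
utility_after_n_rewards <- function(u0, reward, alpha, n) {
  reward + (1 - alpha)^n * (u0 - reward)
}

#' Subjective duration estimate
#'
#' In noiseless mode the true elapsed time is returned.  In tick mode the
#' temporal module accumulates ticks of geometrically growing length and
#' returns the sum of the realized tick lengths that fit wholly within
#' the elapsed interval.
#'
#' @param elapsed true elapsed time since the timer started (s), `>= 0`.
#' @param params a [temporal_params()].
#' @return estimated duration (s).
#' @export
estimate_duration <- function(elapsed, params = temporal_params()) {
  if (is.null(elapsed) || is.na(elapsed))
    stop("timer never started: elapsed time is unknown")
  if (elapsed < 0) stop("elapsed time must be >= 0")
  if (params$noiseless) return(elapsed)
  total <- 0
  tick <- params$start_tick
  repeat {
    len <- tick
    if (params$noise_b > 0)
      len <- len + stats::rlogis(1, 0, params$noise_b * params$multiplier * tick)
    len <- max(len, 0)
    if (total + len > elapsed) break
    total <- total + len
    tick <- tick * params$multiplier
  }
  total
}
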