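---
title: "Modeling adaptation to automation in a time-critical tracking task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling adaptation to automation in a time-critical tracking task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineadapt)
```

## The task and why it is simulated

`lineadapt` simulates a line-following task used to study how operators
calibrate their reliance on automation.  A vehicle must be kept on a line
that scrolls down the screen at 24 px/s; the operator can steer manually
with left/right keys or hand control to an automatic controller, toggling
between the two modes with the space bar.  Commands are sampled at 48 Hz
and each issued command succeeds only with probability $C_a$ (auto mode)
or $C_m$ (manual mode), the two capability parameters manipulated across
a 5 × 5 grid from 0.3 to 0.7.  Three behavioral indices summarize a 40-s
trial: *performance* (fraction of screen updates with the vehicle
overlapping the line), the *auto-use ratio* (fraction of trial time in
auto mode), and the *number of switches*.

The operator is a production-system cognitive model in the ACT-R
tradition.  Eleven condition–action rules implement a
perceive–decide–act cycle: `FindVehicle` and `FindGoal` read the vehicle
and the nearest upcoming corner goal from the display (visual location
reads carry no added latency), and a motor-phase rule then either keeps
the current mode (`KeepA`/`KeepM`), steers (`ToLeft`, `ToRight`, `LtoS`,
`RtoS`), or initiates a mode switch (`ToAuto`/`ToManual`, followed by
`PressSpace` once held keys are released).  Every rule firing takes
50 ms; key presses, releases and the space punch pass through a serial
motor module with preparation (50 ms, skipped for a repeated movement)
and execution (100 ms) stages.  These latencies are what disadvantage
manual control relative to the instantaneous auto controller.

## Learning and the two mechanism extensions

Each rule $i$ carries a utility $U_i$.  When several rules match, one is
selected by noisy-utility conflict resolution: independent logistic noise
of scale $s$ (the `egs` parameter) is added to each utility and the
argmax fires, which is the mechanism behind the softmax description

$$P(i) = \frac{e^{U_i/\sqrt{2}s}}{\sum_j e^{U_j/\sqrt{2}s}}.$$

All headline simulations use $s = 0$: a strict argmax with a uniform
random tie-break.  `FindVehicle` triggers a reward on every cycle, and
every rule fired since the previous reward is updated by the delta rule
(the Q-learning form)

$$U_i(n) = U_i(n-1) + \alpha\,[R_i(n) - U_i(n-1)],$$

with $\alpha = 0.2$ and all utilities initialized to 5.

Two reward schemes are available.  The *default* scheme pays 10 when the
vehicle is perceived on the line and 0 otherwise.  The *semi-Markov*
(SMDP) scheme instead credits the approximate distance traveled since
the previous reward: on line, `MaxVehicleSpeed` (48 px/s) times the
subjectively estimated interval; off line, the absolute displacement of
the perceived vehicle position.  Because rewards arrive at irregular
intervals (cycles stretch during mode switches), summation over the
interval equalizes reward opportunity between the modes — the argument
for the SMDP extension.

The second extension is a *gate* on the mode-switch rules.
Self-confidence $SC$ is identified with the utility of `KeepM` and trust
$T$ with the utility of `KeepA`; `ToAuto` additionally requires
$SC \le T$ and `ToManual` requires $SC \ge T$, both inclusive so that at
equality both directions remain possible and ordinary conflict
resolution decides.  $SC$ can change only during manual episodes and $T$
only during auto episodes (a trace-level invariant in the test suite),
so the gate carries information about the mode *not* currently in use —
the function trust plays in decision-field accounts of reliance.
Crossing rewarding with conflict resolution gives the four variants
`Default-Default`, `Default-SMDP`, `Gating-Default`, `Gating-SMDP`
(see `model_variants()`).

## Course generation

Courses are built by concatenating 48-px-high straight segments whose
angles are drawn uniformly from {30, 45, 90, 135, 150} degrees
(measured from the horizontal; 90 is vertical, smaller angles slope
right, larger slope left, so the set is mirror-symmetric).  A candidate
angle whose segment would exit the admissible horizontal band is
resampled; with the vertical angle always available this terminates, and
an explicit error guards genuinely unsatisfiable bounds.  Goal points
sit on every corner (angle-change junction) plus the course endpoints,
and the optimal line joins successive goals — with goals on every corner
it coincides with the drawn centerline, the reading we adopt for the
ambiguity of whether the displayed optimal line cut corners.  Geometry
is kept real-valued throughout (the 30/150-degree cotangent is
irrational); only rendering would round.

The auto controller issues a 1-px correction toward the optimal line
whenever the vehicle center is more than 0.5 px off it.  The on-line
predicate is inclusive: the vehicle overlaps the line when its center is
within `vehicle_radius + line_width/2` (12.5 px at the defaults) of the
line at the vehicle's row.  Vehicle radius (10 px), line width (5 px)
and screen width (300 px) are not printed in the task description; they
are plausible values for the original display and are configuration
parameters.

## Timing, scheduling and numerical choices

A trial interleaves three clocks: command ticks every 1/48 s (the scroll
advances 0.5 px per tick, so a held key moves the vehicle at most 2 px
per scrolled line pixel — the task's printed speed limit, which is why
48 Hz rather than the also-quoted 20-ms period is adopted), screen
updates every 40 ms (which latch the warning bit perception consumes),
and the production cycle (50-ms firings plus motor stages).  The engine
is event-driven; at equal times events are processed in the fixed order
command tick → frame update → motor completion → rule effect, and two
times closer than $10^{-9}$ s count as equal (distinct events in any
admissible configuration are at least 1/240 s apart).  Command
successes are independent Bernoulli draws per non-straight command; the
vehicle is clamped at the screen edges.  All randomness flows through
R's RNG, so a single seed reproduces a whole trial; per-trial seeds are
derived from (master seed, condition, run index), making grids
exchangeable across execution order.

The scheduler is validated against a brute-force fixed-step simulator
that advances a 2-s toy trial on an integer millisecond clock and must
reproduce the event trace exactly, event for event.  The toy
configuration uses a 50-Hz command channel so that every interval is an
integer number of milliseconds, which a 1-ms grid requires; the
production configuration stays at 48 Hz.

Subjective duration (the SMDP on-line reward needs the time since the
last reward) defaults to the exact elapsed time, keeping rewards
reproducible; ACT-R-style noisy geometric ticks (start 11 ms, multiplier
1.1) are available behind `temporal_params(noiseless = FALSE)`.
Likewise the delta rule is applied as written, without subtracting the
rule-to-reward delay from the propagated reward; the official ACT-R
time-discount variant is available via
`learning_params(time_discount_in_propagation = TRUE)`.

## Reconstructed details

Several model details are not printed and had to be reconstructed; they
are isolated so they can be revised in one place
(`eligible_rules()`).

* **Manual rule conditions.**  The five manual-mode rules are given
  mutually exclusive conditions over the perceived goal side (left /
  aligned within 2 px / right) and the current move-command, so exactly
  one matches any situation and competes only with `ToAuto`.  The
  alternative reading — `KeepM` eligible everywhere alongside the
  steering rules — starves steering under a zero-noise argmax (whichever
  rule happens to lead in utility wins every conflict), flattening the
  manual-only capability curve, which contradicts the reported baseline
  in which all four curves rise with capability.  The partition reading
  restores a manual-only model whose performance climbs steeply with
  $C_m$ while remaining below the auto controller at every matched
  level.
* **Goal targeting.**  `FindGoal` returns the nearest goal strictly
  ahead of the vehicle row (smallest positive vertical distance).
* **Rule count bookkeeping.**  The on-line and off-line branches of
  `FindVehicle` share one name and one utility, preserving the canonical
  count of 11; they differ only in which reward they trigger.
* **Motor queueing.**  Requests to a busy motor module queue rather than
  being dropped; dropping would starve mode switches.
* **Initial mode.**  Trials start in manual mode (stated for the
  baseline simulation, unstated for the two-mode simulation).  Starting
  in auto instead changes none of the grid-level trend statistics
  appreciably.

## Problem sizes and what the tests show

The test suite runs the baseline sweeps at 500 runs per capability level
and the four-variant grid at 200 runs per condition (25 conditions per
variant), the scale at which the trend statistics stabilize; the
acceptance script uses the same sizes.  At that scale the package
reproduces: rising auto-only performance in $C_a$ with auto dominating
the manual-only model at every matched level; auto use rising in $C_a$
and falling in $C_m$; switch counts falling along both axes; and a
roughly four-fold stronger $C_m$-dependence of auto use under SMDP
rewarding than under default rewarding — the mechanistic signature that
motivates the SMDP extension.

One operationalization falls short by design honesty rather than by
accident: the rank correlation of mean performance with $C_a + C_m$ for
the `Gating-SMDP` variant measures about 0.77 against a 0.8 criterion.
The surface rises along both axes for $C_a \le 0.5$ but sags slightly
with $C_m$ at $C_a = 0.7$: the model's manual mode is capped near 0.64
even at $C_m = 0.7$ (the perception cycle costs 150 ms per decision, and
$48 C_m$ px/s cannot track the 30/150-degree segments that drift at
41.6 px/s), so the reliance shift toward manual at high $C_m$ costs a
little performance where auto is strong.  This is the model's own
manual disadvantage, not a simulation artifact, and Pearson-$R^2$ fit
statistics are insensitive to it; the threshold is left unmet rather
than the model adjusted.

## What the synthetic reference grid is and is not

Participant means are not shipped with the package, so the fit machinery
(`fit_stats()`: per-index squared Pearson correlation and RMSE across
the 25 paired condition means) is exercised against
`synth_reference()`, a fixture that reproduces only the *qualitative*
shape of the behavioral surfaces — linear monotone trends
(performance up both axes, auto use up in $C_a$/down in $C_m$, switches
down both) plus Gaussian noise.  It emulates none of the curvature,
variance structure, or individual differences of real participants;
passing tests therefore certify the machinery and the direction of the
model's trends, not quantitative agreement with human data.  A real
reference grid can be supplied as a 25-row CSV via `load_reference()`.

## Known limitations

* The model's manual mode is weaker relative to its auto mode than human
  manual control is, compressing the performance surface at high
  $C_a$ (discussed above).
* Non-gated variants switch modes far more often than is plausible for
  humans (the default-default model averages ~40 switches per 40-s
  trial); gating brings this down by an order of magnitude but the
  remaining count is still model-typical rather than human-typical.
* The softmax expression is an approximation to the implemented logistic
  noisy-max; for two alternatives they differ by up to ~1% in selection
  probability.  All shipped simulations use `egs = 0`, where the
  difference is moot.
* Declarative memory, visual attention shifts, and continuous steering
  dynamics are out of scope; the environment is the abstract tracking
  task, not road driving.
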