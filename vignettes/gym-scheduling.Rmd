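---
title: "Scheduling patients across robots in a rehabilitation gym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scheduling patients across robots in a rehabilitation gym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabgym)
```

## The problem

A robotic rehabilitation gym has `M` patients sharing `N` training robots
over a session of `G` discrete time steps. Each robot trains exactly one
motor skill, and each (patient, robot) pair has its own learning curve.
Moving off a robot costs that robot's *exit time*: a number of idle steps
before either the patient or the vacated robot can start a new training
block. The scheduling question is which patient should be on which robot
when, so that the group as a whole gains as much skill as possible within
the session.

`rehabgym` models this gym, provides the two naive schedules a therapist
might use by hand, and searches for better ones.

## The skill model

Skill on one robot follows a modified hyperbola in cumulative training
time. With parameters `c1` (ceiling), `c2` (shape offset), `c3` (shape
divisor), `c4` (advance rate) and `u` (prior-training term), skill after
`d` steps is

$$v(d) = \frac{c_1\,(c_2 + c_4 (d + u))}{c_2 + c_4 (d + u) + c_3},$$

and the session *gain* is `v(d) - v(0)`. The curve has strictly
diminishing marginal returns for `c4 > 0`: the first step on a fresh robot
is always worth more than the tenth on a robot the patient has been using
all session. That concavity is what makes switching robots worthwhile, and
it is the single mechanism every result in this package rests on.

```{r}
crv <- skill_curve()        # c1=100, c2=1, c3=10, c4=1, u=1
skill_gain(crv, c(1, 4, 7, 12))
marginal_gain(crv, 1:5)     # strictly decreasing
```

Durations are integers only; fractional steps are rejected. A step can
represent any fixed real duration (5 minutes, 10 minutes), which is why the
package never attaches a unit to it. `c2 = 0` and `c4 = 0` are legal
(`c4 = 0` gives a flat curve) so degenerate fixtures can be built; the
random-group generator, not the curve type, enforces the study ranges.
`u` is treated as an opaque calibration constant (its default 1 means "no
previous sessions"); the package does not model carryover between sessions.

## Schedules and feasibility

A schedule is a set of blocks `(patient, robot, start, end)` with 1-based
inclusive step intervals. Feasibility requires: intervals inside `[1, G]`,
no start after the last-start step `H` (the study keeps `H = G`), at most
one block per (patient, robot) pair, no two blocks sharing a robot or a
patient overlapping, and the exit gap: a successor on the same robot, or
the same patient's next block, may start no earlier than
`end + exit_time + 1`.

The `+ 1` deserves a note. Written with inclusive ends, a gap condition of
`next_start >= end + exit` would allow two blocks to share a step when the
exit time is zero. The package therefore uses `end + exit + 1`, which
forbids same-step overlap at zero exit time and, with a 1-step exit time
and a 12-step session, forces exactly the 6 + 5 "switch halfway" split
whose total the equal-curve results table prints. The worked results pin
this semantics down; `check_disjunctive()` documents it on the raw
inequality level.

Two checkable variable encodings of the same feasible set are provided:
time-indexed (`encode_time_indexed()`: a Boolean start indicator per
(robot, patient, step) plus an integer duration per pair) and disjunctive
(`encode_disjunctive()`: integer start/end per pair, activation Booleans,
and precedence Booleans deactivated through a big multiplier
`V = G + max(exit) + 1`, the smallest value that clears a disjunct over
the variable ranges). Both objectives agree with `total_gain()` because
gain depends only on duration, `1 + end - start` either way. The test
suite checks on randomized instances that the two checkers accept exactly
the same block sets as the interval validator.

## Baseline schedules

* **Best robot only** (`best_robot_schedule()`): every patient keeps one
  robot for the whole session. Robots are handed out greedily by
  full-session gain; when two patients want the same robot, the one who
  would gain more wins and the loser takes their next-best free robot.
  Ties break by patient then robot index, making the output deterministic.
* **Switch halfway** (`switch_halfway_schedule()`): one robot for the
  first half, a second for the rest. For a first robot with exit time `e`
  the split is `d1 = ceiling((G - e) / 2)` then `d2 = G - e - d1`, longer
  segment first — the split that reproduces the printed 4+3, 6+6 and 6+5
  layouts. Robot choice is the same greedy pass applied per half, ranking
  each candidate robot by its gain over the half actually on offer (not
  the full session); the alternative full-session ranking differs only
  for strongly asymmetric curves. Plain greedy can strand a patient in a
  fully symmetric group (earlier patients pair up in 2-cycles); the
  assignment is completed by deterministic augmenting paths, accepted
  only when they increase the second-half gain. A patient with no
  second-half option keeps their first robot for the whole session when
  nobody else claims it.

## The optimizer

Commercial branch-and-reduce solvers are deliberately not used; the
instances are tiny integer programs and reproducibility matters more than
generality here. `optimize_schedule()` is a deterministic, seeded anytime
search:

1. **Incumbent seeding.** The better of the two baselines is the starting
   incumbent, so the result can never fall below either baseline at any
   budget (budget 0 returns that baseline).
2. **Exact best-response insertion.** The workhorse is an exact dynamic
   program for a *single* patient against a fixed background: over robot
   subsets and the free windows of each robot's timeline, choose visiting
   order, starts and durations optimally. Within a window only the
   earliest admissible start needs to be considered, since gains depend on
   duration alone. The construction phase inserts patients one at a time
   under several orders; ties in the DP are broken by a robot preference
   order staggered cyclically per patient, which steers symmetric groups
   into rotation patterns instead of mutually blocking choices.
3. **Local moves and ruin-and-recreate.** Each remaining iteration either
   perturbs the incumbent with an encoding-native move (disjunctive:
   shift a block, move its end, toggle activation; time-indexed: move a
   start indicator, adjust a duration integer, toggle an indicator) or
   removes one or two random patients and reinserts them by best response
   with randomized tie-breaks. Every candidate passes through
   `repair_schedule()`; strict improvements replace the incumbent.
4. **Bound and early stop.** `upper_bound()` is the minimum of the
   contention-free bound (sum of `max_individual_gain()` over patients)
   and a robot-capacity relaxation: by concavity each robot can hand out
   at most the sum of its `G` largest per-step marginal gains across
   patients. The capacity relaxation drops patient-side budgets entirely
   rather than spending them greedily — a greedy allocation under both
   budget families is not a valid over-estimate (it can undercut the
   relaxation optimum), and the bound's contract is to dominate every
   feasible schedule. The search stops as soon as the incumbent attains
   the bound, which on the equal-curve scenarios happens in the first
   construction for most cells.

The repair heuristic mirrors the obvious-weakness scan: blocks are pulled
forward to the earliest feasible start (robot already free, patient idle)
and extended whenever patient and robot would both idle afterwards, to a
fixed point. Both moves are gain-monotone, so repair never hurts; it is
also idempotent, which the tests assert on randomized schedules.

An *iteration* is one candidate evaluation. The published experiments
budgeted 1000 iterations of a commercial solver; the two notions are not
commensurable, so budgets here are configuration, not a fidelity claim.

`brute_force_optimal()` is the independent oracle: it enumerates every
timed per-patient plan (ordered blocks on distinct robots, all waiting
positions included) and searches the cross product depth-first, pruning
with the remaining patients' individual maxima when the objective is total
gain. A size guard — a memoised plan count, computed before anything is
materialised — rejects instances beyond roughly 3 patients, 3 robots, 6
steps. Symmetry reduction over identical patients is omitted; the
bound pruning already discards tied branches at the guarded sizes.

## Group objectives

Besides total gain, two group-fairness objectives are available:

* `objective_variance_penalized(m)`: total gain minus `m` times the
  variance of per-patient gains. The variance is the population variance
  (divide by `M`) by default — the choice is not pinned down by the
  formulation, so it is documented and configurable (`var_type =
  "sample"`). The penalty is applied once at session level to the
  distribution of per-patient gains, reading the formulation's intent
  (similar improvement across patients) rather than its literal per-pair
  nesting.
* `objective_relative_to_max(m_p)`: each patient's gain is scored against
  the most that patient could gain alone in the gym
  (`max_individual_gain()`, computed exactly), with a per-patient penalty
  `m_p[j] * (1 - gain_j / max_j)`. A patient with zero maximum and a
  positive coefficient is a domain error.

## Random groups

`generate_group()` draws a pool of 42 curves by default, with `c2` in
[0.01, 100] and `c3` in [5, 1000], then deals `M * N` of them to
patient-robot pairs without replacement, deterministically per seed. Both
ranges span several decades, so sampling is log-uniform by default (a
uniform draw would make small `c2` values vanishingly rare); uniform
sampling is available via `sampling = "uniform"`. The published
random-group totals cannot be reproduced — the underlying draws were
never printed — so for random groups the suite asserts only the ordering
property: optimized schedules at least match both baselines, which the
incumbent seeding guarantees by construction. One pool is drawn per group
seed rather than reusing a single pool across groups.

## What the synthetic scenarios do and do not show

The equal-curve scenarios and random groups emulate the study conditions:
deterministic, perfectly known skill curves; single-skill robots; one
uninterrupted visit per (patient, robot) pair; simultaneous session start
and end. Passing tests show the scheduling machinery is correct under
those assumptions. They say nothing about real rehabilitation data, where
skill is a hidden state observed through noisy task performance,
improvement is stochastic, and motivation, fatigue and forgetting all
move the curves. Those extensions are out of scope here.

## Numerical choices and problem sizes

All skill arithmetic is double precision; comparisons against printed
one-decimal totals use an absolute tolerance of 0.05. Improvement
acceptance uses a `1e-9` slack so floating-point ties do not churn the
incumbent. The test suite runs the nine equal-curve scenarios in full,
optimizer-versus-oracle checks on instances up to 3 patients / 3 robots /
4 steps, and randomized property checks on scenarios up to 4 patients /
4 robots / 8 steps with 25 draws for formulation equivalence — sizes
chosen so the whole suite completes in well under a minute while still
exercising exit times, unequal curves and both encodings.

## Known limitations

* The open-shop structure allows each (patient, robot) pair at most one
  block; schedules with repeated visits are out of scope (the
  time-indexed encoding could be extended, the disjunctive one cannot).
* The anytime search carries no optimality certificate except when the
  incumbent meets `upper_bound()`; on the 6-patient scenarios the bound
  is loose and the gap does not imply suboptimality.
* `max_individual_gain()` enumerates robot subsets; it is exact and fast
  for the intended gym sizes (up to ~10 robots) but exponential beyond.
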