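---
title: "Two bottleneck models of driving under working-memory load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two bottleneck models of driving under working-memory load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogdriver)
```

## The question the simulator probes

When a driver simultaneously keeps a car in a narrow lane (visuospatial
demand) and tracks which speed limit applied *n* signs ago (working-memory
demand), where do the two tasks interfere? `cogdriver` implements, as a
desk-scale discrete-event simulation, two competing answers formulated in
the ACT-R cognitive architecture:

* **Central bottleneck.** Cognition is a serial production system: each
  if-then rule ("production") takes 50 ms of a single procedural resource.
  Two concurrent goal threads — driving and the n-back task — interleave
  productions, and every production the memory task fires can delay a
  steering update by up to 50 ms. Nothing else couples the tasks.
* **Problem-state bottleneck.** In addition to the central bottleneck, the
  driving loop *depends on working memory*: each iteration of the steering
  loop begins with an attend-near production that can only be initiated
  while the problem state — a one-chunk working-memory buffer — is not
  busy. Sequential recall of speed signs swaps the problem-state content
  continuously, each swap occupying the buffer for 200 ms, so driving
  stalls while memory is in active use.

The package simulates both variants through the full 2 (road) x 5 (n-back)
within-subject design, computes the behavioral metrics (steering reversal
rate, lane deviation, speed-compliance errors, bottleneck cost, RMSE/R²
against reference condition means), and preprocesses pupillometry
(despiking, baseline percent change).

## The cognitive kernel

Time is continuous simulation time managed event by event; the only fixed
quantum is the 50-ms production. Resources (procedural, declarative,
problem state, goal buffer, visual, motor) are held greedily and released
politely. When productions of both goal threads are executable, the least
recently attended goal wins; exact ties break lexicographically so reruns
are bit-identical. Every production firing is logged with its initiation
delay and the binding cause — `procedural_contention` or
`problem_state_busy` — which is the substrate of the bottleneck cost: the
average summed delay imposed on the driving thread between two consecutive
speed signs.

A driving-loop iteration is three productions (attend-near, update, motor)
with architecture-scale latencies between them: 85 ms of visual encoding
after the attend production and a 150-ms motor execution during which the
next iteration may already begin perceiving (pipelined). The iteration
cycle is therefore about 235 ms and the procedural resource runs at ~60%
occupancy in single-task driving. This matters structurally: if the loop
were three back-to-back productions, the procedural resource would be
saturated and every n-back production would steal driving time 1:1, making
the central bottleneck almost as costly as the problem-state bottleneck —
the opposite of the dissociation the models are meant to express.

## Declarative memory and the n-back thread

Each sign is encoded as a chunk `{id, previousID, speed}` carrying a fresh
episodic tag and a backward link, forming a linked list through time.
Buffer semantics are strict: a chunk enters declarative memory only when it
is *released* from a buffer. The encode places the new sign in the problem
state and releases the previous content; each recall step issues a
retrieval request for the `previousID` of the problem-state chunk, and the
retrieved chunk swaps in, releasing its predecessor. The recall result
moves to the goal buffer (target speed is control information), upon which
the problem state is released; the thread also releases it when going idle.
These release rules are not bookkeeping niceties: re-presentation at
release is what boosts a chunk's activation, and mis-timed boosts (e.g.
presenting a chunk at encode time) make the freshest sign an unbeatable
retrieval competitor and pin the error rate at 1.

Retrieval scores every stored chunk as

  base-level activation + mp × similarity + logistic noise(s),

with base-level activation `B = ln(Σ_j t_j^-0.5)` over the presentation
history and similarity 0 for the requested sign, decreasing by 0.1 per
intervening sign (the alternative reading, adjacent signs fully similar, is
a configuration switch; both share the −0.1 step). The winner is returned
if it clears the retrieval threshold (default −10, deliberately low so
outright failures are negligible and errors arise as *confusions* between
neighbouring signs); latency is `F·exp(−score)`, capped at 1 s.

Three retrieval parameters are not printed in the source design and are
package calibrations: the mismatch penalty `mp = 16`, noise scale
`s = 0.25`, latency factor `F = 0.2 s`. The governing constraint on `mp`
is that it must exceed the base-level recency advantage of a freshly
released sign over its predecessor (roughly 1–2.5 activation units over a
20-s inter-sign interval); values near 2 leave retrieval recency-dominated
and non-functional, values above ~25 make recall nearly perfect. `mp = 16`
yields recall error rates of roughly 0.07/0.20/0.43/0.53 at n = 1..4 —
increasing in n, with the overestimation at high n that the modeling
approach is known for.

Rehearsal repeats the same sequential walk (n steps from the most recent
sign) a per-level number of times, default `{0, 1, 1, 2, 2}` cycles for
n = 0..4, interleaved production by production with driving. Rehearsal is
suspended while an overtaking manoeuvre is in progress (the drive goal
holds the visual resource for mirror checks). Each problem-state swap
busies the buffer for 200 ms and the *next* swap waits for it (a module
handles one instruction at a time), so during recall the problem state is
near-continuously occupied — exactly the mechanism that starves the
driving loop in the problem-state variant.

## Vehicle, road, and control laws

The road is straight with three lanes (3.5 m highway / 2.5 m construction,
left lane blocked by pylons in construction). The vehicle is a kinematic
single-track model stepped at 5 ms (= the 200-Hz trace): `speed' = phi·a`
(3 m/s² throttle, 6 m/s² brake), `heading' = speed/wheelbase ·
steer/steer_ratio` plus a small heading disturbance (0.004 rad/√s) that
makes an uncorrected car drift, `y' = speed·sin(heading)`.

**Lateral control** follows the two-point law in a high-control loop:
`Δsteer = k_far·Δθ_far + k_near·Δθ_near + k_I·θ_near·Δt`, with near/far
points at the target-lane centre 10 m and 100 m ahead and gains 16/4/3
from the cited steering-model literature. The low-control loop holds the
wheel and merely monitors the distance to the lane edges; within `dist`
metres of an edge control escalates for `t_hc = 3` s. `dist` is
per-condition (0.8 m highway, 0.5 m construction). Numerical choices that
stabilize the discrete loop at a 235-ms update interval: the wheel moves at
most 0.1 rad per motor action (a physical turn-rate limit that also keeps
long-delayed updates from slamming the wheel), the integral term uses at
most the nominal cycle time, and the high→low handoff additionally waits
for a near-neutral wheel (|steer| < 0.05 rad) so the passive phase never
begins with the wheel hard over. The `steer_ratio` of 20 sets the yaw gain
so the per-update loop factor stays below instability across 40–120 km/h.

**Longitudinal control** tracks a fictional point moving at the current
target speed. The headway variable in
`phi' = clamp(phi + k_Δthw·Δthw + k_thw·thw·Δt, −1, 1)` is measured
relative to the desired headway (1 s), i.e. it is zero at the set point.
Measuring it as a raw gap-over-speed with an absolute point position makes
the law a marginally stable double integrator (the simulated speed then
oscillates ±20 km/h indefinitely); the relative form — the form of the
cited car-following law — is a stable PI controller with derivative
action. Gains 6/1.7 settle an 80-km/h step in roughly 7 s under the
saturation limits.

Overtaking: 2–3 scripted slower leads per block spawn ahead in the
right-most drivable lane; within a 3-s headway the driver re-anchors the
steering percepts to the adjacent left lane and returns to the right-most
free lane once clear.

## Design, schedule, and seeds

A block is a minimum 20-s run-in plus exactly 160 s of experimental phase.
Signs appear 10 s into the block and every 20 s after, speeds uniform over
40–120 km/h in steps of 10 without immediate repetition; with the run-in
equal to `max(20·n, 20)` s the n-th sign has always appeared before the
experimental phase, whose own schedule is always 8 signs at 10..150 s.
The common run-in for 0-back is deliberate: without it the 0-back
experimental phase would start from a perfectly centred, drift-free car
and its steering metrics would be biased low purely by initial conditions.

The 20-block schedule pairs every (road, n) cell once in the first half
with strictly alternating roads and no repeated n level, then mirrors in
reverse. The declarative store resets between blocks. A "simulated
participant" is a replicate with derived child seeds; world streams (sign
speeds, traffic, heading disturbance) are shared between the two model
variants so both face identical environments, while cognition streams
(activation noise, motor noise) are variant-specific.

## Metrics

All metrics are computed on the experimental phase only. A lane-marking
crossing is a lane change only if the new lane is held ≥ 5 s (a return
from a shorter excursion is a lane-keeping error, not a change); 6-s
windows around lane changes are excluded and all normalizations use the
retained duration. Steering reversals are sign changes of the wheel angle
through centre, with a 0.005-rad deadband against numerical jitter, never
counted across an excluded gap, reported per second. Lane deviation is the
mean absolute offset from the occupied lane's centre. Speed compliance
scores each inter-sign interval against the *true* n-back target with a ±5
km/h tolerance on the mean absolute deviation after a 5-s settling grace —
maintaining a wrongly recalled speed is an error. Bottleneck cost is the
mean summed initiation delay of driving-thread productions per inter-sign
interval, reported per cause. RMSE and R² compare 10-cell condition-mean
vectors.

Pupillometry: pre-annotated blinks and any sample ≥ 4 SD from the
blink-free mean are removed with ±25-sample margins and filled by monotone
cubic interpolation (`splinefun(method = "monoH.FC")`); boundary gaps use
nearest-valid extension. The baseline is the median pupil size over
fixation samples in the baseline window and the series becomes
`100·(x − m)/m`.

## What the simulations show, and what they do not

At the package defaults, an R = 10 paired run reproduces: error rates
rising steeply with n (≈ 0.09 at 0-back to ≈ 0.6 at 4-back) with no road
effect; bottleneck cost rising with n in both variants and 2–3× larger in
the problem-state variant at every level (≈ 0.8 s vs ≈ 2.2 s per interval
at 4-back); higher steering reversal rates and lower lane deviation on the
narrow construction road for both variants; and in the problem-state
variant a monotone decline of steering reversals across n on the
construction road, where the working-memory gate bites hardest.

Two aspects of the dissociation are weaker than in the reference pattern,
and deliberately left so rather than tuned: on the wide highway the
problem-state decline in reversal rate is not reliably monotone at this
replicate count, and the central variant's reversal-rate range across n is
roughly half the problem-state variant's range rather than under a
quarter. The cause is mechanistic: in this implementation reversals arise
both from noise flips during active steering (proportional to steering
updates — the channel through which blocking should reduce them) and from
corrective episodes after drift; blocked driving time deepens drift and
lengthens the subsequent corrections, which partially compensates the lost
updates, most strongly on the wide road where drift runs longest before
detection.

The generator emulates a simplified world: straight roads, scripted
traffic, Gaussian heading disturbance, and a driver without fatigue,
anticipation, or individual differences. Passing tests on this synthetic
world show the internal consistency of the two bottleneck mechanisms and
of the metric pipeline, not that either model fits any particular human
dataset; the human data of the original study are not redistributed here,
and `fit_metrics()` exists so users can compare the simulator's condition
means against reference means of their own.

## Worked example

```{r example, eval = FALSE}
cfg <- default_config()
blk <- sim_block("construction", n = 2, variant = "problem_state",
                 cfg, world_seed = 11, cog_seed = 12)
analyze_block(blk)

# the full paired design (several minutes)
ce <- run_experiment("central", cfg, master_seed = 1, replicates = 10)
ps <- run_experiment("problem_state", cfg, master_seed = 1, replicates = 10)
ps$summary
```
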