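---
title: "Simulating binaral odor-plume navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating binaral odor-plume navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plumenav simulates a minimal two-sensor ("binaral") agent searching for an
odor source in a 1 x 1 m flow arena, under two classic chemotaxis
strategies: an instantaneous left-right comparison (tropotaxis, **Code A**)
and a temporal-gradient strategy that falls back on the binaral comparison
(klinotaxis, **Code B**). This vignette documents the model, its numerical
choices, the synthetic plume generator, and the design decisions taken where
the problem statement was genuinely open — so that a green test suite can be
read for exactly what it does and does not establish.

## The agent model

**Coordinates.** `x` increases in the flow direction; the inlet wall (odor
ports) is at `x = 0`, the outlet wall at `x = 100` cm, `y` in `[0, 100]` cm.
Angles are mathematical (counterclockwise, 0 along `+x`), so a heading of
180 degrees faces the inlet and hence the source. Degrees at the interface,
radians internally.

**Kinematics.** The chassis center moves in discrete ticks of
`dt = 0.1` s at speed `v = 4` cm/s:

    x[t+dt] = x[t] + v dt cos(theta),  y[t+dt] = y[t] + v dt sin(theta)

A turn changes the heading by `pi/6` (30 degrees) and occupies one tick; the
head-on wall escape backs up with `v = -4` cm/s.

**Sensor layout.** Two odor sensors sit at the front of a chassis of radius
`l_d = 8` cm, separated by `l_s` (8 or 16 cm typical). In the body frame
they are at `(l_d, +/- l_s/2)`; equivalently at distance
`sqrt(l_d^2 + (l_s/2)^2)` from the center at bearings `theta +/- gamma`
with `gamma = arctan(l_s / (2 l_d))`. The radical could be typeset two
ways in the source material; only this reading is consistent with the
definition of `gamma` and with sensors "at the front of the chassis", so it
is the one implemented (both forms are cross-checked in the tests). Derived
quantities are recomputed on demand (`sensor_angle()`, `sensor_radius()`),
never stored.

**Sensor dynamics.** Each sensor low-pass filters the local concentration:

    dS/dt = -k_decay * S + C(x, y, t),   k_decay = ln(2) / 0.8 s

i.e. a sensor half-life of 0.8 s. The update is the *exact* zero-order-hold
solution `S' = S e^(-k dt) + (C/k)(1 - e^(-k dt))` with `C` sampled at the
sensor's position from the current movie frame and held constant over the
tick. This is unconditionally stable, exact for piecewise-constant `C`, and
agrees with a 1-ms forward-Euler integration to within 1e-4 of the signal
scale `max(S, C/k)` — whether the original implementation used Euler or
exact updates is immaterial at that level. Note the equilibrium signal is
`C / k_decay` (about `1.154 C`), not `C`; all thresholds are applied to `S`
on that scale consistently.

## Trial protocol

1. **Baseline acquisition (12 s).** The agent stands still for 10 s so the
   sensors equilibrate, then averages four left-sensor samples over the next
   second and four right-sensor samples over the second after that;
   `S_baseline` is the mean of the two averages. The 0.25-s sample spacing
   is not a multiple of the 0.1-s tick, so the two sampling seconds are
   integrated as four exact 0.25-s sub-steps each (the exponential update is
   exact for any step); the clock still advances by exactly 12 s. On a
   dynamic plume the movie keeps playing during the protocol, so the
   baseline captures ambient fluctuation as a physical sensor would.
2. **Wall avoidance (checked first every loop).** If the chassis center is
   within `d_threshold = 10` cm of a wall, the nearest wall's bearing
   selects a virtual IR sector: within `pi/6` of straight ahead is a
   head-on wall (turn right 100 ms, back up 200 ms at `-v`); bearings out to
   `+pi/2` on the left mean a left-side wall (turn right, forward 200 ms);
   mirrored for the right. Walls behind the agent are ignored; two walls
   within threshold (a corner) conservatively count as head-on. Sector
   widths are not fully specified by the source material; `pi/6` about the
   bearing to the nearest wall point is this package's documented,
   configurable choice.
3. **Odor-driven decision (only if no wall).** Code A: turn toward the
   stronger sensor if the baseline-corrected difference exceeds
   `S_threshold = 0.03`, else go straight. Code B: first compare the change
   in the binaural average since the previous *decision point*,
   `dC = ((S_L + S_R)_now - (S_L + S_R)_prev) / 2`; if `dC > S_threshold/4`
   go straight, else apply the binaral rules at half threshold, else go
   straight. All comparisons are strict inequalities; equality falls through
   to the next rule.

Every action ends with a 300-ms stationary pause, so one odor-driven loop
takes 500-600 ms; sensors integrate through every tick and success (center
within the capture radius of the active source) is checked per tick.

**Design decisions worth knowing about:**

* **Capture radius.** The source material never states the model's capture
  radius; `success_radius_cm = 10` is this package's default and percent
  success is sensitive to it. In particular, because it equals the
  wall-avoidance threshold, a blind straight walk aimed dead-on at a port
  enters the capture disk before wall avoidance can deflect it — a corner
  source is the right control when testing "no odor implies no capture".
* **Time accounting.** The 75-s budget covers navigation only, excluding
  the 12-s baseline. An action already in progress may overshoot the budget
  by at most 0.6 s.
* **Code B memory.** The "previous sample" in the temporal rule is the
  previous decision point (one control loop, ~500-600 ms earlier), not one
  tick earlier; it initializes to the first decision's pair sum so the first
  step is governed by the binaral rules. The constant threshold offsets in
  the textbook form of the temporal difference cancel and are dropped.
* **Start position.** Default is the outlet-midline entry point
  (`x = 92.5`, `y = 50` cm) used for direct comparison with animal runs; a
  mid-arena start is available by passing `start_pose`. Start angles sweep
  90-270 degrees at 3.6-degree increments (51 angles).
* **Containment.** Positions are never clamped inside `advance()` (wall
  logic lives in the navigation loop); within a trial, a corrective move
  that would still exit the arena is clamped to the boundary inset by one
  chassis radius and counted (`n_clamped`).

## Plume fields

Dynamic plumes are 3-D stacks of max-normalized concentration (HDF5 layout
`[t, y, x]` with `fps`, `px_per_cm` and origin attributes; negative voxels
are clipped to zero with a reported count). Sampling is nearest-pixel — the
sensor is treated as a point probe — with the movie looping continuously:
frame `(start_frame - 1 + floor(t * fps)) mod n_frames + 1`. Points outside
the grid read 0, because sensors legitimately overhang the walls while the
center stays inside. Frame indices are 1-based at the R interface; a
4-minute, 3600-frame reference movie implies the 15-fps default (some
derived material quotes 10 Hz, but that is a playback rate; `fps` is a
stored, configurable attribute and never guessed silently). The static
(low-complexity) condition is the per-pixel time average of the movie, and
static trials are fully deterministic.

`probe_stats()` reports, per probe pixel, the time-series mean, sample
(n-1) SD, SD/mean, and **intermittency**: the fraction of time the series
exceeds 4.4% of the time-averaged signal at a reference probe
(conventionally 10 cm downstream of the source). Under this definition a
*more continuous* signal — e.g. from a denser puff stream — spends more
time above the threshold, so intermittency increases toward 1 with puff
rate; the property tests assert that direction.

## The synthetic plume generator

Measured plume movies are large external datasets, so the package bundles a
generator able to reproduce their qualitative statistics: `make_dynamic()`
releases Gaussian puffs at the source every `1/puff_rate_hz` seconds
(starting one arena transit early so frame 1 is fully developed), advects
them downstream at `advection_cm_s = 5` cm/s, grows their variance as
`sigma^2(age) = sigma_0^2 + g * age` (2-D mass conservation scales the peak
by `sigma_0^2 / sigma^2`), and displaces each puff laterally by a shared
Ornstein-Uhlenbeck meander sampled at its release time (frozen-field
advection: the instantaneous plume snakes, the long-run mean is centered).
Frames are normalized by the movie-wide maximum — not per frame — so
temporal fluctuations survive normalization. `make_static()` is the
analytic counterpart, a Gaussian plume `C(d, l) = (sigma_0 / sigma(d)) *
exp(-l^2 / (2 sigma(d)^2))` with `sigma(d) = sigma_0 + s d`, the spread `s`
matched to the puff growth over one arena transit and the source pixel
normalized to 1. The long-run time average of the generated movie
correlates with this field above r = 0.9 once the meander is small, and the
correlation rises monotonically as the meander shrinks (both tested).

Defaults state the emulated world once: 240 s at 15 fps on a 100 x 100 grid
at 1 px/cm, 5 puffs/s, initial radius 3 cm, growth 5 cm^2/s, meander SD
5 cm with a 5-s timescale. The initial radius matches the few-cm odor-tube
horn; growth and meander were chosen so the plume widens to roughly 10 cm
over the 20-s transit and fluctuates intermittently at mid-arena probes —
plausible for a 5-cm/s chamber — and are not revisited. The
`complexity = "high"` preset (emulating removal of the inlet
flow-straightener) triples the meander SD and halves the puff rate, which
inflates the SD and SD/mean of downstream probe series by roughly the
observed two- to four-fold; the tests assert the *ordering*, not the
measured values. What the generator does **not** emulate: real turbulent
fine structure and spectra, absolute concentrations, vertical structure, or
wall effects on the flow. A green directional test (static beats dynamic)
therefore establishes that the *algorithms* respond to intermittent,
meandering input as reported — not that the generator is a fluid-dynamics
model.

One fixture caveat: with the default growth, puffs at any tested rate
overlap enough that intermittency saturates at 1.0 at the 30-cm probe, so
the puff-rate ordering tests use slow-growing puffs (`g = 1` cm^2/s) where
the statistic is informative. The 4.4% rule itself is untouched.

## Metrics

All Figure-level outcome measures are pure functions of a `tracked_path`
(body point per frame, optional nose point): `path_linearity()`
(start-to-end distance over path length), `total_angle_sum()` (sum of
absolute frame-to-frame heading changes, zero-displacement frames skipped),
`wall_hugging_fraction()` (frames within a 5-cm band of a wall),
`nose_body_ratio()`, `delta_nose_angle()` (absolute change in the
body-to-nose bearing per frame, coincident points skipped), and
`resample_path()` (linear interpolation in time to a fixed frame count,
e.g. 755 or 675, endpoints exact). Simulated trials convert with
`as_tracked_path()`, which drops the stationary baseline phase and places
the nose one chassis radius ahead of the center.

## Sweeps, seeding, determinism

`run_sweep()` executes the full design (angles x replicates) and returns a
long-form tidy table so every figure-level aggregate is a pure reduction.
Per-trial seeds are derived arithmetically,
`(base %% 21474) * 100000 + angle_index * 100 + replicate` (always below
2^31), so any single trial is re-runnable in isolation from its table row.
The only randomness in a dynamic trial is the uniformly drawn start frame;
static trials ignore the seed entirely. Condition contrasts
(`compare_conditions()`) run Welch tests on per-replicate summaries (each
replicate's percent success over all angles — the unit the original design
reports), with a closed-form fallback when both groups are deterministic.

## Known limitations

* The agent is a point-kinematics chassis: no differential-drive dynamics,
  no continuous-curvature turns, no collision geometry beyond the center
  clamp.
* No anemotaxis, sniff-rate modulation, or sampling-rate adaptation — the
  controllers are deliberately minimal, which is the point of the
  comparison.
* Nearest-pixel sampling means results depend mildly on grid resolution
  near steep gradients.
* The headline quantitative contrasts from measured PLIF movies require
  those external datasets; the bundled generator supports directional
  conclusions only.

```{r example}
library(plumenav)
arena <- arena_spec()
movie <- make_dynamic(synth_plume_params(duration_s = 40, seed = 7), arena)
static <- time_average(movie)

trial <- run_trial(static, navigator_params("A"), start_angle_deg = 180)
summary(trial)

cfg_s <- sweep_config("A", 8, "static", replicates = 5, base_seed = 11)
cfg_d <- sweep_config("A", 8, "dynamic", replicates = 5, base_seed = 11)
compare_conditions(run_sweep(cfg_s, static), run_sweep(cfg_d, movie),
                   alternative = "greater")
```
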