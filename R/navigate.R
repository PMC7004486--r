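#' Navigation controller parameters
#'
#' Tunables of the hierarchical control loop. Every control loop first checks
#' the virtual IR sensors for a nearby wall; only if none is found does the
#' odor-driven rule set (`code`) run. `"A"` is pure tropotaxis: turn toward
#' the stronger sensor whenever the baseline-corrected left-right difference
#' exceeds `s_threshold`. `"B"` adds a temporal (klinotaxis) rule: if the
#' binaurally averaged signal rose by more than `s_threshold / 4` since the
#' previous decision the agent keeps going straight, otherwise it falls back
#' on the binaral comparison at half threshold.
#'
#' The capture radius `success_radius_cm` is not stated by the reference
#' design; 10 cm is this package's documented default and percent success is
#' sensitive to it.
#'
#' @param code `"A"` (binaral/tropotaxis) or `"B"` (temporal/klinotaxis).
#' @param s_threshold Signal threshold on the filtered sensor difference
#'   (default 0.03).
#' @param d_threshold_cm Wall-avoidance trigger distance from the chassis
#'   center to a wall (default 10).
#' @param time_budget_s Navigation time allotted to find the source
#'   (default 75); excludes the 12-s baseline protocol.
#' @param success_radius_cm Capture radius around the active source.
#' @param pause_s Stationary sensor-equilibration pause after every action
#'   (default 0.3).
#' @param forward_s Duration of each forward/backup move (default 0.2).
#' @param turn_s Duration of a turn (default 0.1; one tick).
#' @param ir_sector_halfwidth_rad Half-width of the center IR sector about
#'   the bearing to the nearest wall point (default `pi/6`).
#' @return An object of class `navigator_params`.
#' @export
navigator_params <- function(code = c("A", "B"), s_threshold = 0.03,
                             d_threshold_cm = 10, time_budget_s = 75,
                             success_radius_cm = 10, pause_s = 0.3,
                             forward_s = 0.2, turn_s = 0.1,
                             ir_sector_halfwidth_rad = pi / 6) {
  code <- match.arg(code)
  vals <- c(s_threshold, d_threshold_cm, time_budget_s, success_radius_cm,
            pause_s, forward_s, turn_s, ir_sector_halfwidth_rad)
  stopifnot_finite(vals, "navigator_params")
  if (s_threshold <= 0 || d_threshold_cm <= 0 || success_radius_cm <= 0) {
    stop("thresholds must be > 0", call. = FALSE)
  }
  structure(list(code = code, s_threshold = s_threshold,
                 d_threshold_cm = d_threshold_cm,
                 time_budget_s = time_budget_s,
                 success_radius_cm = success_radius_cm,
                 pause_s = pause_s, forward_s = forward_s, turn_s = turn_s,
                 ir_sector_halfwidth_rad = ir_sector_halfwidth_rad),
            class = "navigator_params")
}

#' @export
print.navigator_params <- function(x, ...) {
  cat(sprintf(paste0("<navigator_params> Code %s: S_thr=%g, d_thr=%g cm, ",
                     "budget=%g s, capture %g cm\n"),
              x$code, x$s_threshold, x$d_threshold_cm, x$time_budget_s,
              x$success_radius_cm))
  invisible(x)
}

#' Classify a nearby wall
#'
#' Returns which virtual IR sector, if any, detects a wall. A wall counts as
#' near when the chassis center is within `d_threshold_cm` of it. The nearest
#' wall's bearing \eqn{\beta} (signed angle from the heading to the closest
#' wall point) selects the sector: `|beta| <=` sector half-width is
#' `"center"`, `beta` in (half-width, pi/2] is `"left"`, the mirror image is
#' `"right"`, and walls behind the agent (`|beta| > pi/2`) are ignored. Two
#' walls within threshold (a corner) conservatively classify as `"center"`.
#'
#' @param state An [agent_state()] with the center inside the arena.
#' @param arena An [arena_spec()].
#' @param params A [navigator_params()].
#' @return One of `"none"`, `"left"`, `"right"`, `"center"`.
#' @export
check_wall <- function(state, arena, params) {
  x <- state$x_cm; y <- state$y_cm
  d <- c(x, arena$length_cm - x, y, arena$width_cm - y)
  px <- c(0, arena$length_cm, x, x)
  py <- c(y, y, 0, arena$width_cm)
  near <- which(d <= params$d_threshold_cm)
  if (length(near) == 0L) return("none")
  if (length(near) >= 2L) return("center")
  i <- near[which.min(d[near])]
  beta <- wrap_pi(atan2(py[i] - y, px[i] - x) - state$heading_rad)
  hw <- params$ir_sector_halfwidth_rad
  if (abs(beta) <= hw) "center"
  else if (beta > hw && beta <= pi / 2) "left"
  else if (beta < -hw && beta >= -pi / 2) "right"
  else "none"
}

# Tick sequence for each action kind (each entry one 100-ms tick).
action_ticks <- function(kind, params, tick_s) {
  n_fwd <- round(params$forward_s / tick_s)
  n_pause <- round(params$pause_s / tick_s)
  moves <- switch(kind,
    TURN_LEFT_FWD     = c("turnL", rep("fwd", n_fwd)),
    TURN_RIGHT_FWD    = c("turnR", rep("fwd", n_fwd)),
    FWD               = rep("fwd", n_fwd),
    TURN_RIGHT_BACKUP = c("turnR", rep("back", n_fwd)),
    stop("unknown action kind: ", kind, call. = FALSE))
  c(moves, rep("pause", n_pause))
}

wall_action_kind <- function(side) {
  switch(side,
         left   = "TURN_RIGHT_FWD",     # wall on the left: turn right, forward
         right  = "TURN_LEFT_FWD",      # wall on the right: turn left, forward
         center = "TURN_RIGHT_BACKUP",  # head-on: turn right, back up
         stop("avoid_wall: side must be left/right/center", call. = FALSE))
}

#' Execute a wall-avoidance maneuver
#'
#' Runs the corrective schedule for a detected wall: left-side wall means
#' turn right then forward 200 ms; right-side wall means turn left then
#' forward 200 ms; head-on means turn right then back up 200 ms at \eqn{-v}.
#' Every variant ends with a 300-ms stationary pause, so the maneuver
#' occupies 600 ms of simulated time with sensors integrated throughout. A
#' corrective move that would still exit the arena is clamped to the boundary
#' inset by the chassis radius (the clamp count is returned).
#'
#' @param state An [agent_state()].
#' @param side `"left"`, `"right"` or `"center"` (from [check_wall()]).
#' @param geometry An [agent_geometry()].
#' @param params A [navigator_params()].
#' @param arena An [arena_spec()] used for the containment clamp.
#' @param plume Optional plume for sensor integration (`NULL` means zero
#'   concentration everywhere).
#' @param sensors Optional [sensor_state()] to integrate.
#' @param start_frame Movie frame at `clock_s = 0`.
#' @return A list with `action` (the kind executed), `state`, `sensors`, and
#'   `n_clamped`.
#' @export
avoid_wall <- function(state, side, geometry, params, arena = arena_spec(),
                       plume = NULL, sensors = NULL, start_frame = 1L) {
  kind <- wall_action_kind(side)
  if (is.null(sensors)) sensors <- sensor_state()
  n_clamped <- 0L
  for (mv in action_ticks(kind, params, geometry$tick_s)) {
    state <- tick_move(state, mv, geometry)
    cl <- clamp_inset(state, arena, geometry$chassis_radius_cm)
    state <- cl$state; n_clamped <- n_clamped + cl$clamped
    if (!is.null(plume)) {
      sensors <- step_sensors(sensors, state, geometry, plume, start_frame,
                              geometry$tick_s)
    }
  }
  list(action = kind, state = state, sensors = sensors,
       n_clamped = n_clamped)
}

# Apply one tick's motion primitive to an agent_state.
tick_move <- function(state, mv, geometry) {
  switch(mv,
         turnL = turn(state, "left", geometry),
         turnR = turn(state, "right", geometry),
         fwd   = advance(state, geometry),
         back  = advance(state, geometry, -geometry$speed_cm_s),
         pause = { state$clock_s <- state$clock_s + geometry$tick_s; state })
}

# Clamp a center that left the arena back to the chassis-radius inset box.
clamp_inset <- function(state, arena, inset) {
  clamped <- 0L
  if (state$x_cm < 0 || state$x_cm > arena$length_cm ||
      state$y_cm < 0 || state$y_cm > arena$width_cm) {
    state$x_cm <- min(max(state$x_cm, inset), arena$length_cm - inset)
    state$y_cm <- min(max(state$y_cm, inset), arena$width_cm - inset)
    clamped <- 1L
  }
  list(state = state, clamped = clamped)
}

#' Code A decision rule (tropotaxis)
#'
#' Instantaneous binaral comparison, strict inequalities, in order of
#' precedence: if \eqn{(S_L - S_{base}) - (S_R - S_{base}) > S_{thr}} turn
#' left and advance; if the mirror difference exceeds the threshold turn
#' right and advance; otherwise go straight. The baseline correction cancels
#' in the difference but is kept in the signature for fidelity to the rule as
#' stated.
#'
#' @param S_left,S_right Current filtered sensor signals.
#' @param S_baseline Acquired baseline (cancels in the difference).
#' @param params A [navigator_params()].
#' @return `"TURN_LEFT_FWD"`, `"TURN_RIGHT_FWD"` or `"FWD"`.
#' @export
decide_code_a <- function(S_left, S_right, S_baseline = 0, params) {
  d <- (S_left - S_baseline) - (S_right - S_baseline)
  if (d > params$s_threshold) "TURN_LEFT_FWD"
  else if (-d > params$s_threshold) "TURN_RIGHT_FWD"
  else "FWD"
}

#' Code B decision rule (temporal klinotaxis)
#'
#' Computes the change in binaurally averaged signal between the current and
#' previous decision points,
#' \eqn{\Delta\bar C = \tfrac12[(S_L + S_R)_{now} - (S_L + S_R)_{prev}]}
#' (the constant threshold offsets in the definition cancel), then applies,
#' in order of precedence: (1) \eqn{\Delta\bar C > S_{thr}/4} go straight;
#' (2) left-right difference \eqn{> S_{thr}/2} turn left and advance;
#' (3) mirror difference \eqn{> S_{thr}/2} turn right and advance;
#' (4) otherwise go straight. All inequalities are strict.
#'
#' The memory `prev_pair_sum` refers to the previous decision point, one
#' control loop (roughly 500-600 ms) earlier; initialize it to the current
#' pair sum at the first decision so \eqn{\Delta\bar C = 0} and the binaral
#' rules govern the first step.
#'
#' @inheritParams decide_code_a
#' @param prev_pair_sum `S_left + S_right` at the previous decision point.
#' @return A list with `action` and `pair_sum` (the memory to carry forward).
#' @export
decide_code_b <- function(S_left, S_right, prev_pair_sum, S_baseline = 0,
                          params) {
  pair <- S_left + S_right
  dC <- (pair - prev_pair_sum) / 2
  d <- (S_left - S_baseline) - (S_right - S_baseline)
  action <-
    if (dC > params$s_threshold / 4) "FWD"
    else if (d > params$s_threshold / 2) "TURN_LEFT_FWD"
    else if (-d > params$s_threshold / 2) "TURN_RIGHT_FWD"
    else "FWD"
  list(action = action, pair_sum = pair)
}

# Compile a plume into a fast scalar sampler f(x, y, t) for the trial loop.
compile_sampler <- function(plume) {
  if (inherits(plume, "static_plume")) {
    grid <- plume$grid; pxcm <- plume$px_per_cm
    ox <- plume$origin[1]; oy <- plume$origin[2]
    nx <- nrow(grid); ny <- ncol(grid)
    function(x, y, t, start_frame) {
      ix <- floor((x - ox) * pxcm) + 1
      iy <- floor((y - oy) * pxcm) + 1
      if (ix < 1 || ix > nx || iy < 1 || iy > ny) 0 else grid[ix, iy]
    }
  } else {
    frames <- plume$frames; pxcm <- plume$px_per_cm
    ox <- plume$origin[1]; oy <- plume$origin[2]
    d <- dim(frames); nx <- d[1]; ny <- d[2]; nt <- d[3]; fps <- plume$fps
    function(x, y, t, start_frame) {
      ix <- floor((x - ox) * pxcm) + 1
      iy <- floor((y - oy) * pxcm) + 1
      if (ix < 1 || ix > nx || iy < 1 || iy > ny) return(0)
      frames[ix, iy, (start_frame - 1L + floor(t * fps)) %% nt + 1L]
    }
  }
}

#' Run one navigation trial
#'
#' The full trial protocol: (1) on a dynamic plume, draw a random start frame
#' (uniform over the movie, via R's RNG) unless one is supplied; (2) run the
#' 12-s baseline-acquisition protocol; (3) loop wall check then wall
#' avoidance, otherwise the odor-driven rule of the configured code,
#' executing actions in 100-ms ticks with sensor integration, until the
#' chassis center comes within the capture radius of the active source
#' (success) or the navigation clock exceeds the time budget (an action in
#' progress may overshoot the budget by at most 0.6 s).
#'
#' Trials on a static plume are fully deterministic; on a dynamic plume the
#' only randomness is the start frame, so fixing `seed` (or `start_frame`)
#' makes the trajectory reproducible bit for bit.
#'
#' @param plume A [static_plume()] or [dynamic_plume()].
#' @param params A [navigator_params()] (chooses Code A or B).
#' @param arena An [arena_spec()].
#' @param geometry An [agent_geometry()].
#' @param start_pose An [agent_state()]; default is the outlet-midline entry
#'   point (`x = length - 7.5`, `y = width/2`) at `start_angle_deg`, matching
#'   the animal entry hole used for direct comparison.
#' @param start_angle_deg Start heading in degrees (180 faces the inlet);
#'   used only when `start_pose` is NULL.
#' @param source Active odor source: a port name or `(x, y)`.
#' @param seed Optional integer seed for the start-frame draw.
#' @param start_frame Optional explicit start frame (overrides the draw).
#' @return An object of class `trial_result`: fields `success`,
#'   `time_to_target_s` (NA on failure), `trajectory` (one row per tick:
#'   `t_s`, `x_cm`, `y_cm`, `heading_rad`, `S_left`, `S_right`, `action`,
#'   `provenance`), `start_frame`, `seed`, `n_clamped`, `source`, plus the
#'   configuration echo.
#' @export
run_trial <- function(plume, params = navigator_params(),
                      arena = arena_spec(), geometry = agent_geometry(),
                      start_pose = NULL, start_angle_deg = 180,
                      source = "center", seed = NULL, start_frame = NULL) {
  stopifnot(inherits(params, "navigator_params"),
            inherits(arena, "arena_spec"),
            inherits(geometry, "agent_geometry"))
  if (!inherits(plume, "static_plume") && !inherits(plume, "dynamic_plume")) {
    stop("`plume` must be a static_plume or dynamic_plume", call. = FALSE)
  }
  tick <- geometry$tick_s
  for (dur in c(params$pause_s, params$forward_s, params$turn_s)) {
    if (abs(dur / tick - round(dur / tick)) > 1e-9) {
      stop("action durations must be integer multiples of the tick",
           call. = FALSE)
    }
  }
  if (is.null(start_pose)) {
    start_pose <- agent_state(arena$length_cm - 7.5, arena$width_cm / 2,
                              deg2rad(start_angle_deg))
  }
  if (start_pose$x_cm < 0 || start_pose$x_cm > arena$length_cm ||
      start_pose$y_cm < 0 || start_pose$y_cm > arena$width_cm) {
    stop("start pose must lie inside the arena", call. = FALSE)
  }
  src <- resolve_source(arena, source)

  if (!is.null(seed)) set.seed(seed)
  if (is.null(start_frame)) start_frame <- random_start_frame(plume)
  start_frame <- as.integer(start_frame)

  # trajectory recorder (preallocated; one row per integration step)
  n_base <- round(10 / tick) + 8L
  n_nav <- ceiling((params$time_budget_s + 0.7) / tick)
  n_max <- 1L + n_base + n_nav
  traj <- matrix(NA_real_, n_max, 6)
  act_lab <- character(n_max)
  prov_lab <- character(n_max)
  row <- 0L
  rec <- function(t, x, y, th, sl, sr, act, prov) {
    row <<- row + 1L
    traj[row, ] <<- c(t, x, y, th, sl, sr)
    act_lab[row] <<- act
    prov_lab[row] <<- prov
  }

  agent <- start_pose
  sensors <- sensor_state()
  rec(agent$clock_s, agent$x_cm, agent$y_cm, agent$heading_rad, 0, 0,
      "NONE", "baseline")
  base <- acquire_baseline(agent, geometry, plume, sensors, start_frame,
                           on_step = function(a, s) {
                             rec(a$clock_s, a$x_cm, a$y_cm, a$heading_rad,
                                 s$S_left, s$S_right, "NONE", "baseline")
                           })
  agent <- base$agent
  sensors <- base$sensors
  nav_start <- agent$clock_s

  sampler <- compile_sampler(plume)
  k <- sensors$k_decay
  r_sens <- sensor_radius(geometry)
  gam <- sensor_angle(geometry)
  inset <- geometry$chassis_radius_cm
  v <- geometry$speed_cm_s
  inc <- geometry$turn_increment_rad
  radius2 <- params$success_radius_cm^2

  x <- agent$x_cm; y <- agent$y_cm; th <- agent$heading_rad
  clk <- agent$clock_s
  sl <- sensors$S_left; sr <- sensors$S_right
  e_tick <- exp(-k * tick)
  success <- FALSE
  time_to_target <- NA_real_
  n_clamped <- 0L
  pair_mem <- NA_real_   # Code B memory: previous decision-point S_L + S_R

  while (!success && (clk - nav_start) < params$time_budget_s) {
    st <- agent_state(x, y, th, clk)
    side <- check_wall(st, arena, params)
    if (side != "none") {
      kind <- wall_action_kind(side)
      prov <- "wall"
    } else if (params$code == "A") {
      kind <- decide_code_a(sl, sr, sensors$S_baseline, params)
      prov <- "odor"
    } else {
      if (is.na(pair_mem)) pair_mem <- sl + sr
      dec <- decide_code_b(sl, sr, pair_mem, sensors$S_baseline, params)
      kind <- dec$action
      pair_mem <- dec$pair_sum
      prov <- "odor"
    }
    for (mv in action_ticks(kind, params, tick)) {
      if (mv == "turnL") th <- wrap_2pi(th + inc)
      else if (mv == "turnR") th <- wrap_2pi(th - inc)
      else if (mv == "fwd") { x <- x + v * tick * cos(th)
                              y <- y + v * tick * sin(th) }
      else if (mv == "back") { x <- x - v * tick * cos(th)
                               y <- y - v * tick * sin(th) }
      if (x < 0 || x > arena$length_cm || y < 0 || y > arena$width_cm) {
        x <- min(max(x, inset), arena$length_cm - inset)
        y <- min(max(y, inset), arena$width_cm - inset)
        n_clamped <- n_clamped + 1L
      }
      clk <- clk + tick
      cl <- sampler(x + r_sens * cos(th + gam), y + r_sens * sin(th + gam),
                    clk, start_frame)
      cr <- sampler(x + r_sens * cos(th - gam), y + r_sens * sin(th - gam),
                    clk, start_frame)
      sl <- sl * e_tick + (cl / k) * (1 - e_tick)
      sr <- sr * e_tick + (cr / k) * (1 - e_tick)
      rec(clk, x, y, th, sl, sr, kind, prov)
      if ((x - src[1])^2 + (y - src[2])^2 <= radius2) {
        success <- TRUE
        time_to_target <- clk - nav_start
        break
      }
    }
  }

  trajectory <- data.frame(t_s = traj[1:row, 1], x_cm = traj[1:row, 2],
                           y_cm = traj[1:row, 3],
                           heading_rad = traj[1:row, 4],
                           S_left = traj[1:row, 5], S_right = traj[1:row, 6],
                           action = act_lab[1:row],
                           provenance = prov_lab[1:row])
  structure(list(success = success, time_to_target_s = time_to_target,
                 trajectory = trajectory, start_frame = start_frame,
                 seed = seed, n_clamped = n_clamped, source = src,
                 source_name = if (is.character(source)) source else NA,
                 S_baseline = sensors$S_baseline,
                 params = params, geometry = geometry, arena = arena),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> Code %s: %s%s; start frame %d, %d ticks\n",
              x$params$code,
              if (x$success) "SUCCESS" else "failure",
              if (x$success) sprintf(" in %.1f s", x$time_to_target_s) else "",
              x$start_frame, nrow(x$trajectory)))
  invisible(x)
}

#' @export
summary.trial_result <- function(object, ...) {
  tp <- as_tracked_path(object)
  nav <- object$trajectory[object$trajectory$provenance != "baseline", ,
                           drop = FALSE]
  out <- list(success = object$success,
              time_to_target_s = object$time_to_target_s,
              pathlength_cm = path_length(tp),
              linearity = if (nrow(tp) >= 2 && path_length(tp) > 0)
                path_linearity(tp) else NA_real_,
              total_angle_sum_deg = total_angle_sum(tp),
              wall_hugging_fraction = wall_hugging_fraction(tp, object$arena),
              n_wall_actions = sum(nav$provenance == "wall"),
              n_clamped = object$n_clamped)
  class(out) <- "summary.trial_result"
  out
}

#' @export
print.summary.trial_result <- function(x, ...) {
  cat(sprintf(
    paste0("success: %s | time: %.1f s | path: %.1f cm | linearity: %.3f\n",
           "angle sum: %.0f deg | wall fraction: %.2f | wall actions: %d\n"),
    x$success, x$time_to_target_s, x$pathlength_cm, x$linearity,
    x$total_angle_sum_deg, x$wall_hugging_fraction, x$n_wall_actions))
  invisible(x)
}

#' @export
plot.trial_result <- function(x, plume = NULL, ...) {
  ar <- x$arena
  if (!is.null(plume)) {
    g <- if (inherits(plume, "dynamic_plume")) time_average(plume)$grid else
      plume$grid
    graphics::image(seq(0, ar$length_cm, length.out = nrow(g)),
                    seq(0, ar$width_cm, length.out = ncol(g)), g,
                    col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                    xlab = "x (flow, cm)", ylab = "y (cm)", ...)
  } else {
    graphics::plot(NA, xlim = c(0, ar$length_cm), ylim = c(0, ar$width_cm),
                   xlab = "x (flow, cm)", ylab = "y (cm)", asp = 1, ...)
  }
  graphics::rect(0, 0, ar$length_cm, ar$width_cm)
  tr <- x$trajectory
  graphics::lines(tr$x_cm, tr$y_cm, col = "gray30")
  graphics::points(tr$x_cm[1], tr$y_cm[1], pch = 16, col = "darkgreen")
  graphics::points(tr$x_cm[nrow(tr)], tr$y_cm[nrow(tr)], pch = 16,
                   col = if (x$success) "blue" else "red")
  graphics::symbols(x$source[1], x$source[2],
                    circles = x$params$success_radius_cm, inches = FALSE,
                    add = TRUE, fg = "orange")
  invisible(x)
}

#' Write a trajectory to CSV (with a JSON sidecar)
#'
#' Writes one row per integration step with columns `t_s`, `x_cm`, `y_cm`,
#' `heading_rad`, `S_left`, `S_right`, `action`, `provenance`, and a JSON
#' sidecar (`<path>.json`) carrying `success`, `time_to_target_s`, `seed`,
#' `start_frame` and a configuration echo.
#'
#' @param trial A [trial_result()][run_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_result"))
  utils::write.csv(trial$trajectory, path, row.names = FALSE)
  sidecar <- list(success = trial$success,
                  time_to_target_s = trial$time_to_target_s,
                  seed = trial$seed, start_frame = trial$start_frame,
                  source = trial$source, n_clamped = trial$n_clamped,
                  params = unclass(trial$params),
                  geometry = unclass(trial$geometry))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
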