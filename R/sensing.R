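#' Sensor state
#'
#' Left/right low-pass-filtered gas-sensor signals obeying
#' \eqn{\dot S = -k_{decay} S + C(x, y, t)}. At equilibrium in a constant
#' field \eqn{C} the signal settles at \eqn{C/k_{decay}} (signal units are
#' concentration x time). The decay constant defaults to
#' \eqn{\ln 2 / 0.8\,\mathrm{s}^{-1}}, i.e. a sensor half-life of 0.8 s
#' matched to hardware response data.
#'
#' @param k_decay Decay rate constant in 1/s.
#' @return An object of class `sensor_state` with fields `S_left`, `S_right`,
#'   `k_decay`, `S_baseline` (NA until acquired) and `baseline_acquired`.
#' @export
sensor_state <- function(k_decay = log(2) / 0.8) {
  stopifnot_finite(k_decay, "k_decay")
  if (k_decay <= 0) stop("k_decay must be > 0", call. = FALSE)
  structure(list(S_left = 0, S_right = 0, k_decay = k_decay,
                 S_baseline = NA_real_, baseline_acquired = FALSE),
            class = "sensor_state")
}

#' @export
print.sensor_state <- function(x, ...) {
  cat(sprintf("<sensor_state> S_L=%.4f S_R=%.4f k=%.3f/s baseline=%s\n",
              x$S_left, x$S_right, x$k_decay,
              if (x$baseline_acquired) sprintf("%.4f", x$S_baseline) else
                "not acquired"))
  invisible(x)
}

#' One sensor update step
#'
#' Exact zero-order-hold solution of \eqn{\dot S = -kS + C} with the
#' concentration held constant over the step:
#' \eqn{S' = S e^{-k\,dt} + (C/k)(1 - e^{-k\,dt})}. Unconditionally stable
#' for any `dt`; the output is a convex combination of `S` and the fixed
#' point `C/k`.
#'
#' @param S Current signal value.
#' @param C Concentration at the sensor, held constant over the step.
#' @param dt Step duration in s (> 0).
#' @param k_decay Decay rate constant in 1/s.
#' @return Updated signal value.
#' @examples
#' update_sensor(1, 0, 0.8, log(2) / 0.8)  # one half-life: 0.5
#' @export
update_sensor <- function(S, C, dt, k_decay) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  e <- exp(-k_decay * dt)
  S * e + (C / k_decay) * (1 - e)
}

# Advance both sensors one step against the plume at the agent's current pose.
step_sensors <- function(sensors, agent, geometry, plume, start_frame, dt) {
  pos <- sensor_positions(agent, geometry)
  cl <- sample_plume(plume, pos$left, agent$clock_s, start_frame)
  cr <- sample_plume(plume, pos$right, agent$clock_s, start_frame)
  sensors$S_left <- update_sensor(sensors$S_left, cl, dt, sensors$k_decay)
  sensors$S_right <- update_sensor(sensors$S_right, cr, dt, sensors$k_decay)
  sensors
}

#' Acquire the sensor baseline
#'
#' The pre-navigation protocol, identical for both controllers: the agent
#' stays stationary for 10 s while both sensors equilibrate against the
#' (possibly dynamic) plume, then averages 4 left-sensor samples taken over
#' the next second, then 4 right-sensor samples over the second after that.
#' The stored baseline is the mean of the two per-sensor averages and the
#' clock advances by exactly 12 s.
#'
#' Equilibration is integrated in 100-ms ticks; each sampling second runs as
#' four 0.25-s sub-steps (the exponential update is exact for any step), the
#' sensors continuing to evolve between samples. On a dynamic plume the movie
#' advances throughout, so the baseline captures ambient fluctuation exactly
#' as a physical sensor would.
#'
#' @param agent An [agent_state()] (stationary during the protocol).
#' @param geometry An [agent_geometry()].
#' @param plume A [static_plume()] or [dynamic_plume()].
#' @param sensors A fresh [sensor_state()]; calling twice is an error.
#' @param start_frame 1-based movie frame at `clock_s = 0`.
#' @param on_step Optional callback `function(agent, sensors)` invoked after
#'   every integration step (used by [run_trial()] to record the trajectory).
#' @return A list with the updated `agent` (clock advanced 12 s) and
#'   `sensors` (baseline fields set).
#' @export
acquire_baseline <- function(agent, geometry, plume, sensors,
                             start_frame = 1L, on_step = NULL) {
  stopifnot(inherits(sensors, "sensor_state"))
  if (sensors$baseline_acquired) {
    stop("baseline already acquired; the protocol runs once per trial",
         call. = FALSE)
  }
  tick <- geometry$tick_s
  for (i in seq_len(round(10 / tick))) {
    sensors <- step_sensors(sensors, agent, geometry, plume, start_frame, tick)
    agent$clock_s <- agent$clock_s + tick
    if (!is.null(on_step)) on_step(agent, sensors)
  }
  sample_one <- function(field) {
    vals <- numeric(4)
    for (j in 1:4) {
      sensors <<- step_sensors(sensors, agent, geometry, plume, start_frame,
                               0.25)
      agent$clock_s <<- agent$clock_s + 0.25
      if (!is.null(on_step)) on_step(agent, sensors)
      vals[j] <- sensors[[field]]
    }
    mean(vals)
  }
  s_l <- sample_one("S_left")
  s_r <- sample_one("S_right")
  sensors$S_baseline <- (s_l + s_r) / 2
  sensors$baseline_acquired <- TRUE
  list(agent = agent, sensors = sensors)
}
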