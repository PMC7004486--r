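#' Agent chassis geometry
#'
#' Physical parameters of the simulated two-sensor agent. The two odor sensors
#' sit at the front of a circular chassis of radius `chassis_radius_cm`
#' (\eqn{\ell_d}), laterally offset by half the sensor separation
#' \eqn{\ell_s/2}: in the body frame their coordinates are
#' \eqn{(\ell_d, \pm\ell_s/2)}. Equivalently each sensor lies at distance
#' \eqn{\sqrt{\ell_d^2 + (\ell_s/2)^2}} from the center at bearing
#' \eqn{\theta \pm \gamma} with \eqn{\gamma = \arctan(\ell_s / (2\ell_d))}.
#' The derived quantities are recomputed on demand (see [sensor_angle()] and
#' [sensor_radius()]) so they can never go stale.
#'
#' @param chassis_radius_cm Chassis radius \eqn{\ell_d} in cm (default 8).
#' @param sensor_sep_cm Inter-sensor distance \eqn{\ell_s} in cm; 8 and 16 are
#'   the typical settings.
#' @param speed_cm_s Forward speed \eqn{v} in cm/s (default 4).
#' @param tick_s Control-loop tick \eqn{\Delta t} in seconds (default 0.1).
#' @param turn_increment_rad Heading change per turn command (default
#'   \eqn{\pi/6}, i.e. 30 degrees per 100-ms turn).
#' @return An object of class `agent_geometry`.
#' @examples
#' g <- agent_geometry(sensor_sep_cm = 16)
#' sensor_angle(g)   # pi/4
#' sensor_radius(g)  # sqrt(128)
#' @export
agent_geometry <- function(chassis_radius_cm = 8, sensor_sep_cm = 8,
                           speed_cm_s = 4, tick_s = 0.1,
                           turn_increment_rad = pi / 6) {
  stopifnot_finite(c(chassis_radius_cm, sensor_sep_cm, speed_cm_s, tick_s,
                     turn_increment_rad), "agent_geometry parameters")
  if (chassis_radius_cm <= 0) stop("chassis_radius_cm must be > 0", call. = FALSE)
  if (sensor_sep_cm < 0) stop("sensor_sep_cm must be >= 0", call. = FALSE)
  if (tick_s <= 0) stop("tick_s must be > 0", call. = FALSE)
  structure(list(chassis_radius_cm = chassis_radius_cm,
                 sensor_sep_cm = sensor_sep_cm,
                 speed_cm_s = speed_cm_s,
                 tick_s = tick_s,
                 turn_increment_rad = turn_increment_rad),
            class = "agent_geometry")
}

#' @rdname agent_geometry
#' @param geometry An `agent_geometry`.
#' @export
sensor_angle <- function(geometry) {
  atan(geometry$sensor_sep_cm / (2 * geometry$chassis_radius_cm))
}

#' @rdname agent_geometry
#' @export
sensor_radius <- function(geometry) {
  sqrt(geometry$chassis_radius_cm^2 + (geometry$sensor_sep_cm / 2)^2)
}

#' @export
print.agent_geometry <- function(x, ...) {
  cat(sprintf(paste0("<agent_geometry> ld=%g cm, ls=%g cm (gamma=%.1f deg),",
                     " v=%g cm/s, tick=%g s\n"),
              x$chassis_radius_cm, x$sensor_sep_cm, rad2deg(sensor_angle(x)),
              x$speed_cm_s, x$tick_s))
  invisible(x)
}

#' Agent pose and clock
#'
#' @param x_cm,y_cm Center position in arena coordinates (cm).
#' @param heading_rad Heading \eqn{\theta} in radians, mathematical
#'   convention; stored wrapped to `[0, 2*pi)`.
#' @param clock_s Elapsed simulated time in seconds.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(x_cm = 0, y_cm = 0, heading_rad = 0, clock_s = 0) {
  stopifnot_finite(c(x_cm, y_cm, heading_rad, clock_s), "agent_state")
  structure(list(x_cm = x_cm, y_cm = y_cm,
                 heading_rad = wrap_2pi(heading_rad), clock_s = clock_s),
            class = "agent_state")
}

#' @export
print.agent_state <- function(x, ...) {
  cat(sprintf("<agent_state> (%.2f, %.2f) cm, heading %.1f deg, t=%.1f s\n",
              x$x_cm, x$y_cm, rad2deg(x$heading_rad), x$clock_s))
  invisible(x)
}

#' Move the agent along its heading
#'
#' Discrete-time kinematic update
#' \eqn{x_{t+\Delta t} = x_t + v\,\Delta t\cos\theta},
#' \eqn{y_{t+\Delta t} = y_t + v\,\Delta t\sin\theta}. A negative speed
#' reverses course (the head-on wall-avoidance backup uses \eqn{v = -4} cm/s).
#' The heading is unchanged and the clock advances by `duration_s`.
#'
#' @param state An [agent_state()].
#' @param geometry An [agent_geometry()].
#' @param speed_cm_s Signed speed in cm/s; defaults to the geometry's speed.
#' @param duration_s Non-negative duration in s; callers keep this an integer
#'   multiple of the tick.
#' @return The displaced `agent_state`.
#' @export
advance <- function(state, geometry, speed_cm_s = geometry$speed_cm_s,
                    duration_s = geometry$tick_s) {
  stopifnot_finite(c(speed_cm_s, duration_s), "advance inputs")
  if (duration_s < 0) stop("duration_s must be >= 0", call. = FALSE)
  agent_state(state$x_cm + speed_cm_s * duration_s * cos(state$heading_rad),
              state$y_cm + speed_cm_s * duration_s * sin(state$heading_rad),
              state$heading_rad,
              state$clock_s + duration_s)
}

#' Turn the agent in place
#'
#' A turn changes the heading by one turn increment (default
#' \eqn{\pm\pi/6}): left is \eqn{\theta + \pi/6}, right is
#' \eqn{\theta - \pi/6}. Turning occupies one 100-ms tick of simulated time;
#' the position is unchanged.
#'
#' @inheritParams advance
#' @param direction `"left"` or `"right"`.
#' @return The rotated `agent_state`.
#' @export
turn <- function(state, direction = c("left", "right"), geometry) {
  direction <- match.arg(direction)
  dtheta <- if (direction == "left") geometry$turn_increment_rad else
    -geometry$turn_increment_rad
  agent_state(state$x_cm, state$y_cm,
              state$heading_rad + dtheta,
              state$clock_s + geometry$tick_s)
}

#' Sensor positions in arena coordinates
#'
#' Both sensors lie at distance [sensor_radius()] from the chassis center at
#' bearings \eqn{\theta + \gamma} (left) and \eqn{\theta - \gamma} (right);
#' equivalently at body-frame coordinates \eqn{(\ell_d, \pm\ell_s/2)}.
#'
#' @inheritParams advance
#' @return A list with numeric `(x, y)` elements `left` and `right`.
#' @examples
#' s <- agent_state(0, 0, 0)
#' sensor_positions(s, agent_geometry(8, 8))  # L = (8, 4), R = (8, -4)
#' @export
sensor_positions <- function(state, geometry) {
  r <- sensor_radius(geometry)
  gam <- sensor_angle(geometry)
  th <- state$heading_rad
  list(left  = c(state$x_cm + r * cos(th + gam),
                 state$y_cm + r * sin(th + gam)),
       right = c(state$x_cm + r * cos(th - gam),
                 state$y_cm + r * sin(th - gam)))
}
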