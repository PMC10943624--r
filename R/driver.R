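# Lateral and longitudinal control of the driver model.
#
# Lateral control has two loops. The high-control loop updates the steering
# angle at every iteration with the two-point law (near/far point bearings).
# The low-control loop is passive: the steering angle is held and the model
# merely monitors the distance to the lane edges; when the car comes within
# `dist` metres of an edge, control escalates to the high loop for `t_hc`
# seconds. Longitudinal control tracks a fictional point moving at the
# current target speed through a time-headway law on the accelerator value.

#' Steering parameters
#'
#' @param k_far,k_near,k_I Two-point steering gains (far-point bearing
#'   change, near-point bearing change, and near-point bearing integral).
#' @param dist Minimal lateral distance to a lane edge (m) that triggers the
#'   high-control loop.
#' @param t_hc Time the model stays in the high-control loop after an
#'   escalation (s).
#' @param motor_noise_sd SD of the zero-mean motor noise (rad) added to each
#'   steering update in the high-control loop.
#' @param max_delta Largest wheel movement a single motor action can apply
#'   (rad); a physical wheel-turn rate limit that keeps delayed updates,
#'   whose percept changes and elapsed time can be large, from slamming the
#'   wheel.
#' @param max_angle Wheel-angle bound (rad) at driving speed.
#' @return List of class `steering_params`.
#' @export
steering_params <- function(k_far = 16, k_near = 4, k_I = 3,
                            dist = 0.5, t_hc = 3,
                            motor_noise_sd = 0.02,
                            max_delta = 0.1, max_angle = 0.6) {
  stopifnot(k_far > 0, k_near > 0, k_I > 0, dist >= 0, t_hc > 0,
            motor_noise_sd >= 0, max_delta > 0, max_angle > 0)
  structure(list(k_far = k_far, k_near = k_near, k_I = k_I,
                 dist = dist, t_hc = t_hc,
                 motor_noise_sd = motor_noise_sd,
                 max_delta = max_delta, max_angle = max_angle),
            class = "steering_params")
}

#' Longitudinal control parameters
#'
#' The model maintains a fixed distance to a fictional point moving at the
#' target speed: the point sits `thw_desired` seconds ahead at the target
#' speed, and the headway variable entering the control law is measured
#' relative to that desired headway (zero when the car holds the target
#' speed at the desired gap).
#'
#' @param k_dthw Gain on the change in time headway between iterations.
#' @param k_thw Gain on the time headway itself (applied per second).
#' @param thw_desired Desired time headway to the fictional point (s).
#' @return List of class `longitudinal_params`.
#' @export
longitudinal_params <- function(k_dthw = 6, k_thw = 1.7, thw_desired = 1) {
  stopifnot(k_dthw > 0, k_thw > 0, thw_desired > 0)
  structure(list(k_dthw = k_dthw, k_thw = k_thw, thw_desired = thw_desired),
            class = "longitudinal_params")
}

#' Two-point steering update (high-control loop)
#'
#' `delta_steer = k_far * dtheta_far + k_near * dtheta_near +
#' k_I * theta_near * dt`: the steering-wheel angle is nudged by the changes
#' in far- and near-point bearings plus an integral correction on the
#' near-point bearing.
#'
#' @param percepts,prev_percepts Lists with `theta_near`, `theta_far` (rad)
#'   from [perceive_points()], at the current and previous iteration.
#' @param params A [steering_params()].
#' @param dt Time since the previous update (s), > 0.
#' @return Steering-angle increment (rad).
#' @export
steer_high_control <- function(percepts, prev_percepts, params, dt) {
  if (dt <= 0) stop("dt must be positive")
  params$k_far * (percepts$theta_far - prev_percepts$theta_far) +
    params$k_near * (percepts$theta_near - prev_percepts$theta_near) +
    params$k_I * percepts$theta_near * dt
}

#' Low-control monitor
#'
#' In the low-control loop the steering angle is held; the model only checks
#' whether the car has come within `dist` metres of either edge of its
#' current lane, in which case control escalates to the high loop.
#'
#' @param v A [vehicle_state()].
#' @param g A [road_geometry()].
#' @param params A [steering_params()].
#' @return `"escalate"` or `"stay_low"`.
#' @export
monitor_low_control <- function(v, g, params) {
  lf <- lane_frame(g, v$lane_index)
  offset <- v$y - lf$center
  edge_dist <- g$lane_width / 2 - abs(offset)
  if (edge_dist < params$dist) "escalate" else "stay_low"
}

#' Longitudinal accelerator update
#'
#' `phi' = clamp(phi + k_dthw * dthw + k_thw * thw * dt, -1, 1)`, where `thw`
#' is the time headway to a fictional point moving at the target speed
#' (measured relative to the desired headway, so 0 at the set point) and
#' `dthw` its change since the previous iteration. At phi = -1 the brake is
#' fully pressed, at +1 the throttle.
#'
#' @param phi Current accelerator value.
#' @param thw Time headway relative to the desired headway (s; negative when
#'   the car is closer than desired, i.e. too fast).
#' @param dthw Change in time headway since the last iteration (s).
#' @param dt Time since the last iteration (s), > 0.
#' @param params A [longitudinal_params()].
#' @return Updated accelerator value in \[-1, 1\].
#' @export
longitudinal_update <- function(phi, thw, dthw, dt, params) {
  if (dt <= 0) stop("dt must be positive")
  min(1, max(-1, phi + params$k_dthw * dthw + params$k_thw * thw * dt))
}

#' Overtaking decision
#'
#' When a slower lead vehicle in the driver's lane comes within the headway
#' threshold and the adjacent left lane is drivable, the steering percepts
#' are re-anchored to the left lane's centre; once past the lead vehicle the
#' driver returns to the right-most free lane. With no free adjacent lane the
#' driver follows at reduced accelerator instead.
#'
#' @param v A [vehicle_state()].
#' @param traffic Data.frame of active leads with columns `x` (longitudinal
#'   position, m), `lane_index`, `speed` (m/s).
#' @param g A [road_geometry()].
#' @param headway_s Initiation threshold on time headway to the lead (s).
#' @param clear_m Longitudinal clearance (m) required past a lead before
#'   returning to its lane.
#' @return List with `target_lane` and `follow` (`TRUE` when boxed in behind
#'   a lead with no free lane).
#' @export
begin_overtake <- function(v, traffic, g, headway_s = 3, clear_m = 25) {
  drivable <- setdiff(seq_len(g$n_lanes) - 1L, g$blocked_lanes)
  # right-most drivable lane not blocked by a nearby lead
  target <- max(drivable)
  follow <- FALSE
  if (nrow(traffic) > 0L) {
    for (lane in sort(drivable, decreasing = TRUE)) {
      in_lane <- traffic[traffic$lane_index == lane, , drop = FALSE]
      ahead <- in_lane[in_lane$x > v$x - clear_m, , drop = FALSE]
      blocking <- any(ahead$x - v$x < headway_s * max(v$speed, 1))
      if (!blocking) { target <- lane; break }
      if (lane == min(drivable)) { # boxed in: follow the lead
        target <- v$lane_index
        follow <- TRUE
      }
    }
  }
  list(target_lane = target, follow = follow)
}
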