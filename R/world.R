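# Road, speed signs, scripted traffic, and single-track vehicle kinematics
# for the two visuospatial conditions (wide highway vs. narrow construction
# site). The road is straight and effectively unbounded; lateral position is
# kept in a global road frame (0 = road centre, positive to the right) and
# converted to a lane-relative offset on demand.

SIGN_SPEEDS <- seq(40, 120, by = 10)

#' Road geometry for one visuospatial condition
#'
#' Three lanes throughout; the highway condition has 3.5-m lanes, the
#' construction condition 2.5-m lanes with the left-most lane blocked off.
#'
#' @param condition `"highway"` or `"construction"`.
#' @param lane_width Override of the lane width in metres (defaults to the
#'   condition's value).
#' @param n_lanes Number of lanes (3).
#' @return A list of class `road_geometry` with fields `condition`,
#'   `lane_width`, `n_lanes`, `blocked_lanes` (0-based from the left),
#'   `centers` (global y of each lane centre) and `boundaries`.
#' @export
road_geometry <- function(condition = c("highway", "construction"),
                          lane_width = NULL, n_lanes = 3L) {
  condition <- match.arg(condition)
  if (is.null(lane_width))
    lane_width <- if (condition == "highway") 3.5 else 2.5
  stopifnot(lane_width > 0, n_lanes >= 1L)
  blocked <- if (condition == "construction") 0L else integer()
  centers <- (seq_len(n_lanes) - 1L - (n_lanes - 1L) / 2) * lane_width
  structure(list(condition = condition, lane_width = lane_width,
                 n_lanes = as.integer(n_lanes), blocked_lanes = blocked,
                 centers = centers,
                 boundaries = c(centers - lane_width / 2,
                                centers[n_lanes] + lane_width / 2)),
            class = "road_geometry")
}

#' Lane frame of a drivable lane
#'
#' @param g A [road_geometry()].
#' @param lane_index 0-based lane index from the left.
#' @return List with `center` (global y, m), `left_edge`, `right_edge`
#'   (offsets relative to the centre, i.e. -w/2 and +w/2).
#' @export
lane_frame <- function(g, lane_index) {
  if (lane_index < 0L || lane_index >= g$n_lanes)
    stop("lane index out of range: ", lane_index)
  if (lane_index %in% g$blocked_lanes)
    stop("lane ", lane_index, " is blocked in the ", g$condition,
         " condition")
  list(center = g$centers[lane_index + 1L],
       left_edge = -g$lane_width / 2, right_edge = g$lane_width / 2)
}

#' Lane index of a global lateral position
#'
#' @param g A [road_geometry()].
#' @param y Global lateral position(s), m.
#' @return Integer lane index (0-based), clamped to the road.
#' @export
lane_of <- function(g, y) {
  idx <- findInterval(y, g$boundaries[-c(1L, length(g$boundaries))])
  pmin(pmax(idx, 0L), g$n_lanes - 1L)
}

#' Generate a block's speed-sign schedule
#'
#' The first sign appears 10 s into the block and subsequent signs every
#' 20 s thereafter; speeds are drawn uniformly from 40-120 km/h in steps of
#' 10, without immediate repetition so that every sign is informative.
#'
#' @param block_duration Block duration (s), > 0.
#' @param seed Optional integer seed for reproducible speed draws.
#' @param allow_repeat If `TRUE`, successive signs may repeat a speed.
#' @return A data.frame with columns `appear_time`, `speed`, `ordinal`
#'   (1-based index of the sign within the block).
#' @export
sign_schedule <- function(block_duration, seed = NULL, allow_repeat = FALSE) {
  stopifnot(block_duration >= 10)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(10, block_duration, by = 20)
  k <- length(times)
  speeds <- numeric(k)
  speeds[1] <- sample(SIGN_SPEEDS, 1L)
  if (k > 1L) for (i in 2:k) {
    pool <- if (allow_repeat) SIGN_SPEEDS
            else SIGN_SPEEDS[SIGN_SPEEDS != speeds[i - 1]]
    speeds[i] <- pool[sample.int(length(pool), 1L)]
  }
  data.frame(appear_time = times, speed = speeds, ordinal = seq_len(k))
}

#' Initial vehicle state
#'
#' @param g A [road_geometry()].
#' @param lane_index Starting lane (defaults to the right-most drivable).
#' @param speed_kmh Initial speed, km/h.
#' @return A list of class `vehicle_state`: global lateral position `y` (m),
#'   `heading` (rad), `speed` (m/s), `x` longitudinal position (m),
#'   `steer_angle` (rad, steering-wheel angle, 0 = centred), `phi`
#'   (accelerator value in \[-1, 1\]; -1 full brake, +1 full throttle) and
#'   `lane_index`.
#' @export
vehicle_state <- function(g, lane_index = NULL, speed_kmh = 80) {
  if (is.null(lane_index)) lane_index <- g$n_lanes - 1L
  lf <- lane_frame(g, lane_index)
  structure(list(y = lf$center, heading = 0, speed = speed_kmh / 3.6,
                 x = 0, steer_angle = 0, phi = 0,
                 lane_index = as.integer(lane_index)),
            class = "vehicle_state")
}

#' World physics constants
#'
#' Simple kinematic single-track model; the gains translate the accelerator
#' value phi into longitudinal acceleration and the steering-wheel angle into
#' yaw rate via `heading' = speed / wheelbase * steer / steer_ratio`.
#'
#' @param wheelbase m.
#' @param a_throttle Maximum throttle acceleration, m/s^2 (phi = +1).
#' @param a_brake Maximum braking deceleration, m/s^2 (phi = -1).
#' @param steer_ratio Steering-wheel to road-wheel ratio.
#' @param dt Internal physics step (s); 5 ms, i.e. the 200-Hz trace rate.
#' @param crosswind_sd Heading disturbance, rad per sqrt(s); the random-walk
#'   noise that makes an uncorrected vehicle drift in its lane.
#' @return List of class `world_params`.
#' @export
world_params <- function(wheelbase = 2.5, a_throttle = 3, a_brake = 6,
                         steer_ratio = 20, dt = 0.005,
                         crosswind_sd = 0.004) {
  stopifnot(wheelbase > 0, a_throttle > 0, a_brake > 0, steer_ratio > 0,
            dt > 0, crosswind_sd >= 0)
  structure(list(wheelbase = wheelbase, a_throttle = a_throttle,
                 a_brake = a_brake, steer_ratio = steer_ratio, dt = dt,
                 crosswind_sd = crosswind_sd),
            class = "world_params")
}

#' Advance the vehicle kinematics
#'
#' Integrates the single-track kinematics over `dt` with the current controls
#' held constant: `speed' = phi * a`, `heading' = speed / wheelbase * steer /
#' steer_ratio (+ disturbance)`, `y' = speed * sin(heading)`,
#' `x' = speed * cos(heading)`. The lane index is re-derived from the global
#' lateral position after the step.
#'
#' @param v A [vehicle_state()].
#' @param dt Time step (s), > 0.
#' @param g A [road_geometry()].
#' @param wp A [world_params()].
#' @param disturbance Heading increment (rad) added over the step.
#' @return The advanced `vehicle_state`.
#' @export
advance_vehicle <- function(v, dt, g, wp = world_params(), disturbance = 0) {
  if (dt <= 0) stop("dt must be positive")
  a <- if (v$phi >= 0) wp$a_throttle else wp$a_brake
  v$speed <- max(0, v$speed + v$phi * a * dt)
  v$heading <- v$heading +
    v$speed / wp$wheelbase * (v$steer_angle / wp$steer_ratio) * dt +
    disturbance
  v$y <- v$y + v$speed * sin(v$heading) * dt
  v$x <- v$x + v$speed * cos(v$heading) * dt
  v$lane_index <- lane_of(g, v$y)
  v
}

#' Perceive the near- and far-point bearings
#'
#' The two-point steering percepts: bearings, relative to the current
#' heading, of the target-lane centre points 10 m (near) and 100 m (far)
#' ahead of the car.
#'
#' @param v A [vehicle_state()].
#' @param g A [road_geometry()].
#' @param target_lane Lane whose centre anchors the points (defaults to the
#'   vehicle's current lane).
#' @param near_dist,far_dist Look-ahead distances (m), 10 and 100.
#' @return List with `theta_near` and `theta_far` (rad; positive = target to
#'   the right of the heading).
#' @export
perceive_points <- function(v, g, target_lane = v$lane_index,
                            near_dist = 10, far_dist = 100) {
  center <- lane_frame(g, target_lane)$center
  off <- center - v$y
  list(theta_near = atan2(off, near_dist) - v$heading,
       theta_far = atan2(off, far_dist) - v$heading)
}

#' Script the block's lead vehicles
#'
#' Two to three slower lead vehicles per block, each appearing at a seeded
#' time a fixed distance ahead of the driver in the right-most drivable lane
#' and moving at a fraction of the prevailing speed limit, which makes an
#' overtaking manoeuvre necessary roughly 2-3 times per block.
#'
#' @param block_duration Block duration (s).
#' @param seed Optional integer seed.
#' @param enabled If `FALSE`, returns an empty script.
#' @param ahead_m Spawn distance ahead of the driver (m).
#' @param speed_frac Lead speed as a fraction of the current limit.
#' @return Data.frame `appear_time`, `ahead_m`, `speed_frac`.
#' @export
spawn_traffic <- function(block_duration, seed = NULL, enabled = TRUE,
                          ahead_m = 130, speed_frac = 0.55) {
  empty <- data.frame(appear_time = numeric(), ahead_m = numeric(),
                      speed_frac = numeric())
  if (!enabled) return(empty)
  if (!is.null(seed)) set.seed(seed)
  n <- sample(2:3, 1L)
  # spread the appearances over the block with jitter, none in the final 30 s
  span <- max(block_duration - 30, 1)
  t0 <- sort(stats::runif(n, min = 5, max = span))
  data.frame(appear_time = t0, ahead_m = rep(ahead_m, n),
             speed_frac = rep(speed_frac, n))
}
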