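# Run configuration: nested defaults, YAML loading with strict validation.
# Every tunable of the simulator lives here so that experiments are fully
# described by (config, variant, master seed).

#' Default run configuration
#'
#' Returns the full nested configuration with the model's default parameter
#' values: world kinematics, steering and longitudinal control, declarative
#' memory, n-back rehearsal schedule, and experiment design constants.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    variant = "problem_state",
    world = list(
      wheelbase = 2.5,            # m
      a_throttle = 3,             # m/s^2 at phi = +1
      a_brake = 6,                # m/s^2 at phi = -1
      steer_ratio = 20,           # steering wheel : road wheels (yaw-gain scale)
      dt = 0.005,                 # s; 200 Hz trace rate
      crosswind_sd = 0.004,       # rad / sqrt(s) heading disturbance
      n_lanes = 3L,
      lane_width_highway = 3.5,   # m
      lane_width_construction = 2.5,
      traffic_enabled = TRUE,
      traffic_ahead_m = 130,
      traffic_speed_frac = 0.55),
    steering = list(
      k_far = 16, k_near = 4, k_I = 3,
      dist_highway = 0.8,         # m; edge margin triggering high control
      dist_construction = 0.5,
      t_hc = 3,                   # s; dwell in the high-control loop
      motor_noise_sd = 0.02,      # rad per steering update
      max_delta = 0.1,            # rad; wheel movement per motor action
      max_angle = 0.6),           # rad; wheel-angle bound at speed
    longitudinal = list(
      k_dthw = 6, k_thw = 1.7, thw_desired = 1),
    memory = list(
      d = 0.5, rt = -10, mp = 16, s = 0.25,
      F = 0.2, latency_cap = 1.0,
      similarity_step = -0.1, adjacent_zero = FALSE),
    nback = list(
      rehearsals = c(0L, 1L, 1L, 2L, 2L),  # cycles for n = 0..4
      drive_productions = 3L),    # productions per driving-loop iteration
    cognition = list(
      visual_encode = 0.085,      # s; visual module encoding a percept
      motor_exec = 0.150),        # s; executing a steering/pedal movement
    experiment = list(
      exp_duration = 160,         # s of experimental phase per block
      replicates = 22L,           # simulated participants
      initial_speed_kmh = 80)
  ), class = "run_config")
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: ", here)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]]))
        stop("configuration key ", here, " must be a mapping")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate a run configuration
#'
#' Checks types, ranges and cross-field constraints; called by
#' [load_config()] and by the simulator entry points.
#'
#' @param cfg A configuration list.
#' @return `cfg`, invisibly, after validation.
#' @export
validate_config <- function(cfg) {
  fail <- function(...) stop("invalid configuration: ", ..., call. = FALSE)
  if (!cfg$variant %in% c("central", "problem_state"))
    fail("variant must be 'central' or 'problem_state'")
  w <- cfg$world
  if (w$lane_width_highway <= 0 || w$lane_width_construction <= 0)
    fail("lane widths must be positive")
  if (w$n_lanes < 2) fail("need at least 2 lanes")
  if (w$dt <= 0) fail("world.dt must be positive")
  if (w$wheelbase <= 0 || w$a_throttle <= 0 || w$a_brake <= 0 ||
      w$steer_ratio <= 0)
    fail("world kinematic constants must be positive")
  s <- cfg$steering
  if (s$k_far <= 0 || s$k_near <= 0 || s$k_I <= 0)
    fail("steering gains must be positive")
  if (s$dist_highway < 0 || s$dist_highway >= w$lane_width_highway / 2 ||
      s$dist_construction < 0 ||
      s$dist_construction >= w$lane_width_construction / 2)
    fail("steering dist margins must lie in [0, lane_width/2)")
  if (s$t_hc <= 0) fail("steering.t_hc must be positive")
  l <- cfg$longitudinal
  if (l$k_dthw <= 0 || l$k_thw <= 0) fail("longitudinal gains must be positive")
  m <- cfg$memory
  if (m$d <= 0 || m$mp < 0 || m$s < 0 || m$F <= 0)
    fail("memory parameters out of range")
  nb <- cfg$nback
  if (length(nb$rehearsals) != 5L || any(nb$rehearsals < 0))
    fail("nback.rehearsals must be 5 non-negative counts (n = 0..4)")
  if (nb$drive_productions < 2L)
    fail("nback.drive_productions must be at least 2")
  cg <- cfg$cognition
  if (cg$visual_encode < 0 || cg$motor_exec < 0)
    fail("cognition latencies must be non-negative")
  e <- cfg$experiment
  if (e$exp_duration < 20) fail("experiment.exp_duration too short")
  if (e$replicates < 1) fail("experiment.replicates must be >= 1")
  invisible(cfg)
}

#' Load a configuration from YAML
#'
#' Reads a YAML file of overrides, merges it onto [default_config()]
#' (rejecting unknown keys with their full path) and validates the result.
#' An empty file yields the defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    ov <- yaml::read_yaml(path)
    if (!is.null(ov)) cfg <- merge_config(cfg, ov)
  }
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}
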