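# Synthetic test fixtures with machine-readable ground truth: planted
# steering reversals, scripted lane excursions, injected pupil artifacts and
# speed profiles with known compliance.

#' Generate a synthetic fixture with known ground truth
#'
#' @param kind One of `"reversals"`, `"lane_change"`, `"pupil_artifacts"`,
#'   `"speed_profile"`.
#' @param params Named list of kind-specific parameters (all optional):
#'   * reversals: `k` crossings, `duration` (s), `rate_hz` sample rate.
#'   * lane_change: `hold_s` dwell in the adjacent lane, `t_cross`,
#'     `duration`.
#'   * pupil_artifacts: `n_spikes`, `duration`, `rate_hz`, `amp_sd` spike
#'     amplitude in SDs.
#'   * speed_profile: `targets` (km/h per interval), `offsets` (mean driven
#'     deviation per interval, km/h), `interval_s`.
#' @param seed Optional integer seed.
#' @return List with `trace` (or `pupil`) and `truth` (the planted ground
#'   truth sidecar).
#' @export
generate_fixture <- function(kind, params = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  switch(kind,
    reversals = fixture_reversals(params),
    lane_change = fixture_lane_change(params),
    pupil_artifacts = fixture_pupil(params),
    speed_profile = fixture_speed(params),
    stop("unknown fixture kind: ", kind))
}

fixture_reversals <- function(p) {
  k <- p$k %||% 5L
  duration <- p$duration %||% 10
  rate <- p$rate_hz %||% 200
  tt <- seq(1 / rate, duration, by = 1 / rate)
  nrow <- length(tt)
  # piecewise-constant angle alternating sign across k planted crossings
  cross_t <- sort(stats::runif(k, 0.5, duration - 0.5))
  seg <- findInterval(tt, cross_t)
  angle <- ifelse(seg %% 2 == 0, 0.08, -0.08) +
    stats::rnorm(nrow, 0, 0.0005)
  trace <- data.frame(time_s = tt, lat_pos_m = 0, lane_index = 2L,
                      steer_angle_rad = angle, phi = 0, speed_kmh = 80,
                      long_pos_m = tt * 80 / 3.6)
  list(trace = trace, truth = list(kind = "reversals", crossings = cross_t,
                                   k = k, duration = duration))
}

fixture_lane_change <- function(p) {
  hold <- p$hold_s %||% 8
  t_cross <- p$t_cross %||% 50
  duration <- p$duration %||% 160
  rate <- 200
  tt <- seq(1 / rate, duration, by = 1 / rate)
  lane <- rep(2L, length(tt))
  lane[tt >= t_cross & tt < t_cross + hold] <- 1L
  trace <- data.frame(time_s = tt, lat_pos_m = 0, lane_index = lane,
                      steer_angle_rad = 0.01, phi = 0, speed_kmh = 80,
                      long_pos_m = tt * 80 / 3.6)
  list(trace = trace,
       truth = list(kind = "lane_change", t_cross = t_cross, hold_s = hold,
                    is_lane_change = hold >= 5))
}

fixture_pupil <- function(p) {
  n_spikes <- p$n_spikes %||% 3L
  duration <- p$duration %||% 30
  rate <- p$rate_hz %||% 500
  amp_sd <- p$amp_sd %||% 6
  tt <- seq(1 / rate, duration, by = 1 / rate)
  nr <- length(tt)
  clean <- 4 + 0.3 * sin(2 * pi * tt / 11) + 0.1 * sin(2 * pi * tt / 3.7)
  x <- clean + stats::rnorm(nr, 0, 3e-04)
  sdv <- stats::sd(x)
  idx <- sort(sample(seq(200L, nr - 200L), n_spikes))
  x[idx] <- mean(x) + amp_sd * sdv
  fixations <- data.frame(start = min(tt), end = max(tt))
  list(pupil = pupil_trace(tt, x, fixations = fixations),
       clean = clean,
       truth = list(kind = "pupil_artifacts", spike_idx = idx,
                    amp_sd = amp_sd))
}

fixture_speed <- function(p) {
  targets <- p$targets %||% c(80, 100, 60)
  offsets <- p$offsets %||% c(2, -7, 4)
  interval_s <- p$interval_s %||% 20
  stopifnot(length(targets) == length(offsets))
  rate <- 200
  k <- length(targets)
  tt <- seq(1 / rate, k * interval_s, by = 1 / rate)
  iv <- pmin(findInterval(tt, seq(0, by = interval_s,
                                  length.out = k + 1L)), k)
  speed <- targets[iv] + offsets[iv]
  trace <- data.frame(time_s = tt, lat_pos_m = 0, lane_index = 2L,
                      steer_angle_rad = 0.01, phi = 0, speed_kmh = speed,
                      long_pos_m = cumsum(speed / 3.6) / rate)
  signs <- data.frame(appear_time = seq(0, by = interval_s,
                                        length.out = k),
                      speed = targets, ordinal = seq_len(k))
  list(trace = trace, signs = signs,
       truth = list(kind = "speed_profile",
                    correct = abs(offsets) <= 5))
}

#' Write a fixture to disk
#'
#' Writes the trace (or pupil samples) as CSV and the ground-truth sidecar
#' as JSON next to it.
#'
#' @param fx A fixture from [generate_fixture()].
#' @param stem Path stem; `<stem>.csv` and `<stem>_truth.json` are written.
#' @export
write_fixture <- function(fx, stem) {
  if (!is.null(fx$trace)) {
    write_trace_csv(fx$trace, paste0(stem, ".csv"))
  } else {
    utils::write.csv(data.frame(time_s = fx$pupil$time_s,
                                diameter = fx$pupil$diameter),
                     paste0(stem, ".csv"), row.names = FALSE)
  }
  jsonlite::write_json(fx$truth, paste0(stem, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
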