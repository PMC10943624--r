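make_trace <- function(duration = 160, rate = 200, lane = 2L) {
  tt <- seq(1 / rate, duration, by = 1 / rate)
  data.frame(time_s = tt, lat_pos_m = 0, lane_index = lane,
             steer_angle_rad = 0, phi = 0, speed_kmh = 80,
             long_pos_m = tt * 80 / 3.6)
}

test_that("lane-change detection applies the 5-second adjacency rule", {
  tr <- make_trace()
  tr$lane_index[tr$time_s >= 50 & tr$time_s < 58] <- 1L   # held 8 s
  # the excursion and the later return are both genuine lane changes
  expect_equal(detect_lane_changes(tr), c(50, 58), tolerance = 0.01)
  tr2 <- make_trace()
  tr2$lane_index[tr2$time_s >= 50 & tr2$time_s < 53] <- 1L  # held 3 s
  expect_equal(length(detect_lane_changes(tr2)), 0L)
  expect_equal(length(detect_lane_changes(make_trace())), 0L)
})

test_that("masking removes 6-s windows, merges overlaps, and reduces duration", {
  tr <- make_trace(160)
  m1 <- mask_segments(tr, 80)
  expect_equal(sum(!m1$excluded) / 200, 154, tolerance = 0.02)
  # overlapping windows merge rather than double-count
  m2 <- mask_segments(tr, c(80, 82))
  expect_equal(sum(m2$excluded) / 200, 8, tolerance = 0.02)
  m0 <- mask_segments(tr, numeric(0))
  expect_false(any(m0$excluded))
  # monotonicity: adding an exclusion never increases retained duration
  expect_lte(sum(!m2$excluded), sum(!m1$excluded))
})

test_that("steering reversals count centre crossings over retained time", {
  tr <- make_trace(10)
  # the printed example: 3 sign changes
  angles <- c(0.1, -0.1, 0.2, 0.3, -0.05)
  tr$steer_angle_rad <- rep(angles, length.out = nrow(tr))[
    order(rep(seq_along(angles), length.out = nrow(tr)))]
  tr5 <- data.frame(time_s = 1:5, lat_pos_m = 0, lane_index = 2L,
                    steer_angle_rad = angles, phi = 0, speed_kmh = 80,
                    long_pos_m = 1:5)
  expect_equal(steering_reversal_rate(tr5) * 5, 3)
  # constant positive angle: no reversals
  trc <- make_trace(10); trc$steer_angle_rad <- 0.2
  expect_equal(steering_reversal_rate(trc), 0)
  # 3 crossings over 10 s retained = 0.3 per second
  fx <- generate_fixture("reversals", list(k = 3, duration = 10), seed = 2)
  expect_equal(steering_reversal_rate(fx$trace), 0.3, tolerance = 1e-6)
})

test_that("reversal counts match a brute-force scan on random fixtures", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 1000
    ang <- stats::rnorm(n, 0, 0.05)
    tr <- data.frame(time_s = seq_len(n) / 200, lat_pos_m = 0,
                     lane_index = 2L, steer_angle_rad = ang, phi = 0,
                     speed_kmh = 80, long_pos_m = seq_len(n))
    # brute force: walk the samples, track last definite sign
    eps <- 0.005
    last <- 0; count <- 0
    for (a in ang) {
      if (abs(a) < eps) next
      s <- sign(a)
      if (last != 0 && s != last) count <- count + 1
      last <- s
    }
    expect_equal(steering_reversal_rate(tr) * n / 200, count)
  }
})

test_that("reversals are not counted across excluded gaps", {
  tr <- make_trace(20)
  tr$steer_angle_rad <- ifelse(tr$time_s < 10, 0.1, -0.1)  # one crossing
  m <- mask_segments(tr, 10)   # mask the crossing region
  expect_equal(steering_reversal_rate(m), 0)
})

test_that("lane deviation is the mean absolute offset over retained samples", {
  tr <- make_trace(10)
  tr$lat_pos_m <- 0.3
  expect_equal(lane_deviation(tr), 0.3)
  tr$lat_pos_m <- rep(c(0.2, -0.2), length.out = nrow(tr))
  expect_equal(lane_deviation(tr), 0.2)
  tr$lat_pos_m <- 0
  expect_equal(lane_deviation(tr), 0)
})

test_that("speed compliance scores intervals against the n-back ground truth", {
  fx <- generate_fixture("speed_profile",
                         list(targets = c(80, 100, 60),
                              offsets = c(4, -7, 2)), seed = 1)
  sc <- score_speed_compliance(fx$trace, fx$signs, n = 0)
  expect_equal(sc$intervals$correct, c(TRUE, FALSE, TRUE))
  expect_equal(sc$error_rate, 1 / 3)
  # |84 - 80| <= 5 correct, |86 - 80| > 5 incorrect
  fx2 <- generate_fixture("speed_profile",
                          list(targets = c(80, 80), offsets = c(4, 6)))
  sc2 <- score_speed_compliance(fx2$trace, fx2$signs, n = 0,
                                grace = 1)
  expect_equal(sc2$intervals$correct, c(TRUE, FALSE))
  # scoring is against the true target: holding a wrong speed is an error
  fx3 <- generate_fixture("speed_profile",
                          list(targets = c(80, 100), offsets = c(0, -20)))
  sc3 <- score_speed_compliance(fx3$trace, fx3$signs, n = 0)
  expect_false(sc3$intervals$correct[2])
  expect_error(score_speed_compliance(fx3$trace, fx3$signs[0, ], 0))
})

test_that("bottleneck cost averages summed delays over inter-sign intervals", {
  delays <- data.frame(
    time_s = c(12, 25, 31), production = "p", goal = "drive",
    requested_s = c(11.8, 24.9, 30.9),
    cause = c("problem_state_busy", "problem_state_busy",
              "procedural_contention"),
    delay_s = c(0.2, 0.1, 0.1))
  expect_equal(bottleneck_cost(delays, c(10, 30, 50)), 0.2)
  expect_equal(bottleneck_cost(delays, c(10, 30, 50),
                               cause = "problem_state_busy"), 0.15)
  expect_equal(bottleneck_cost(delays[0, ], c(10, 30)), 0)
  expect_error(bottleneck_cost(delays, 10), "two signs")
})

test_that("fit metrics reproduce the RMSE and R-squared definitions", {
  expect_equal(fit_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(rmse = 0, r2 = 1))
  expect_equal(fit_metrics(c(1, 2), c(1, 4))$rmse, sqrt(2))
  # translation invariance of RMSE
  a <- c(0.3, 0.5, 0.7, 0.4); b <- c(0.35, 0.45, 0.65, 0.5)
  expect_equal(fit_metrics(a + 1, b + 1)$rmse, fit_metrics(a, b)$rmse)
  expect_error(fit_metrics(c(1, 2), c(3, 3)), "zero variance")
})

test_that("metrics are invariant to a shift of the trace time origin", {
  fx <- generate_fixture("reversals", list(k = 4, duration = 20), seed = 3)
  tr <- fx$trace
  tr2 <- tr; tr2$time_s <- tr2$time_s + 100
  expect_equal(steering_reversal_rate(tr2), steering_reversal_rate(tr))
  expect_equal(lane_deviation(tr2), lane_deviation(tr))
})
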