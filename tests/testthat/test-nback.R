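noise_off <- function(...) retrieval_params(s = 0, ...)

test_that("signs encode as a backward linked list with distinct episodic tags", {
  st <- memory_store_new()
  ns <- nback_state(2, "central")
  c1 <- encode_sign(80, 1, ns, st, 10)
  expect_true(is.na(c1$previous_id))
  c2 <- encode_sign(80, 2, ns, st, 30)   # same speed, new episode
  c3 <- encode_sign(50, 3, ns, st, 50)
  expect_equal(c3$previous_id, c2$id)
  expect_equal(c2$previous_id, c1$id)
  expect_false(c1$id == c2$id)
  # chunks enter declarative memory on release, not at encode time
  expect_equal(length(st$id), 2L)        # c1, c2 released by later encodes
  expect_equal(ns$ps_chunk$id, c3$id)
})

test_that("sequential recall walks the linked list to the n-th sign back", {
  st <- memory_store_new()
  ns <- nback_state(2, "central")
  speeds <- c(80, 50, 110, 70)
  for (i in seq_along(speeds)) encode_sign(speeds[i], i, ns, st, i * 20)
  res <- recall_nback(2, ns, st, noise_off(), 81)
  expect_false(res$failed)
  expect_equal(res$speed, 50)            # two signs back from sign 4
  expect_equal(length(res$swap_times), 2L)
  # 0-back returns the problem-state sign with zero retrievals
  ns0 <- nback_state(0, "central")
  st0 <- memory_store_new()
  encode_sign(90, 1, ns0, st0, 10)
  r0 <- recall_nback(0, ns0, st0, noise_off(), 11)
  expect_equal(r0$speed, 90)
  expect_equal(length(r0$swap_times), 0L)
})

test_that("with noise, recall sometimes returns a neighbouring sign's speed", {
  set.seed(3)
  wrong <- 0; total <- 0
  for (rep in 1:60) {
    st <- memory_store_new()
    ns <- nback_state(2, "central")
    speeds <- sample(seq(40, 120, 10), 6)
    for (i in seq_along(speeds)) encode_sign(speeds[i], i, ns, st, i * 20)
    res <- recall_nback(2, ns, st, retrieval_params(s = 0.4, mp = 5), 121)
    if (!res$failed) {
      total <- total + 1
      if (res$speed != speeds[4]) wrong <- wrong + 1
    }
  }
  expect_gt(wrong, 0)
  expect_lt(wrong, total)   # errors are confusions, not the rule
})

test_that("rehearsal repeats the sequential walk and boosts activations", {
  st <- memory_store_new()
  ns <- nback_state(3, "central", rehearsals = 2L)
  for (i in 1:5) encode_sign(40 + 10 * i, i, ns, st, i * 20)
  recall_nback(3, ns, st, noise_off(), 101)
  before <- length(unlist(st$times))
  rh <- rehearse(3, 2, ns, st, noise_off(), 105)
  expect_equal(length(rh$swap_times), 6L)   # 2 cycles x 3 swaps
  expect_gt(length(unlist(st$times)), before)
  # rehearsed chunks carry higher activation than equal-age unrehearsed ones
  st2 <- memory_store_new()
  a <- sign_chunk("a", NULL, 80, 0, 1); b <- sign_chunk("b", "a", 90, 0, 2)
  record_presentation(st2, a, 0)
  record_presentation(st2, b, 0)
  record_presentation(st2, a, 10)           # one rehearsal of a
  expect_gt(base_level_activation(st2$times[[1]], 20),
            base_level_activation(st2$times[[2]], 20))
})

test_that("rehearsal walks nothing when no predecessors exist", {
  st <- memory_store_new()
  ns <- nback_state(1, "central", rehearsals = 1L)
  encode_sign(80, 1, ns, st, 10)
  rh <- rehearse(0, 1, ns, st, noise_off(), 12)
  expect_equal(length(rh$swap_times), 0L)
})

test_that("the goal transfer frees the problem state and keeps the speed", {
  st <- memory_store_new()
  ns <- nback_state(0, "central")
  encode_sign(80, 1, ns, st, 10)
  update_target_speed(80, ns, st, 10.3)
  expect_equal(ns$goal_speed, 80)
  expect_null(ns$ps_chunk)
  expect_equal(length(st$id), 1L)        # released to declarative memory
  # a failed recall leaves the goal buffer unchanged
  update_target_speed(NA_real_, ns)
  expect_equal(ns$goal_speed, 80)
})

test_that("driving is gated on the problem state only in that variant", {
  ns <- nback_state(2, "problem_state")
  ns$ps_busy_until <- 5.15
  g1 <- gate_driving("problem_state", ns, 5.0)
  expect_false(g1$allow)
  expect_equal(g1$until, 5.15)
  g2 <- gate_driving("central", ns, 5.0)
  expect_true(g2$allow)
  g3 <- gate_driving("problem_state", ns, 5.2)
  expect_true(g3$allow)
})

test_that("each problem-state swap busies the buffer for 200 ms", {
  st <- memory_store_new()
  ns <- nback_state(2, "problem_state")
  for (i in 1:4) encode_sign(40 + 10 * i, i, ns, st, i * 20)
  expect_equal(ns$ps_busy_until, 80 + 0.2)
  res <- recall_nback(2, ns, st, noise_off(), 81)
  expect_equal(ns$ps_busy_until, max(res$swap_times) + 0.2)
})

test_that("per-recall production effort grows linearly in n", {
  # productions per complete recall: one request + one harvest per step
  cfg <- default_config()
  cfg$world$traffic_enabled <- FALSE
  counts <- vapply(c(1, 3), function(n) {
    b <- sim_block("construction", n, "central", cfg, world_seed = 5,
                   cog_seed = 6, exp_duration = 60)
    d <- b$delays
    sum(d$production %in% c("request-retrieval", "harvest-retrieval") &
        d$time_s >= b$exp_start) / 3   # three experimental signs
  }, numeric(1))
  # slope: rehearsal cycles included, effort strictly increases with n
  expect_gt(counts[2], counts[1])
})
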