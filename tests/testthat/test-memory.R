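test_that("base-level activation matches direct evaluation of the decay sum", {
  # printed examples
  expect_equal(base_level_activation(0, 1, 0.5), 0)
  expect_equal(base_level_activation(c(0, 2), 4, 0.5),
               log(2^-0.5 + 4^-0.5))
  # random histories against an independent elementwise evaluation
  set.seed(1)
  for (i in 1:50) {
    times <- sort(stats::runif(sample(1:8, 1), 0, 100))
    t_now <- max(times) + stats::runif(1, 0.1, 50)
    d <- stats::runif(1, 0.2, 0.9)
    oracle <- log(sum(vapply(times, function(tj) (t_now - tj)^(-d),
                             numeric(1))))
    expect_equal(base_level_activation(times, t_now, d), oracle,
                 tolerance = 1e-12)
  }
  expect_error(base_level_activation(numeric(0), 1), "empty")
  expect_error(base_level_activation(c(1, 2), 2), "later")
})

test_that("activation decays between presentations and jumps at each one", {
  tt <- seq(2, 30, by = 0.5)
  a1 <- vapply(tt, function(t) base_level_activation(1, t), numeric(1))
  expect_true(all(diff(a1) < 0))
  before <- base_level_activation(1, 9.99)
  after <- base_level_activation(c(1, 10), 10.01)
  expect_gt(after, before)
})

test_that("presentations merge by episodic id and reject non-monotone times", {
  st <- memory_store_new()
  ch <- sign_chunk("sign-001", NULL, 80, 10, 1)
  record_presentation(st, ch, 10)
  expect_equal(st$times[[1]], 10)
  record_presentation(st, ch, 30)
  expect_equal(st$times[[1]], c(10, 30))
  expect_equal(length(st$id), 1L)
  # distinct episodic tags with the same speed stay separate
  ch2 <- sign_chunk("sign-002", "sign-001", 80, 50, 2)
  record_presentation(st, ch2, 50)
  expect_equal(length(st$id), 2L)
  expect_error(record_presentation(st, ch, 5), "non-monotone")
})

test_that("similarity is 0 for the same sign and falls by 0.1 per position", {
  expect_equal(sign_similarity(3, 3), 0)
  for (k in 1:5)
    expect_equal(sign_similarity(1, 1 + k) - sign_similarity(1, k + 2), 0.1)
  expect_equal(sign_similarity(2, 5), sign_similarity(5, 2))
  # alternative reading: adjacent signs fully similar, same per-step decrement
  expect_equal(sign_similarity(1, 2, adjacent_zero = TRUE), 0)
  expect_equal(sign_similarity(1, 4, adjacent_zero = TRUE) -
               sign_similarity(1, 5, adjacent_zero = TRUE), 0.1)
})

test_that("noise-free retrieval equals a brute-force argmax oracle", {
  set.seed(7)
  for (rep in 1:20) {
    st <- memory_store_new()
    nch <- sample(3:8, 1)
    speeds <- sample(seq(40, 120, 10), nch, replace = TRUE)
    for (i in seq_len(nch)) {
      ch <- sign_chunk(sprintf("s%02d", i),
                       if (i == 1) NULL else sprintf("s%02d", i - 1),
                       speeds[i], i * 20, i)
      record_presentation(st, ch, i * 20)
      if (stats::runif(1) < 0.5)
        record_presentation(st, ch, i * 20 + stats::runif(1, 1, 5))
    }
    t_now <- nch * 20 + 10
    target <- sample(nch, 1)
    pars <- retrieval_params(s = 0)
    res <- retrieve(st, sprintf("s%02d", target), pars, t_now)
    # independent scoring
    scores <- vapply(seq_len(nch), function(i) {
      log(sum((t_now - st$times[[i]])^(-pars$d))) +
        pars$mp * pars$similarity_step * abs(i - target)
    }, numeric(1))
    expect_false(res$failed)
    expect_equal(res$chunk$id, st$id[which.max(scores)])
    expect_equal(res$score, max(scores), tolerance = 1e-12)
    expect_equal(res$latency,
                 min(pars$F * exp(-max(scores)), pars$latency_cap))
  }
})

test_that("retrieval from an empty store fails; below-threshold scores fail", {
  pars <- retrieval_params(s = 0)
  expect_true(retrieve(memory_store_new(), "x", pars, 1)$failed)
  st <- memory_store_new()
  record_presentation(st, sign_chunk("s1", NULL, 80, 0, 1), 0)
  strict <- retrieval_params(s = 0, rt = 10)  # unreachable threshold
  expect_true(retrieve(st, "s1", strict, 100)$failed)
})

test_that("retrieval error rate is non-decreasing in the noise scale", {
  build <- function() {
    st <- memory_store_new()
    for (i in 1:5) {
      ch <- sign_chunk(sprintf("s%d", i),
                       if (i == 1) NULL else sprintf("s%d", i - 1),
                       40 + 10 * i, i * 20, i)
      record_presentation(st, ch, i * 20)
    }
    st
  }
  err <- vapply(c(0, 0.3, 0.8, 2), function(s) {
    st <- build()
    pars <- retrieval_params(s = s, mp = 5)
    set.seed(123)
    mean(vapply(1:300, function(i)
      retrieve(st, "s3", pars, 115)$chunk$id != "s3", logical(1)))
  }, numeric(1))
  expect_true(all(diff(err) >= 0))
})

test_that("a 2-step-back target is confused more often than a 1-step-back one", {
  # graded similarity penalties shrink per unit time: deeper targets sit in
  # a flatter activation landscape and lose more often under noise
  pars <- retrieval_params(s = 0.4, mp = 5)
  run <- function(target_id) {
    st <- memory_store_new()
    for (i in 1:6) {
      ch <- sign_chunk(sprintf("s%d", i),
                       if (i == 1) NULL else sprintf("s%d", i - 1),
                       40 + 10 * i, i * 20, i)
      record_presentation(st, ch, i * 20)
    }
    mean(vapply(1:400, function(i)
      retrieve(st, target_id, pars, 125)$chunk$id != target_id, logical(1)))
  }
  set.seed(9)
  e1 <- run("s5")  # one step back from the most recent sign
  e2 <- run("s4")  # two steps back
  expect_gt(e2, e1)
})

test_that("store dump and load round-trip losslessly", {
  st <- memory_store_new()
  record_presentation(st, sign_chunk("s1", NULL, 80, 0, 1), 0)
  record_presentation(st, sign_chunk("s2", "s1", 80, 20, 2), 20)
  record_presentation(st, sign_chunk("s1", NULL, 80, 0, 1), 33.5)
  path <- tempfile(fileext = ".jsonl")
  memory_dump(st, path)
  st2 <- memory_load(path)
  expect_equal(st2$id, st$id)
  expect_equal(st2$previous_id, st$previous_id)
  expect_equal(st2$speed, st$speed)
  expect_equal(st2$times, st$times)
  unlink(path)
})
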