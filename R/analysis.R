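# Behavioral metrics: lane-change detection with the 5-s adjacency rule,
# 6-s exclusion masking, steering reversal rate, lane deviation,
# speed-compliance scoring (+/- 5 km/h), bottleneck cost per inter-sign
# interval, and the RMSE / R^2 model-fit statistics.

#' Detect lane changes in a trace
#'
#' A crossing of the lane markings counts as a lane change only when the
#' adjacent lane is then held for at least `hold_s` seconds; shorter
#' excursions are lane-keeping errors and are not returned.
#'
#' @param trace Data.frame with `time_s` and `lane_index`.
#' @param hold_s Minimum dwell in the new lane (s), default 5.
#' @return Numeric vector of crossing times (first sample in the new lane).
#' @export
detect_lane_changes <- function(trace, hold_s = 5) {
  li <- trace$lane_index
  tt <- trace$time_s
  if (length(li) < 2L) return(numeric(0))
  r <- rle(li)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  if (length(r$lengths) < 2L) return(numeric(0))
  dwell <- function(j) {
    t_cross <- tt[starts[j]]
    t_leave <- if (j < length(r$lengths)) tt[ends[j] + 1L]
               else tt[length(tt)]
    t_leave - t_cross
  }
  out <- numeric(0)
  for (j in 2:length(r$lengths)) {
    if (dwell(j) < hold_s) next
    # returning to the original lane after a brief excursion closes a
    # lane-keeping error, not a lane change
    if (j >= 3L && dwell(j - 1L) < hold_s &&
        r$values[j - 2L] == r$values[j]) next
    out <- c(out, tt[starts[j]])
  }
  out
}

#' Mask excluded segments around lane changes
#'
#' Flags all samples inside a symmetric window (6 s total by default) around
#' each crossing as excluded; overlapping windows merge. Downstream metrics
#' normalize by the retained duration only.
#'
#' @param trace A trace data.frame with `time_s`.
#' @param crossings Crossing times from [detect_lane_changes()].
#' @param half_width Half of the exclusion window (s), default 3.
#' @return The trace with a logical `excluded` column.
#' @export
mask_segments <- function(trace, crossings, half_width = 3) {
  excl <- rep(FALSE, nrow(trace))
  for (tc in crossings)
    excl <- excl | (trace$time_s >= tc - half_width &
                    trace$time_s <= tc + half_width)
  trace$excluded <- excl
  trace
}

retained <- function(trace) {
  if (is.null(trace$excluded)) trace else trace[!trace$excluded, , drop = FALSE]
}

#' Steering reversal rate
#'
#' Counts crossings of the steering wheel's centre position (sign changes of
#' the steering angle through zero) over the retained samples and divides by
#' the retained duration. Samples with `|angle| < deadband` are ignored when
#' determining the sign so that numeric jitter at exactly zero does not
#' create spurious reversals; crossings are never counted across an excluded
#' gap.
#'
#' @param trace Trace with `time_s`, `steer_angle_rad` and optionally
#'   `excluded`.
#' @param deadband Ignore-band around zero (rad), default 0.005.
#' @return Reversals per second.
#' @export
steering_reversal_rate <- function(trace, deadband = 0.005) {
  tr <- retained(trace)
  nr <- nrow(tr)
  if (nr < 2L) stop("no retained samples")
  step <- stats::median(diff(trace$time_s))
  dur <- nr * step
  if (dur <= 0) stop("retained duration is zero")
  # contiguous retained segments (gaps where samples were excluded)
  seg <- cumsum(c(TRUE, diff(tr$time_s) > 1.5 * step))
  count <- 0L
  for (sg in split(tr$steer_angle_rad, seg)) {
    sgn <- sign(sg[abs(sg) >= deadband])
    if (length(sgn) > 1L) count <- count + sum(diff(sgn) != 0)
  }
  count / dur
}

#' Mean absolute lane deviation
#'
#' The mean absolute distance to the centre of the currently occupied lane
#' over the retained samples, in metres.
#'
#' @param trace Trace with `lat_pos_m` and optionally `excluded`.
#' @return Metres.
#' @export
lane_deviation <- function(trace) {
  tr <- retained(trace)
  if (nrow(tr) == 0L) stop("no retained samples")
  mean(abs(tr$lat_pos_m))
}

#' Score speed compliance against the n-back ground truth
#'
#' For each inter-sign interval the correct target is the speed shown n
#' signs before the interval's sign; the interval is correct when the mean
#' absolute difference between the driven speed and the target, after a
#' settling grace period, is within the tolerance. Scoring is against the
#' ground truth: maintaining an incorrectly recalled speed counts as an
#' error.
#'
#' @param trace Trace with `time_s`, `speed_kmh`.
#' @param signs Data.frame `appear_time`, `speed`, `ordinal` (full block
#'   sequence, including any build-up signs).
#' @param n N-back level.
#' @param tolerance km/h, default 5.
#' @param grace Settling time after each sign excluded from the interval
#'   mean (s), default 5.
#' @param window Optional `c(t0, t1)`: score only signs appearing inside it.
#' @return List: `intervals` (data.frame with `ordinal`, `t0`, `t1`,
#'   `target`, `mean_abs_dev`, `correct`) and `error_rate`.
#' @export
score_speed_compliance <- function(trace, signs, n, tolerance = 5,
                                   grace = 5, window = NULL) {
  use <- signs
  if (!is.null(window))
    use <- use[use$appear_time >= window[1] & use$appear_time < window[2], ,
               drop = FALSE]
  use <- use[use$ordinal - n >= 1L, , drop = FALSE]
  if (nrow(use) == 0L) stop("no scoreable inter-sign intervals")
  t_end <- max(trace$time_s)
  rows <- lapply(seq_len(nrow(use)), function(i) {
    o <- use$ordinal[i]
    t0 <- use$appear_time[i]
    nxt <- signs$appear_time[signs$appear_time > t0]
    t1 <- if (length(nxt)) min(min(nxt), t_end) else t_end
    target <- signs$speed[signs$ordinal == o - n]
    sel <- trace$time_s >= t0 + grace & trace$time_s < t1
    if (!any(sel)) return(NULL)
    mad <- mean(abs(trace$speed_kmh[sel] - target))
    data.frame(ordinal = o, t0 = t0, t1 = t1, target = target,
               mean_abs_dev = mad, correct = mad <= tolerance)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) == 0L)
    stop("no completed inter-sign intervals")
  list(intervals = rows, error_rate = mean(!rows$correct))
}

#' Bottleneck cost per inter-sign interval
#'
#' The average, over pairs of consecutive speed signs, of the summed
#' production-initiation delays occurring between the two signs, optionally
#' restricted to one cause (`procedural_contention` or `problem_state_busy`).
#'
#' @param delays Delay ledger from [delay_log()].
#' @param sign_times Appearance times of the signs (s), at least two.
#' @param cause Optional cause filter.
#' @param goal Optional goal filter.
#' @return Mean summed delay per interval (s).
#' @export
bottleneck_cost <- function(delays, sign_times, cause = NULL, goal = NULL) {
  sign_times <- sort(sign_times)
  if (length(sign_times) < 2L) stop("need at least two signs")
  per <- vapply(seq_len(length(sign_times) - 1L), function(i)
    cost_ledger(delays, c(sign_times[i], sign_times[i + 1L]),
                cause = cause, goal = goal),
    numeric(1))
  mean(per)
}

#' RMSE and R-squared between model and reference condition means
#'
#' `RMSE = sqrt(mean((model - ref)^2))`; `R^2 = 1 - SS_res / SS_tot` with the
#' reference means as the observations.
#'
#' @param model_means,reference_means Equal-length aligned numeric vectors
#'   (one entry per condition cell).
#' @return List with `rmse` and `r2`.
#' @export
fit_metrics <- function(model_means, reference_means) {
  stopifnot(length(model_means) == length(reference_means),
            length(model_means) >= 2L)
  ss_tot <- sum((reference_means - mean(reference_means))^2)
  if (ss_tot == 0) stop("reference means have zero variance; R^2 undefined")
  ss_res <- sum((model_means - reference_means)^2)
  list(rmse = sqrt(mean((model_means - reference_means)^2)),
       r2 = 1 - ss_res / ss_tot)
}

#' Analyze one simulated block
#'
#' Applies the full metric pipeline to a [sim_block()] result, restricted to
#' the experimental phase: lane-change detection and 6-s masking, steering
#' reversal rate, lane deviation, speed-compliance error rate, and
#' bottleneck costs per cause.
#'
#' @param block A `drive_block`.
#' @param deadband Steering-reversal deadband (rad).
#' @return One-row data.frame of block metrics.
#' @export
analyze_block <- function(block, deadband = 0.005) {
  tr <- block$trace
  exp_tr <- tr[tr$time_s >= block$exp_start & tr$time_s < block$exp_end, ,
               drop = FALSE]
  crossings <- detect_lane_changes(exp_tr)
  exp_tr <- mask_segments(exp_tr, crossings)
  srr <- steering_reversal_rate(exp_tr, deadband)
  ld <- lane_deviation(exp_tr)
  sc <- score_speed_compliance(tr, block$signs, block$n,
                               window = c(block$exp_start, block$exp_end))
  exp_sign_t <- block$signs$appear_time[
    block$signs$appear_time >= block$exp_start]
  # cost = delays imposed on the driving thread (delayed steering updates)
  cost_proc <- bottleneck_cost(block$delays, exp_sign_t,
                               cause = "procedural_contention",
                               goal = "drive")
  cost_ps <- bottleneck_cost(block$delays, exp_sign_t,
                             cause = "problem_state_busy",
                             goal = "drive")
  data.frame(variant = block$variant, road = block$road, n = block$n,
             srr = srr, lane_dev = ld, error_rate = sc$error_rate,
             cost_procedural = cost_proc, cost_problem_state = cost_ps,
             cost_total = cost_proc + cost_ps,
             n_lane_changes = length(crossings),
             flagged = block$flagged,
             stringsAsFactors = FALSE)
}
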