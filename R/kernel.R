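# Discrete-event production-system kernel with threaded-cognition goal
# arbitration and bottleneck-delay instrumentation.
#
# Time is continuous simulation time in seconds. The only fixed duration is
# the 50 ms a production occupies the procedural resource; everything else is
# event-driven.

PRODUCTION_DURATION <- 0.050

#' Define a production rule
#'
#' A production is an if-then rule executed by the procedural module. Every
#' production occupies the procedural resource for exactly 50 ms of
#' simulation time; it may additionally occupy other resources (visual,
#' motor, ...) for the same interval under the greedy/polite principle.
#'
#' @param name Unique production name (character scalar).
#' @param goal Goal thread the production belongs to, e.g. `"drive"` or
#'   `"nback"`.
#' @param resources Character vector of additional resource tags required
#'   beside `"procedural"` (which is always required and need not be listed).
#' @return An object of class `production`.
#' @examples
#' production("attend-near", "drive", "visual")
#' @export
production <- function(name, goal, resources = character()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(goal), length(goal) == 1L)
  structure(
    list(name = name, goal = goal,
         resources = unique(c("procedural", resources))),
    class = "production")
}

#' Create a production-system kernel
#'
#' The kernel tracks resource occupancy, a per-goal "last attended" ledger
#' used for threaded-cognition arbitration, and a log of production firings
#' with any initiation delays and their cause (`procedural_contention` or
#' `problem_state_busy`).
#'
#' @param resources Character vector of resource tags to register.
#' @param goals Character vector of goal tags.
#' @return An environment of class `ck_kernel`.
#' @export
kernel_new <- function(resources = c("procedural", "declarative",
                                     "problem_state", "goal_buffer",
                                     "visual", "motor"),
                       goals = c("drive", "nback")) {
  k <- new.env(parent = emptyenv())
  k$busy_until <- stats::setNames(rep(-Inf, length(resources)), resources)
  k$owner <- stats::setNames(rep(NA_character_, length(resources)), resources)
  k$last_attended <- stats::setNames(rep(-Inf, length(goals)), goals)
  # preallocated delay log, grown geometrically
  n0 <- 1024L
  k$log_n <- 0L
  k$log_cap <- n0
  k$log_production <- character(n0)
  k$log_goal <- character(n0)
  k$log_requested <- numeric(n0)
  k$log_started <- numeric(n0)
  k$log_cause <- character(n0)
  class(k) <- "ck_kernel"
  k
}

kernel_log_grow <- function(k) {
  cap <- k$log_cap * 2L
  length(k$log_production) <- cap
  length(k$log_goal) <- cap
  length(k$log_requested) <- cap
  length(k$log_started) <- cap
  length(k$log_cause) <- cap
  k$log_cap <- cap
}

#' Request a resource
#'
#' Greedy discipline: the grant time is the earliest legal instant,
#' `max(t, busy_until)`. Queued requests are served first-come first-served
#' by request time.
#'
#' @param k A kernel from [kernel_new()].
#' @param r Resource tag.
#' @param t Request time (s).
#' @return The grant time (s).
#' @export
request_resource <- function(k, r, t) {
  if (!r %in% names(k$busy_until))
    stop("unregistered resource: ", r)
  max(t, k$busy_until[[r]])
}

#' Mark a resource busy
#'
#' Internal bookkeeping used by [execute_production()]; exposed so task
#' scripts can hold a non-procedural resource across an interval (e.g. the
#' declarative module during a retrieval, or the problem state).
#'
#' @inheritParams request_resource
#' @param until Time the occupancy ends (s).
#' @param owner Name recorded as the owner.
#' @export
occupy_resource <- function(k, r, until, owner = "anonymous") {
  if (!r %in% names(k$busy_until))
    stop("unregistered resource: ", r)
  k$busy_until[[r]] <- until
  k$owner[[r]] <- owner
  invisible(NULL)
}

#' Release a resource
#'
#' Clears the owner and makes the resource grantable from `t` (polite
#' principle: resources are released as soon as they are no longer needed).
#' Releasing an unowned resource is a programming error and signals one.
#'
#' @inheritParams request_resource
#' @export
release_resource <- function(k, r, t) {
  if (!r %in% names(k$busy_until))
    stop("unregistered resource: ", r)
  if (is.na(k$owner[[r]]))
    stop("release of unowned resource: ", r)
  k$owner[[r]] <- NA_character_
  k$busy_until[[r]] <- t
  invisible(NULL)
}

#' Select the goal to serve (threaded cognition)
#'
#' When productions of several goal threads are executable at the same time,
#' the production of the least recently attended goal is selected. Exact ties
#' are broken lexicographically on the goal tag so reruns are deterministic.
#'
#' @param candidates Character vector of competing goal tags (non-empty).
#' @param ledger Named numeric vector of last-attended times, or a kernel.
#' @return The selected goal tag.
#' @examples
#' select_goal(c("drive", "nback"), c(drive = 0.30, nback = 0.12))
#' @export
select_goal <- function(candidates, ledger) {
  if (length(candidates) == 0L) stop("empty candidate set")
  if (inherits(ledger, "ck_kernel")) ledger <- ledger$last_attended
  la <- ledger[candidates]
  la[is.na(la)] <- -Inf
  cand <- candidates[la == min(la)]
  sort(cand)[1L]
}

#' Execute a production
#'
#' The production occupies the procedural resource (and any other resource it
#' requires) for exactly 50 ms of simulation time, starting at the first
#' instant all required resources are free and any external gate has opened.
#' The initiation delay (`started - requested`) is logged together with its
#' cause: `problem_state_busy` when an explicit problem-state gate was the
#' binding constraint, `procedural_contention` otherwise.
#'
#' @param k A kernel.
#' @param p A [production()].
#' @param t_request Time at which the production's conditions were met (s).
#' @param gate Optional extra earliest-start time (s), e.g. the
#'   problem-state availability gating the driving loop.
#' @return Invisibly, a list with `started`, `ended`, `delay`, `cause`.
#' @export
execute_production <- function(k, p, t_request, gate = -Inf) {
  res <- p$resources
  bu <- k$busy_until[res]
  if (anyNA(bu)) stop("unregistered resource in production ", p$name)
  t_res <- max(bu)
  start <- max(t_request, t_res, gate)
  cause <- if (gate > max(t_request, t_res)) "problem_state_busy"
           else "procedural_contention"
  end <- start + PRODUCTION_DURATION
  # occupy then immediately release at completion (polite principle)
  k$busy_until[res] <- end
  k$last_attended[[p$goal]] <- start
  i <- k$log_n + 1L
  if (i > k$log_cap) kernel_log_grow(k)
  k$log_n <- i
  k$log_production[[i]] <- p$name
  k$log_goal[[i]] <- p$goal
  k$log_requested[[i]] <- t_request
  k$log_started[[i]] <- start
  k$log_cause[[i]] <- cause
  invisible(list(started = start, ended = end,
                 delay = start - t_request, cause = cause))
}

#' Extract the production firing log
#'
#' @param k A kernel.
#' @return A data.frame with columns `time_s` (start), `production`, `goal`,
#'   `cause`, `delay_s`. Rows are in firing order.
#' @export
delay_log <- function(k) {
  n <- k$log_n
  idx <- seq_len(n)
  data.frame(
    time_s = k$log_started[idx],
    production = k$log_production[idx],
    goal = k$log_goal[idx],
    requested_s = k$log_requested[idx],
    cause = k$log_cause[idx],
    delay_s = k$log_started[idx] - k$log_requested[idx],
    stringsAsFactors = FALSE)
}

#' Sum bottleneck delays over a time window
#'
#' Total initiation delay accumulated by productions whose conditions were
#' met (`requested_s`) inside `[t0, t1)`, optionally restricted to one cause
#' and/or one goal. This is the substrate of the bottleneck cost accounting:
#' the sum of all production delays between two speed signs.
#'
#' @param records A delay log data.frame from [delay_log()].
#' @param window Numeric vector `c(t0, t1)` with `t0 < t1`.
#' @param cause Optional: `"procedural_contention"` or `"problem_state_busy"`.
#' @param goal Optional goal tag filter.
#' @return Total delay in seconds.
#' @export
cost_ledger <- function(records, window, cause = NULL, goal = NULL) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  keep <- records$requested_s >= window[1] & records$requested_s < window[2]
  if (!is.null(cause)) keep <- keep & records$cause == cause
  if (!is.null(goal)) keep <- keep & records$goal == goal
  sum(records$delay_s[keep])
}

#' Write a production event log to CSV
#'
#' @param records Data.frame from [delay_log()].
#' @param path Output file.
#' @export
write_event_log <- function(records, path) {
  utils::write.csv(records[, c("time_s", "production", "goal", "cause",
                               "delay_s")],
                   path, row.names = FALSE)
  invisible(path)
}
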