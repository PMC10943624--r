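# The speed-sign n-back task thread: episodic encoding into a backward
# linked list, sequential recall by walking the previous-sign links,
# rehearsal by the same mechanism, and the gating rule distinguishing the
# central-bottleneck from the problem-state-bottleneck variant.

PS_SWAP_OCCUPANCY <- 0.200  # problem-state busy time after each content swap

#' Create an n-back task state
#'
#' @param n N-back level (0-4).
#' @param variant `"central"` (interference through serialized production
#'   initiation only) or `"problem_state"` (driving additionally gated on
#'   working-memory availability).
#' @param rehearsals Number of rehearsal cycles after each successful recall.
#' @return Environment of class `nback_state`.
#' @export
nback_state <- function(n, variant = c("central", "problem_state"),
                        rehearsals = 0L) {
  if (!(n %in% 0:4)) stop("n-back level must be in 0..4")
  variant <- match.arg(variant)
  st <- new.env(parent = emptyenv())
  st$n <- as.integer(n)
  st$variant <- variant
  st$rehearsals <- as.integer(rehearsals)
  st$latest_id <- NA_character_
  st$latest_pos <- 0L
  st$latest_prev_id <- NA_character_
  st$ps_chunk <- NULL         # chunk currently held in the problem state
  st$ps_busy_until <- -Inf
  st$goal_speed <- NA_real_
  class(st) <- "nback_state"
  st
}

#' Encode a speed sign as an episodic chunk
#'
#' The sign is encoded as a fresh chunk carrying an episodic tag, the tag of
#' the previous sign (forming a linked list backwards in time) and the
#' speed. The new chunk enters the problem state; the chunk previously held
#' there is released to declarative memory (a buffer is stored on clearing,
#' not before), which is what makes the previous sign retrievable. Episodic
#' tags keep two signs with the same speed distinct.
#'
#' @param speed Sign speed (km/h).
#' @param ordinal 1-based position of the sign in the block's sequence.
#' @param state An [nback_state()].
#' @param store A [memory_store_new()] store.
#' @param t Encoding time (s).
#' @return The new [sign_chunk()].
#' @export
encode_sign <- function(speed, ordinal, state, store, t) {
  ch <- sign_chunk(id = sprintf("sign-%03d", ordinal),
                   previous_id = if (is.na(state$latest_id)) NULL
                                 else state$latest_id,
                   speed = speed, created_at = t, seq_pos = ordinal)
  ps_swap(state, ch, store, t)
  state$latest_id <- ch$id
  state$latest_pos <- ch$seq_pos
  state$latest_prev_id <- ch$previous_id
  ch
}

#' Swap the problem-state content
#'
#' Places `chunk` in the problem state; the outgoing chunk is released to
#' declarative memory (recording a presentation, merging with an existing
#' history). The problem state stays busy for 200 ms after the swap.
#'
#' @param state An [nback_state()].
#' @param chunk Incoming [sign_chunk()].
#' @param store Declarative store receiving the released chunk.
#' @param t Swap time (s).
#' @export
ps_swap <- function(state, chunk, store, t) {
  if (!is.null(state$ps_chunk))
    record_presentation(store, state$ps_chunk, t)
  state$ps_chunk <- chunk
  state$ps_busy_until <- t + PS_SWAP_OCCUPANCY
  invisible(state)
}

#' One backward step of the sequential walk
#'
#' Issues a retrieval request for the chunk whose episodic id equals the
#' current chunk's `previous_id`. The retrieved chunk (possibly a confusion
#' under partial matching) replaces the problem-state content.
#'
#' @param store Declarative store.
#' @param current Chunk currently in the problem state (a [sign_chunk()]),
#'   whose `previous_id` slot supplies the request.
#' @param params [retrieval_params()].
#' @param t Time of the retrieval request (s).
#' @return The [retrieve()] result, with `request_id` attached, or a failure
#'   when the current chunk has no predecessor.
#' @export
nback_step <- function(store, current, params, t) {
  prev <- current$previous_id
  if (is.null(prev) || is.na(prev))
    return(list(chunk = NULL, failed = TRUE, latency = 0, score = -Inf,
                request_id = NA_character_))
  res <- retrieve(store, prev, params, t)
  res$request_id <- prev
  res
}

#' Sequential n-back recall
#'
#' Walks the episodic linked list n steps back from the most recent sign,
#' one retrieval per step; each retrieved chunk swaps into the problem state
#' (busying it for 200 ms in the problem-state variant) and is re-presented
#' to declarative memory. Returns the speed of the final chunk, which can be
#' a neighbouring sign's speed when partial matching mixes two signs up.
#'
#' @param n Steps to walk back (0 returns the latest sign's speed directly).
#' @param state An [nback_state()].
#' @param store Declarative store.
#' @param params [retrieval_params()].
#' @param t Start time (s).
#' @param step_dt Nominal time between successive swaps (s) used by this
#'   stand-alone entry point; inside the simulator swap times come from the
#'   production schedule.
#' @return List: `speed` (NA on failure), `failed`, `swap_times`, `ids`.
#' @export
recall_nback <- function(n, state, store, params, t, step_dt = 0.35) {
  if (n == 0L) {
    if (is.null(state$ps_chunk))
      return(list(speed = NA_real_, failed = TRUE,
                  swap_times = numeric(), ids = character()))
    return(list(speed = state$ps_chunk$speed, failed = FALSE,
                swap_times = numeric(), ids = character()))
  }
  cur <- if (!is.null(state$ps_chunk) &&
             identical(state$ps_chunk$id, state$latest_id)) state$ps_chunk
         else {
           i <- match(state$latest_id, store$id)
           if (is.na(i)) return(list(speed = NA_real_, failed = TRUE,
                                     swap_times = numeric(),
                                     ids = character()))
           sign_chunk(store$id[i], store$previous_id[i], store$speed[i],
                      store$created_at[i], store$seq_pos[i])
         }
  swaps <- numeric(0)
  ids <- character(0)
  tt <- t
  for (k in seq_len(n)) {
    res <- nback_step(store, cur, params, tt)
    if (res$failed)
      return(list(speed = NA_real_, failed = TRUE, swap_times = swaps,
                  ids = ids))
    t_swap <- tt + PRODUCTION_DURATION  # harvest production completes
    ps_swap(state, res$chunk, store, t_swap)
    swaps <- c(swaps, t_swap)
    ids <- c(ids, res$chunk$id)
    cur <- res$chunk
    tt <- tt + step_dt
  }
  list(speed = cur$speed, failed = FALSE, swap_times = swaps, ids = ids)
}

#' Rehearse the task-relevant sign sequence
#'
#' After a successful recall the sequence is rehearsed via the same
#' sequential walk, `cycles` times; each re-presentation boosts the chunks'
#' base-level activation and, in the problem-state variant, re-busies the
#' problem state.
#'
#' @param n Walk length per cycle.
#' @param cycles Number of rehearsal cycles.
#' @inheritParams recall_nback
#' @return List with `swap_times` and `ids` over all cycles.
#' @export
rehearse <- function(n, cycles, state, store, params, t, step_dt = 0.35) {
  swaps <- numeric(0)
  ids <- character(0)
  tt <- t
  for (cy in seq_len(cycles)) {
    res <- recall_nback(n, state, store, params, tt, step_dt)
    swaps <- c(swaps, res$swap_times)
    ids <- c(ids, res$ids)
    tt <- if (length(res$swap_times)) max(res$swap_times) + step_dt
          else tt + step_dt
  }
  list(swap_times = swaps, ids = ids)
}

#' Transfer the recalled target speed to the goal buffer
#'
#' The target speed is control information and lives in the goal buffer,
#' where longitudinal control reads it. Once transferred there is no need to
#' retain the chunk in the problem state, so it is released to declarative
#' memory immediately; only the 200-ms tail of the last swap remains, which
#' is why the 0-back task leaves the problem state nearly always free.
#'
#' @param speed Recalled speed (km/h); NA leaves the goal buffer unchanged.
#' @param state An [nback_state()].
#' @param store Declarative store receiving the released chunk (optional for
#'   a bare goal update).
#' @param t Transfer time (s); required when `store` is given.
#' @return Invisibly, the goal speed now in effect.
#' @export
update_target_speed <- function(speed, state, store = NULL, t = NULL) {
  if (!is.na(speed)) state$goal_speed <- speed
  if (!is.null(store) && !is.null(state$ps_chunk)) {
    record_presentation(store, state$ps_chunk, t)
    state$ps_chunk <- NULL
  }
  invisible(state$goal_speed)
}

#' Gate the driving loop on working-memory availability
#'
#' In the problem-state variant each iteration of the high- or low-control
#' loop, which begins with the attend-near production, can only be initiated
#' when the problem state is not busy; the central variant never gates (only
#' procedural contention applies there).
#'
#' @param variant `"central"` or `"problem_state"`.
#' @param state An [nback_state()].
#' @param t Current time (s).
#' @return List: `allow` (logical) and `until` (earliest start; `t` when
#'   allowed).
#' @export
gate_driving <- function(variant, state, t) {
  if (variant == "central" || state$ps_busy_until <= t)
    list(allow = TRUE, until = t)
  else
    list(allow = FALSE, until = state$ps_busy_until)
}
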