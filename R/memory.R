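# Declarative memory: base-level activation, partial matching with a graded
# speed-sign similarity scale, logistic activation noise, and thresholded
# retrieval with a latency that decays exponentially in activation.

#' Retrieval parameter set
#'
#' @param d Base-level decay; the power-law decay exponent, conventionally 0.5.
#' @param rt Retrieval threshold. The default is deliberately low (-10) so
#'   that outright retrieval failures effectively never occur and task errors
#'   arise through partial matching (mixing up two signs) instead.
#' @param mp Mismatch-penalty scale (>= 0) multiplying chunk similarity.
#'   The scale must exceed the base-level recency advantage of a freshly
#'   encoded sign over its predecessor (roughly 1-2.5 activation units) for
#'   the episodic-tag request to constrain retrieval at all; the default is
#'   calibrated so n-back confusions grow with level.
#' @param s Scale of the transient logistic activation noise (>= 0); one draw
#'   per candidate per retrieval attempt.
#' @param F Latency factor (s): retrieval latency is `F * exp(-score)`.
#' @param latency_cap Upper bound on retrieval latency (s).
#' @param similarity_step Per-position similarity decrement (negative).
#' @param adjacent_zero If `TRUE`, positional distance `k` maps to similarity
#'   `step * (k - 1)` (adjacent signs fully similar); the default maps `k` to
#'   `step * k`. Both readings share the -0.1 per-step decrement.
#' @return A list of class `retrieval_params`.
#' @export
retrieval_params <- function(d = 0.5, rt = -10, mp = 16, s = 0.25,
                             F = 0.2, latency_cap = 1.0,
                             similarity_step = -0.1, adjacent_zero = FALSE) {
  stopifnot(d > 0, mp >= 0, s >= 0, F > 0, latency_cap > 0,
            similarity_step <= 0)
  structure(list(d = d, rt = rt, mp = mp, s = s, F = F,
                 latency_cap = latency_cap,
                 similarity_step = similarity_step,
                 adjacent_zero = adjacent_zero),
            class = "retrieval_params")
}

#' Create an empty declarative store
#'
#' The store holds speed-sign chunks (episodic id, backward link, speed) and
#' their presentation histories. Chunks with the same episodic id merge:
#' re-presenting one appends to its history rather than duplicating it.
#'
#' @return An environment of class `declarative_store`.
#' @export
memory_store_new <- function() {
  st <- new.env(parent = emptyenv())
  st$id <- character()
  st$previous_id <- character()
  st$speed <- numeric()
  st$created_at <- numeric()
  st$seq_pos <- integer()     # ordinal position in the sign sequence
  st$times <- list()          # presentation histories, strictly increasing
  class(st) <- "declarative_store"
  st
}

#' Construct a speed-sign chunk
#'
#' @param id Episodic tag (unique per sign occurrence).
#' @param previous_id Episodic tag of the previous sign, or `NA` for the
#'   first sign; together the chunks form a linked list backwards in time.
#' @param speed Sign speed in km/h, one of 40, 50, ..., 120.
#' @param created_at Creation time (s).
#' @param seq_pos Ordinal position of the sign in the block's sign sequence.
#' @return A list of class `sign_chunk`.
#' @export
sign_chunk <- function(id, previous_id, speed, created_at, seq_pos) {
  if (!speed %in% seq(40, 120, by = 10))
    stop("speed must be in {40, 50, ..., 120} km/h")
  structure(list(id = id,
                 previous_id = if (is.null(previous_id)) NA_character_
                               else previous_id,
                 speed = speed, created_at = created_at,
                 seq_pos = as.integer(seq_pos)),
            class = "sign_chunk")
}

#' Record a presentation of a chunk
#'
#' Clearing a buffer stores its chunk in declarative memory; identical chunks
#' (same episodic id) merge, so a re-presentation appends the time to the
#' existing history. Presentation times must be non-decreasing per chunk.
#'
#' @param store A [memory_store_new()] store.
#' @param chunk A [sign_chunk()] (only its id matters for re-presentations).
#' @param t Presentation time (s).
#' @export
record_presentation <- function(store, chunk, t) {
  i <- match(chunk$id, store$id)
  if (is.na(i)) {
    store$id <- c(store$id, chunk$id)
    store$previous_id <- c(store$previous_id, chunk$previous_id)
    store$speed <- c(store$speed, chunk$speed)
    store$created_at <- c(store$created_at, t)
    store$seq_pos <- c(store$seq_pos, chunk$seq_pos)
    store$times <- c(store$times, list(t))
  } else {
    h <- store$times[[i]]
    if (t < h[length(h)]) stop("non-monotone presentation time for ", chunk$id)
    store$times[[i]] <- c(h, t)
  }
  invisible(store)
}

#' Base-level activation
#'
#' `B_i = ln(sum_j (t_now - t_j)^(-d))` over the presentation history: the
#' log-sum of power-law-decayed traces, rising with frequency and recency.
#'
#' @param times Numeric vector of presentation times t_j (s).
#' @param t_now Current time (s); must be strictly later than every t_j.
#' @param d Decay exponent (> 0).
#' @return The activation (dimensionless).
#' @examples
#' base_level_activation(0, 1)            # single presentation 1 s ago -> 0
#' base_level_activation(c(0, 2), 4, 0.5) # log(2^-0.5 + 4^-0.5)
#' @export
base_level_activation <- function(times, t_now, d = 0.5) {
  if (length(times) == 0L) stop("empty presentation history")
  if (t_now <= max(times))
    stop("t_now must be later than every presentation time")
  log(sum((t_now - times)^(-d)))
}

#' Similarity of two sign chunks
#'
#' Similarity is 0 for the same sign and decreases by `step` (default -0.1)
#' for each speed sign that occurred in between, i.e. linearly in the
#' positional distance within the sign sequence. Symmetric.
#'
#' @param pos_a,pos_b Ordinal positions of the two signs in the sequence.
#' @param step Per-position decrement (negative; default -0.1).
#' @param adjacent_zero Alternative reading under which adjacent signs have
#'   similarity 0 and distance `k` maps to `step * (k - 1)`.
#' @return Similarity value (<= 0).
#' @export
sign_similarity <- function(pos_a, pos_b, step = -0.1, adjacent_zero = FALSE) {
  dist <- abs(pos_a - pos_b)
  if (adjacent_zero) step * pmax(dist - 1L, 0L) else step * dist
}

#' Retrieve a chunk by episodic id with partial matching
#'
#' Every chunk in the store is scored as
#' `base-level activation + mp * similarity(candidate, target) + noise`,
#' where similarity is the graded sign-sequence scale and noise is logistic
#' with scale `s` (one independent draw per candidate). The highest-scoring
#' chunk is retrieved iff its score clears the retrieval threshold `rt`;
#' otherwise the retrieval fails. Latency is `F * exp(-score)`, capped.
#'
#' Partial matching is what produces n-back confusions: a near-neighbour of
#' the requested sign can out-score it when noise is on.
#'
#' @param store A declarative store.
#' @param request_id Episodic id the retrieval request specifies.
#' @param params A [retrieval_params()] set.
#' @param t_now Current time (s).
#' @return A list: `chunk` (a [sign_chunk()] or `NULL`), `failed`, `latency`
#'   (s), `score` (winning score, `-Inf` on empty store).
#' @export
retrieve <- function(store, request_id, params, t_now) {
  n <- length(store$id)
  if (n == 0L) {
    return(list(chunk = NULL, failed = TRUE,
                latency = params$latency_cap, score = -Inf))
  }
  target <- match(request_id, store$id)
  if (is.na(target))
    stop("requested id not present in the sign sequence: ", request_id)
  act <- vapply(seq_len(n), function(i)
    base_level_activation(store$times[[i]], t_now, params$d), numeric(1))
  sim <- sign_similarity(store$seq_pos, store$seq_pos[target],
                         step = params$similarity_step,
                         adjacent_zero = params$adjacent_zero)
  noise <- if (params$s > 0) stats::rlogis(n, location = 0, scale = params$s)
           else numeric(n)
  score <- act + params$mp * sim + noise
  win <- which.max(score)
  best <- score[win]
  lat <- min(params$F * exp(-best), params$latency_cap)
  if (best < params$rt) {
    return(list(chunk = NULL, failed = TRUE,
                latency = params$latency_cap, score = best))
  }
  ch <- sign_chunk(store$id[win], store$previous_id[win], store$speed[win],
                   store$created_at[win], store$seq_pos[win])
  list(chunk = ch, failed = FALSE, latency = lat, score = best)
}

#' Dump a declarative store to JSON lines
#'
#' One JSON object per chunk with its presentation history; the counterpart
#' [memory_load()] restores an identical store.
#'
#' @param store A declarative store.
#' @param path File path.
#' @export
memory_dump <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(store$id)) {
    rec <- list(id = store$id[i], previous_id = store$previous_id[i],
                speed = store$speed[i], created_at = store$created_at[i],
                seq_pos = store$seq_pos[i], times = store$times[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Load a declarative store from JSON lines
#'
#' @param path File written by [memory_dump()].
#' @return A declarative store.
#' @export
memory_load <- function(path) {
  st <- memory_store_new()
  for (ln in readLines(path)) {
    rec <- jsonlite::fromJSON(ln)
    st$id <- c(st$id, rec$id)
    st$previous_id <- c(st$previous_id,
                        if (is.null(rec$previous_id)) NA_character_
                        else rec$previous_id)
    st$speed <- c(st$speed, rec$speed)
    st$created_at <- c(st$created_at, rec$created_at)
    st$seq_pos <- c(st$seq_pos, as.integer(rec$seq_pos))
    st$times <- c(st$times, list(as.numeric(rec$times)))
  }
  st
}
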