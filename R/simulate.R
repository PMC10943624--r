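# The coupled simulator for one experimental block: two goal threads
# (driving and the n-back task) interleaved production by production through
# the kernel, a vehicle advanced on a 5-ms grid between control events, and
# full instrumentation (200-Hz trace, task events, delay ledger).
#
# The drive thread repeats a short production sequence per control-loop
# iteration: attend-near (the gating point in the problem-state variant),
# zero or more processing productions, then a motor production whose
# completion applies the steering/accelerator update. The n-back thread
# attends and encodes each sign, walks the episodic linked list n steps back
# (one retrieval request + harvest per step), transfers the recalled speed
# to the goal buffer, and rehearses.

#' Simulate one experimental block
#'
#' Runs the production-system driver through one block of the design:
#' a build-up phase of `20 * n` seconds during which the first n signs
#' accrue, followed by the experimental phase (160 s by default) with eight
#' speed signs. World randomness (sign speeds, traffic, heading disturbance)
#' is drawn from `world_seed`, cognition randomness (activation noise, motor
#' noise) from `cog_seed`, so the two model variants can share identical
#' worlds.
#'
#' @param road `"highway"` or `"construction"`.
#' @param n N-back level (0-4).
#' @param variant `"central"` or `"problem_state"`.
#' @param cfg A [default_config()]-shaped configuration.
#' @param world_seed,cog_seed Integer seeds.
#' @param exp_duration Override of the experimental-phase duration (s).
#' @return A list of class `drive_block`: `trace` (200-Hz data.frame with
#'   `time_s`, `lat_pos_m` (offset from the current lane centre),
#'   `lane_index`, `steer_angle_rad`, `phi`, `speed_kmh`, `long_pos_m`),
#'   `events`, `delays` (production delay ledger), `signs`, `buildup`,
#'   `exp_start`, `exp_end`, `road`, `n`, `variant`, `flagged` (TRUE if the
#'   vehicle left the road entirely).
#' @export
sim_block <- function(road, n, variant, cfg = default_config(),
                      world_seed = 1L, cog_seed = 2L,
                      exp_duration = cfg$experiment$exp_duration) {
  stopifnot(n %in% 0:4, variant %in% c("central", "problem_state"))
  wcf <- cfg$world; scf <- cfg$steering; lcf <- cfg$longitudinal
  wp <- world_params(wcf$wheelbase, wcf$a_throttle, wcf$a_brake,
                     wcf$steer_ratio, wcf$dt, wcf$crosswind_sd)
  lane_w <- if (road == "highway") wcf$lane_width_highway
            else wcf$lane_width_construction
  g <- road_geometry(road, lane_width = lane_w, n_lanes = wcf$n_lanes)
  dist_road <- if (road == "highway") scf$dist_highway
               else scf$dist_construction
  sp <- steering_params(scf$k_far, scf$k_near, scf$k_I, dist_road, scf$t_hc,
                        scf$motor_noise_sd, scf$max_delta, scf$max_angle)
  lp <- longitudinal_params(lcf$k_dthw, lcf$k_thw)
  mcf <- cfg$memory
  mpars <- retrieval_params(mcf$d, mcf$rt, mcf$mp, mcf$s, mcf$F,
                            mcf$latency_cap, mcf$similarity_step,
                            mcf$adjacent_zero)
  kprod <- as.integer(cfg$nback$drive_productions)
  venc <- cfg$cognition$visual_encode
  mexec <- cfg$cognition$motor_exec

  # every block gets at least 20 s of pre-experimental driving: levels with
  # n >= 1 need it to accrue their first n signs, and the same run-in for
  # 0-back equalizes the dynamical state (drift, control mode) at the start
  # of the analyzed phase across levels
  buildup <- max(20 * n, 20)
  dur <- buildup + exp_duration
  dt <- wp$dt
  nstep <- as.integer(ceiling(dur / dt - 1e-9))

  ## ---- world randomness (shared between variants) ----
  set.seed(world_seed)
  signs <- sign_schedule(dur)
  traffic <- spawn_traffic(dur, enabled = wcf$traffic_enabled,
                           ahead_m = wcf$traffic_ahead_m,
                           speed_frac = wcf$traffic_speed_frac)
  wind <- stats::rnorm(nstep, 0, wp$crosswind_sd * sqrt(dt))
  ## ---- cognition randomness ----
  set.seed(cog_seed)

  ## ---- world state ----
  drivable <- setdiff(seq_len(g$n_lanes) - 1L, g$blocked_lanes)
  right_lane <- max(drivable)
  y <- g$centers[right_lane + 1L]
  heading <- 0; v <- cfg$experiment$initial_speed_kmh / 3.6
  x <- 0; steer <- 0; phi <- 0
  filled <- 0L
  tr_y <- numeric(nstep); tr_h <- numeric(nstep); tr_v <- numeric(nstep)
  tr_x <- numeric(nstep); tr_st <- numeric(nstep); tr_ph <- numeric(nstep)
  yaw_gain <- 1 / (wp$wheelbase * wp$steer_ratio)

  advance_to <- function(tt) {
    ti <- min(nstep, as.integer(floor(tt / dt + 1e-9)))
    if (ti <= filled) return(invisible(NULL))
    idx <- (filled + 1L):ti
    m <- length(idx)
    a <- if (phi >= 0) wp$a_throttle else wp$a_brake
    vv <- pmax(0, v + phi * a * dt * seq_len(m))
    hh <- heading + cumsum(vv * steer * yaw_gain * dt + wind[idx])
    yy <- y + cumsum(vv * sin(hh) * dt)
    xx <- x + cumsum(vv * cos(hh) * dt)
    tr_y[idx] <<- yy; tr_h[idx] <<- hh; tr_v[idx] <<- vv
    tr_x[idx] <<- xx; tr_st[idx] <<- steer; tr_ph[idx] <<- phi
    y <<- yy[m]; heading <<- hh[m]; v <<- vv[m]; x <<- xx[m]
    filled <<- ti
    invisible(NULL)
  }

  ## ---- kernel and productions ----
  k <- kernel_new()
  p_drive <- vector("list", kprod)
  p_drive[[1L]] <- production("attend-near", "drive", "visual")
  if (kprod > 2L) for (j in 2:(kprod - 1L))
    p_drive[[j]] <- production(sprintf("drive-process-%d", j - 1L), "drive")
  p_drive[[kprod]] <- production("drive-motor", "drive", "motor")
  p_attend_sign <- production("attend-sign", "nback", "visual")
  p_encode <- production("encode-sign", "nback", "problem_state")
  p_request <- production("request-retrieval", "nback")
  p_harvest <- production("harvest-retrieval", "nback", "problem_state")
  p_goal <- production("update-target-speed", "nback", "goal_buffer")

  ## ---- drive thread state ----
  d_phase <- 1L; d_ready <- 0
  d_mode <- "low"; d_high_until <- -Inf
  d_prev_perc <- NULL; d_pend_perc <- NULL
  d_last_motor <- 0; d_target_lane <- right_lane
  d_thw_prev <- 0; d_follow <- FALSE
  d_maneuver <- FALSE  # lane-change in progress (mirror checks hold visual)
  target_v <- cfg$experiment$initial_speed_kmh / 3.6

  ## ---- traffic state (lazy activation; analytic motion) ----
  n_tr <- nrow(traffic)
  tr_active <- logical(n_tr); tr_x0 <- numeric(n_tr)
  tr_t0 <- numeric(n_tr); tr_vl <- numeric(n_tr)
  tr_lane <- rep(right_lane, n_tr)

  ## ---- n-back thread state ----
  ns <- nback_state(n, variant,
                    rehearsals = cfg$nback$rehearsals[n + 1L])
  store <- memory_store_new()
  nsigns <- nrow(signs)
  nb_phase <- "attend_sign"; nb_ready <- signs$appear_time[1L]
  sign_ptr <- 1L
  walk_remaining <- 0L; walk_len0 <- 0L; rehears_remaining <- 0L
  in_rehearsal <- FALSE; recall_complete <- FALSE
  cur_chunk <- NULL; pend_speed <- NA_real_
  pending_chunk <- NULL; cur_sign_ord <- 0L
  latest_chunk_from <- function() {
    if (!is.null(ns$ps_chunk) && identical(ns$ps_chunk$id, ns$latest_id))
      return(ns$ps_chunk)
    i <- match(ns$latest_id, store$id)
    sign_chunk(store$id[i], store$previous_id[i], store$speed[i],
               store$created_at[i], store$seq_pos[i])
  }

  ## ---- event log ----
  ev_t <- numeric(0); ev_type <- character(0)
  ev_val <- numeric(0); ev_true <- numeric(0)
  log_event <- function(tt, type, val = NA_real_, truth = NA_real_) {
    ev_t <<- c(ev_t, tt); ev_type <<- c(ev_type, type)
    ev_val <<- c(ev_val, val); ev_true <<- c(ev_true, truth)
    invisible(NULL)
  }

  to_idle <- function(tt) {
    # polite principle: the problem-state content is not needed between
    # episodes; release it to declarative memory right away
    if (!is.null(ns$ps_chunk)) {
      record_presentation(store, ns$ps_chunk, tt)
      ns$ps_chunk <- NULL
    }
    if (sign_ptr <= nsigns) {
      nb_phase <<- "attend_sign"
      nb_ready <<- max(tt, signs$appear_time[sign_ptr])
    } else {
      nb_phase <<- "idle"; nb_ready <<- Inf
    }
    invisible(NULL)
  }

  start_rehearsal_or_idle <- function(tt) {
    # rehearsal walks the full n-deep task-relevant chain from the most
    # recent sign, via the same sequential mechanism as recall
    walk_len0 <<- min(n, ns$latest_pos - 1L)
    # rehearsal is suspended while a lane change is in progress: the drive
    # goal holds the visual resource for mirror checks (greedy/polite)
    if (n >= 1L && ns$rehearsals > 0L && walk_len0 > 0L && !d_maneuver) {
      in_rehearsal <<- TRUE
      rehears_remaining <<- ns$rehearsals
      walk_remaining <<- walk_len0
      cur_chunk <<- latest_chunk_from()
      nb_phase <<- "request"; nb_ready <<- tt
    } else to_idle(tt)
    invisible(NULL)
  }

  motor_effect <- function(tm) {
    advance_to(tm)
    Dt <- tm - d_last_motor
    if (Dt <= 0) Dt <- dt
    ## activate scheduled leads
    if (n_tr > 0L) for (i in seq_len(n_tr)) {
      if (!tr_active[i] && tm >= traffic$appear_time[i]) {
        tr_active[i] <<- TRUE
        tr_vl[i] <<- traffic$speed_frac[i] * target_v
        tr_x0[i] <<- x + traffic$ahead_m[i]
        tr_t0[i] <<- tm
      }
    }
    act <- which(tr_active)
    lead_df <- data.frame(x = tr_x0[act] + tr_vl[act] * (tm - tr_t0[act]),
                          lane_index = tr_lane[act], speed = tr_vl[act])
    vst <- list(y = y, heading = heading, speed = v, x = x,
                steer_angle = steer, phi = phi,
                lane_index = lane_of(g, y))
    ot <- begin_overtake(vst, lead_df, g)
    if (ot$target_lane != d_target_lane) {
      log_event(tm, "lane_target_change", ot$target_lane)
      d_target_lane <<- ot$target_lane
      d_mode <<- "high"
      d_maneuver <<- TRUE
      d_high_until <<- max(d_high_until, tm + sp$t_hc)
      d_prev_perc <<- d_pend_perc
    }
    d_follow <<- ot$follow
    center <- g$centers[d_target_lane + 1L]
    if (d_mode == "high") {
      if (!is.null(d_prev_perc) && !is.null(d_pend_perc)) {
        # the integral term assumes the nominal loop cycle; a delayed update
        # does not integrate the near-point error over the waiting time
        dst <- steer_high_control(d_pend_perc, d_prev_perc, sp,
                                  min(Dt, 0.25)) +
          stats::rnorm(1, 0, sp$motor_noise_sd)
        dst <- min(sp$max_delta, max(-sp$max_delta, dst))
        steer <<- min(sp$max_angle, max(-sp$max_angle, steer + dst))
      }
      d_prev_perc <<- d_pend_perc
      if (d_maneuver && abs(y - center) < 0.3 && abs(heading) < 0.01)
        d_maneuver <<- FALSE
      # high control persists t_hc seconds; the handoff additionally waits
      # for a near-neutral wheel so the passive phase never starts with the
      # wheel hard over (its small residual angle is what makes the car
      # drift back toward a lane edge). A lane-change manoeuvre keeps high
      # control until settled in the target lane.
      if (tm >= d_high_until && !d_maneuver && abs(steer) < 0.05)
        d_mode <<- "low"
    } else {
      edge_dist <- g$lane_width / 2 - abs(y - center)
      if (edge_dist < sp$dist) {
        d_mode <<- "high"
        d_high_until <<- tm + sp$t_hc
        d_prev_perc <<- d_pend_perc
      }
    }
    # headway to the fictional point moving at the target speed, measured
    # relative to the desired headway (0 at the set point)
    thw <- lp$thw_desired * (target_v / max(v, 1) - 1)
    if (d_follow) {
      phi <<- min(phi, 0)
    } else {
      phi <<- longitudinal_update(phi, thw, thw - d_thw_prev, Dt, lp)
    }
    d_thw_prev <<- thw
    d_last_motor <<- tm
    invisible(NULL)
  }

  ## ---- main event loop ----
  eps <- 1e-12
  repeat {
    d_gate <- if (variant == "problem_state" && d_phase == 1L)
      ns$ps_busy_until else -Inf
    proc_free <- k$busy_until[["procedural"]]
    s_d <- max(d_ready, d_gate, proc_free)
    s_n <- max(nb_ready, proc_free)
    if (min(s_d, s_n) >= dur) break
    who <- if (s_d < s_n - eps) "drive"
           else if (s_n < s_d - eps) "nback"
           else select_goal(c("drive", "nback"), k)

    if (who == "drive") {
      rec <- execute_production(k, p_drive[[d_phase]], d_ready, gate = d_gate)
      tc <- rec$ended
      if (d_phase == 1L) {
        # the visual module needs venc to encode the percept; the next
        # production of the iteration waits for it, procedural is free
        tp <- tc + venc
        occupy_resource(k, "visual", tp, "drive-encoding")
        advance_to(tp)
        center <- g$centers[d_target_lane + 1L]
        off <- center - y
        d_pend_perc <- list(theta_near = atan2(off, 10) - heading,
                            theta_far = atan2(off, 100) - heading)
        d_ready <- tp
        d_phase <- 2L
      } else if (d_phase == kprod) {
        motor_effect(tc)
        # the movement itself executes for mexec (motor module busy; the
        # next iteration pipelines, only its motor production queues)
        occupy_resource(k, "motor", tc + mexec, "drive-movement")
        d_ready <- tc
        d_phase <- 1L
      } else {
        d_ready <- tc
        d_phase <- d_phase + 1L
      }
    } else {
      switch(nb_phase,
        attend_sign = {
          rec <- execute_production(k, p_attend_sign, nb_ready)
          nb_phase <- "encode"; nb_ready <- rec$ended
        },
        encode = {
          # the problem-state module must finish encoding its previous
          # content before accepting the new sign
          rec <- execute_production(k, p_encode, nb_ready,
                                    gate = ns$ps_busy_until)
          te <- rec$ended
          ch <- encode_sign(signs$speed[sign_ptr], sign_ptr, ns, store, te)
          log_event(te, "sign_encoded", ch$speed)
          cur_sign_ord <- sign_ptr
          sign_ptr <- sign_ptr + 1L
          if (n == 0L) {
            pend_speed <- ch$speed
            recall_complete <- TRUE
            nb_phase <- "goal"; nb_ready <- te
          } else {
            avail <- ch$seq_pos - 1L
            wl <- min(n, avail)
            recall_complete <- (wl == n)
            if (wl == 0L) {
              to_idle(te)
            } else {
              in_rehearsal <- FALSE
              walk_remaining <- wl
              walk_len0 <- wl
              cur_chunk <- ch
              nb_phase <- "request"; nb_ready <- te
            }
          }
        },
        request = {
          rec <- execute_production(k, p_request, nb_ready)
          tr <- rec$ended
          res <- nback_step(store, cur_chunk, mpars, tr)
          if (res$failed) {
            log_event(tr, "recall_failure")
            to_idle(tr)
          } else {
            occupy_resource(k, "declarative", tr + res$latency, "retrieval")
            pending_chunk <- res$chunk
            nb_phase <- "harvest"; nb_ready <- tr + res$latency
          }
        },
        harvest = {
          # one swap at a time: the 200-ms problem-state encoding of the
          # previous swap must complete first (module seriality)
          rec <- execute_production(k, p_harvest, nb_ready,
                                    gate = ns$ps_busy_until)
          th <- rec$ended
          release_resource(k, "declarative", th)
          ps_swap(ns, pending_chunk, store, th)
          cur_chunk <- pending_chunk
          log_event(th, if (in_rehearsal) "rehearsal_swap" else "recall_swap",
                    pending_chunk$speed)
          walk_remaining <- walk_remaining - 1L
          if (walk_remaining > 0L) {
            nb_phase <- "request"; nb_ready <- th
          } else if (!in_rehearsal) {
            if (recall_complete) {
              pend_speed <- cur_chunk$speed
              nb_phase <- "goal"; nb_ready <- th
            } else start_rehearsal_or_idle(th)
          } else {
            rehears_remaining <- rehears_remaining - 1L
            if (rehears_remaining > 0L && walk_len0 > 0L) {
              walk_remaining <- walk_len0
              cur_chunk <- latest_chunk_from()
              nb_phase <- "request"; nb_ready <- th
            } else to_idle(th)
          }
        },
        goal = {
          rec <- execute_production(k, p_goal, nb_ready)
          tg <- rec$ended
          update_target_speed(pend_speed, ns, store, tg)
          truth <- if (cur_sign_ord - n >= 1L)
            signs$speed[cur_sign_ord - n] else NA_real_
          log_event(tg, "target_update", pend_speed, truth)
          target_v <- ns$goal_speed / 3.6
          start_rehearsal_or_idle(tg)
        },
        idle = {
          nb_ready <- Inf  # defensive; idle never wins the arbitration
        })
    }
  }
  advance_to(dur)

  lane_idx <- lane_of(g, tr_y)
  trace <- data.frame(
    time_s = seq_len(nstep) * dt,
    lat_pos_m = tr_y - g$centers[lane_idx + 1L],
    lane_index = lane_idx,
    steer_angle_rad = tr_st,
    phi = tr_ph,
    speed_kmh = tr_v * 3.6,
    long_pos_m = tr_x)
  flagged <- any(abs(tr_y) > g$boundaries[length(g$boundaries)] + 2)

  structure(list(
    trace = trace,
    events = data.frame(time_s = ev_t, type = ev_type, value = ev_val,
                        truth = ev_true, stringsAsFactors = FALSE),
    delays = delay_log(k),
    signs = signs,
    buildup = buildup, exp_start = buildup, exp_end = dur,
    road = road, n = n, variant = variant,
    flagged = flagged),
    class = "drive_block")
}
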