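# The 2 (road) x 5 (n-back) within-model design: a 20-block schedule whose
# first half pairs every condition once with strictly alternating road
# conditions and no n-back level twice in a row, mirrored in reverse for the
# second half; block execution and replicate-level aggregation.

#' Build the 20-block schedule
#'
#' The first ten blocks pair each n-back level (0-4) once with each road
#' condition such that the road alternates between every block and no
#' n-back level occurs twice in a row; the schedule is drawn uniformly among
#' valid orderings. Blocks 11-20 repeat blocks 10-1 in reverse order.
#'
#' @param seed Optional integer seed.
#' @return Data.frame with `block` (1-20), `road`, `n`.
#' @export
build_schedule <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roads <- c("highway", "construction")
  first <- sample(roads, 1L)
  road_seq <- rep(c(first, setdiff(roads, first)), 5L)
  repeat {
    n_a <- sample(0:4)          # levels for odd positions (road `first`)
    n_b <- sample(0:4)          # levels for even positions
    n_seq <- integer(10L)
    n_seq[seq(1, 9, 2)] <- n_a
    n_seq[seq(2, 10, 2)] <- n_b
    if (all(diff(n_seq) != 0L)) break
  }
  half <- data.frame(block = 1:10, road = road_seq, n = n_seq,
                     stringsAsFactors = FALSE)
  mirror <- half[10:1, ]
  mirror$block <- 11:20
  rownames(mirror) <- NULL
  rbind(half, mirror)
}

#' Run one block of the experiment
#'
#' Thin wrapper around [sim_block()] taking a schedule row.
#'
#' @param spec List or one-row data.frame with `road` and `n`.
#' @param variant `"central"` or `"problem_state"`.
#' @param cfg Configuration.
#' @param world_seed,cog_seed Integer seeds.
#' @return A `drive_block` (see [sim_block()]).
#' @export
run_block <- function(spec, variant, cfg = default_config(),
                      world_seed = 1L, cog_seed = 2L) {
  sim_block(spec$road, spec$n, variant, cfg,
            world_seed = world_seed, cog_seed = cog_seed)
}

# Child-seed table: schedule seed per replicate, a world seed per
# (replicate, block) shared across variants, and a cognition seed per
# (replicate, block, variant).
derive_seeds <- function(master_seed, replicates, n_blocks = 20L) {
  set.seed(master_seed)
  pool <- sample.int(.Machine$integer.max - 1L,
                     replicates * (1L + n_blocks * 3L))
  dim3 <- replicates * n_blocks
  list(schedule = pool[seq_len(replicates)],
       world = matrix(pool[replicates + seq_len(dim3)],
                      nrow = replicates),
       cog_central = matrix(pool[replicates + dim3 + seq_len(dim3)],
                            nrow = replicates),
       cog_problem_state = matrix(pool[replicates + 2L * dim3 +
                                         seq_len(dim3)],
                                  nrow = replicates))
}

#' Run the full experiment for one model variant
#'
#' Simulates `replicates` simulated participants, each performing the
#' 20-block mirrored schedule, and aggregates block metrics into
#' per-condition means. The declarative store resets between blocks. Child
#' seeds are derived deterministically from the master seed; the world seeds
#' (sign sequences, traffic, heading disturbance) are shared between the two
#' variants, so running both variants with the same master seed confronts
#' them with identical worlds.
#'
#' @param variant `"central"` or `"problem_state"`.
#' @param cfg Configuration.
#' @param master_seed Integer master seed.
#' @param replicates Number of simulated participants (defaults to the
#'   configured value).
#' @param keep_blocks If `TRUE`, the per-block `drive_block` objects are
#'   returned as well (memory-heavy).
#' @param out_dir Optional directory: per-block trace and event CSVs and the
#'   summary JSON are written there.
#' @return List of class `experiment_run`: `blocks` (per-block metric
#'   data.frame), `summary` (per-condition means), `variant`,
#'   `master_seed`.
#' @export
run_experiment <- function(variant, cfg = default_config(),
                           master_seed = 1L,
                           replicates = cfg$experiment$replicates,
                           keep_blocks = FALSE, out_dir = NULL) {
  validate_config(cfg)
  seeds <- derive_seeds(master_seed, replicates)
  cogkey <- paste0("cog_", variant)
  rows <- vector("list", replicates * 20L)
  kept <- if (keep_blocks) vector("list", replicates * 20L) else NULL
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ii <- 0L
  for (r in seq_len(replicates)) {
    sched <- build_schedule(seeds$schedule[r])
    for (b in seq_len(20L)) {
      ii <- ii + 1L
      blk <- sim_block(sched$road[b], sched$n[b], variant, cfg,
                       world_seed = seeds$world[r, b],
                       cog_seed = seeds[[cogkey]][r, b])
      met <- analyze_block(blk)
      met$replicate <- r
      met$block <- b
      rows[[ii]] <- met
      if (keep_blocks) kept[[ii]] <- blk
      if (!is.null(out_dir)) {
        stem <- file.path(out_dir, sprintf("rep%02d_block%02d", r, b))
        write_trace_csv(blk$trace, paste0(stem, "_trace.csv"))
        utils::write.csv(blk$events, paste0(stem, "_events.csv"),
                         row.names = FALSE)
      }
    }
  }
  blocks <- do.call(rbind, rows)
  summ <- condition_summary(blocks)
  out <- structure(list(blocks = blocks, summary = summ, variant = variant,
                        master_seed = master_seed,
                        replicates = replicates),
                   class = "experiment_run")
  if (keep_blocks) out$block_objects <- kept
  if (!is.null(out_dir))
    write_summary_json(out, file.path(out_dir, "summary.json"))
  out
}

#' Aggregate block metrics into per-condition means
#'
#' @param blocks Per-block metric data.frame from [run_experiment()].
#' @return Data.frame with one row per (road, n) cell and mean `srr`,
#'   `lane_dev`, `error_rate`, `cost_procedural`, `cost_problem_state`,
#'   `cost_total`, plus the number of contributing blocks.
#' @export
condition_summary <- function(blocks) {
  agg <- stats::aggregate(
    blocks[, c("srr", "lane_dev", "error_rate", "cost_procedural",
               "cost_problem_state", "cost_total")],
    by = list(road = blocks$road, n = blocks$n), FUN = mean)
  cnt <- stats::aggregate(list(n_blocks = blocks$srr),
                          by = list(road = blocks$road, n = blocks$n),
                          FUN = length)
  out <- merge(agg, cnt, by = c("road", "n"))
  out[order(out$road, out$n), ]
}
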