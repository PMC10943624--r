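# Pupillometry preprocessing: blink/artifact removal with +/- 25-sample
# margins and monotone cubic interpolation, followed by percent-change
# baselining against the median fixation pupil size in a baseline window.

#' Construct a pupil trace
#'
#' @param time_s Sample times (s), uniform 500-Hz grid.
#' @param diameter Pupil diameter (arbitrary units).
#' @param blinks Data.frame of pre-annotated blink intervals with columns
#'   `start`, `end` (s).
#' @param fixations Data.frame of fixation intervals, columns `start`, `end`.
#' @return List of class `pupil_trace`.
#' @export
pupil_trace <- function(time_s, diameter, blinks = NULL, fixations = NULL) {
  stopifnot(length(time_s) == length(diameter))
  empty <- data.frame(start = numeric(), end = numeric())
  if (is.null(blinks)) blinks <- empty
  if (is.null(fixations)) fixations <- empty
  chk <- function(iv) {
    if (nrow(iv) && (min(iv$start) < min(time_s) - 1e-9 ||
                     max(iv$end) > max(time_s) + 1e-9))
      stop("interval outside trace bounds")
    iv
  }
  structure(list(time_s = time_s, diameter = diameter,
                 blinks = chk(blinks), fixations = chk(fixations)),
            class = "pupil_trace")
}

in_intervals <- function(tt, iv) {
  out <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(iv)))
    out <- out | (tt >= iv$start[i] & tt <= iv$end[i])
  out
}

#' Despike a pupil trace
#'
#' Removes pre-annotated blink intervals and, on the blink-free samples,
#' any sample at least `sd_limit` standard deviations from the mean; each
#' removal is widened by `margin` samples (25 samples = 50 ms at 500 Hz) on
#' both sides. Gaps are filled by monotone cubic interpolation between the
#' flanking valid samples; gaps touching a trace boundary are filled by
#' nearest-valid extension.
#'
#' @param p A [pupil_trace()].
#' @param sd_limit SD threshold for artifact samples, default 4.
#' @param margin Samples removed on each side of a bad stretch, default 25.
#' @return The trace with `diameter` cleaned and a logical `interpolated`
#'   field marking replaced samples.
#' @export
despike_pupil <- function(p, sd_limit = 4, margin = 25L) {
  x <- p$diameter
  nx <- length(x)
  bad <- in_intervals(p$time_s, p$blinks)
  bad <- widen_mask(bad, margin)
  mu <- mean(x[!bad]); sdv <- stats::sd(x[!bad])
  if (is.finite(sdv) && sdv > 0) {
    spike <- !bad & abs(x - mu) >= sd_limit * sdv
    bad <- bad | widen_mask(spike, margin)
  }
  good <- which(!bad)
  if (length(good) < 2L) stop("too few valid samples to interpolate")
  fun <- stats::splinefun(p$time_s[good], x[good], method = "monoH.FC")
  xi <- x
  if (any(bad)) {
    idx <- which(bad)
    xi[idx] <- fun(p$time_s[idx])
    # nearest-valid extension at the boundaries
    first_good <- good[1L]; last_good <- good[length(good)]
    if (first_good > 1L) xi[seq_len(first_good - 1L)] <- x[first_good]
    if (last_good < nx) xi[(last_good + 1L):nx] <- x[last_good]
  }
  p$diameter <- xi
  p$interpolated <- bad
  p
}

widen_mask <- function(mask, margin) {
  if (!any(mask) || margin <= 0L) return(mask)
  idx <- which(mask)
  lo <- pmax(1L, idx - margin)
  hi <- pmin(length(mask), idx + margin)
  out <- logical(length(mask))
  for (i in seq_along(idx)) out[lo[i]:hi[i]] <- TRUE
  out
}

#' Baseline-normalize a pupil trace
#'
#' The baseline is the median pupil size of the fixation samples inside the
#' baseline window (the 5 s after the start of the experiment and 5 s before
#' the first speed sign); the output is the percent change
#' `100 * (x - m) / m`. When condition labels are supplied, the mean percent
#' change over fixation samples is returned per condition cell.
#'
#' @param p A (despiked) [pupil_trace()].
#' @param baseline_window `c(t0, t1)` (s).
#' @param groups Optional data.frame with `start`, `end` and label columns
#'   (e.g. `road`, `n`); means are computed over fixation samples within
#'   each group interval.
#' @return List: `pct` (percent-change series), `baseline`,
#'   `fixation_mean` (overall mean percent change over fixations), and
#'   `group_means` when `groups` is given.
#' @export
baseline_normalize <- function(p, baseline_window, groups = NULL) {
  stopifnot(length(baseline_window) == 2L,
            baseline_window[1] < baseline_window[2])
  fix <- in_intervals(p$time_s, p$fixations)
  base_sel <- fix & p$time_s >= baseline_window[1] &
    p$time_s <= baseline_window[2]
  if (!any(base_sel)) stop("no fixation samples in the baseline window")
  m <- stats::median(p$diameter[base_sel])
  pct <- 100 * (p$diameter - m) / m
  out <- list(pct = pct, baseline = m,
              fixation_mean = mean(pct[fix]))
  if (!is.null(groups)) {
    gm <- groups
    gm$mean_pct <- vapply(seq_len(nrow(groups)), function(i) {
      sel <- fix & p$time_s >= groups$start[i] & p$time_s <= groups$end[i]
      if (!any(sel)) NA_real_ else mean(pct[sel])
    }, numeric(1))
    out$group_means <- gm
  }
  out
}
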