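#' Basal (diastolic) fluorescence statistics of one cell
#'
#' Estimates the mean and SD of the basal F/F0 level from diastolic samples,
#' with iterative exclusion of samples more than \code{sd_mult} SDs above
#' the running mean (upward excursions are calcium events, so trimming is
#' one-sided), until convergence or 10 iterations. The 2-SD band derived
#' from these statistics defines both the SCR detection threshold and the
#' event duration (time between the bounding 2-SD crossings).
#'
#' @param y F/F0 trace of one cell.
#' @param times frame times (s).
#' @param protocol a \code{\link{ca_protocol}}.
#' @param exclusion_s length (s) of the stimulus-locked window excluded from
#'   the initial diastolic sample set; default \code{0.8 / rate_hz}.
#' @param sd_mult trimming multiplier, default 2.
#' @return list \code{mean}, \code{sd}, \code{n_kept}, \code{n_total},
#'   \code{degenerate} (TRUE when the SD collapsed to 0, e.g. on a constant
#'   trace, in which case downstream thresholding must fall back to the
#'   amplitude rule alone).
#' @export
estimate_basal_stats <- function(y, times, protocol,
                                 exclusion_s = NULL, sd_mult = 2) {
  if (is.null(exclusion_s)) exclusion_s <- 0.8 / protocol$rate_hz
  keep <- rep(TRUE, length(times))
  for (s in protocol$stimulus_times) {
    keep[times >= s - 1e-9 & times < s + exclusion_s] <- FALSE
  }
  x <- y[keep]
  if (length(x) < 20) {
    stop("fewer than 20 diastolic samples; cannot estimate basal statistics")
  }
  n_total <- length(x)
  for (it in 1:10) {
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    inlier <- x <= m + sd_mult * s
    if (all(inlier)) break
    x <- x[inlier]
  }
  m <- mean(x)
  s <- stats::sd(x)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) s <- 0
  list(mean = m, sd = s, n_kept = length(x), n_total = n_total,
       degenerate = degenerate)
}

#' Detect spontaneous diastolic calcium release (SCR) events
#'
#' Within each diastolic interval (from the first return of the trace below
#' basal mean + 2 SD after a paced peak, to the next stimulus; after the
#' pace-stop time the entire tail is diastolic) candidate events are
#' contiguous regions above basal mean + 2 SD. Candidates separated by less
#' than \code{merge_gap_s} are merged; merged regions containing several
#' peaks separated by a pronounced dip are split back into individual
#' events. A candidate becomes an SCR event iff its amplitude (peak minus
#' basal mean) is at least \code{threshold_frac} times the cell's mean
#' accepted paced-transient amplitude — the "at least 10% of the triggered
#' transient" inclusion rule. Event duration is the time between the
#' bounding 2-SD crossings.
#'
#' @param norm a \code{\link{normalize_recording}} result.
#' @param transients a \code{\link{detect_paced_transients}} result for the
#'   same recording (defines the per-cell amplitude reference; cells with no
#'   accepted transients use the recording-level mean, flagged).
#' @param threshold_frac relative amplitude threshold, default 0.10.
#' @param sd_mult basal-SD multiplier, default 2.
#' @param merge_gap_s sub-threshold gaps shorter than this are bridged,
#'   default 0.05 s.
#' @param split_depth_frac a merged region is split at an interior minimum
#'   when both flanking peaks exceed it by \code{max(sd_mult * basal_sd,
#'   split_depth_frac * region amplitude)}; default 0.25.
#' @return object of class \code{ca_scr}: list with \code{events}
#'   (data.frame \code{cell}, \code{onset_s}, \code{peak_s},
#'   \code{amplitude}, \code{duration_s}, \code{interval_index}),
#'   \code{exposure} (data.frame \code{cell}, \code{exposure_s}),
#'   \code{thresholds} (per-cell basal stats and amplitude reference),
#'   \code{params}.
#' @export
detect_scr <- function(norm, transients, threshold_frac = 0.10,
                       sd_mult = 2, merge_gap_s = 0.05,
                       split_depth_frac = 0.25) {
  stopifnot(inherits(norm, "ca_norm"))
  times <- norm$times
  dt <- stats::median(diff(times))
  proto <- norm$protocol
  stims <- proto$stimulus_times
  n_frames <- length(times)
  ref_all <- if (nrow(transients)) mean(transients$amplitude) else NA_real_
  ev <- list()
  expo <- numeric(length(norm$cells))
  thr_rows <- list()
  for (ci in seq_along(norm$cells)) {
    cell <- norm$cells[ci]
    y <- norm$fnorm[ci, ]
    bs <- estimate_basal_stats(y, times, proto, sd_mult = sd_mult)
    thr <- bs$mean + sd_mult * bs$sd
    tr_c <- transients[transients$cell == cell, , drop = FALSE]
    ref <- if (nrow(tr_c)) mean(tr_c$amplitude) else ref_all
    ref_flag <- if (nrow(tr_c)) "cell" else
      if (is.finite(ref)) "recording" else "none"
    thr_rows[[ci]] <- data.frame(
      cell = cell, basal_mean = bs$mean, basal_sd = bs$sd,
      threshold = thr, ref_amplitude = ref, ref_source = ref_flag,
      degenerate = bs$degenerate, stringsAsFactors = FALSE)

    # diastolic intervals for this cell
    iv_start <- numeric(0); iv_end <- numeric(0)
    bounds <- c(stims, Inf)
    first_stim <- if (length(stims)) stims[1] else Inf
    if (times[1] < first_stim) {
      iv_start <- times[1]
      iv_end <- min(first_stim, times[n_frames])
    }
    for (si in seq_along(stims)) {
      nxt <- if (si < length(stims)) stims[si + 1] else times[n_frames]
      pk_c <- tr_c[tr_c$stim_index == si, , drop = FALSE]
      t_from <- if (nrow(pk_c)) {
        # first return below the 2-SD band after the paced peak
        cand <- which(times > pk_c$t_peak[1] & y < thr)
        cand <- cand[times[cand] <= nxt + 1e-9]
        if (length(cand)) times[cand[1]] else NA_real_
      } else stims[si] + 0.1  # failed beat: skip just the stimulus artifact
      if (is.finite(t_from) && t_from < nxt) {
        iv_start <- c(iv_start, t_from)
        iv_end <- c(iv_end, nxt)
      }
    }
    expo[ci] <- sum(iv_end - iv_start)

    above <- y > thr
    for (ii in seq_along(iv_start)) {
      ix <- which(times >= iv_start[ii] & times < iv_end[ii])
      if (length(ix) < 2) next
      a <- above[ix]
      if (!any(a)) next
      r <- rle(a)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- data.frame(s = starts[r$values], e = ends[r$values])
      # merge runs separated by < merge_gap_s, but only when both flanking
      # runs rise clearly above the noise band (2 x the threshold
      # multiplier): a bare noise spike next to an event must not be glued
      # to it, or onsets drift early and durations inflate
      if (nrow(runs) > 1) {
        substantial <- bs$mean + 2 * sd_mult * bs$sd
        run_max <- vapply(seq_len(nrow(runs)),
                          function(q) max(y[ix[runs$s[q]:runs$e[q]]]),
                          numeric(1))
        merged <- runs[1, ]
        last_max <- run_max[1]
        for (q in 2:nrow(runs)) {
          gap <- (runs$s[q] - merged$e[nrow(merged)] - 1) * dt
          if (gap < merge_gap_s &&
              min(last_max, run_max[q]) >= substantial) {
            merged$e[nrow(merged)] <- runs$e[q]
            last_max <- max(last_max, run_max[q])
          } else {
            merged <- rbind(merged, runs[q, ])
            last_max <- run_max[q]
          }
        }
        runs <- merged
      }
      for (q in seq_len(nrow(runs))) {
        seg_ix <- ix[runs$s[q]:runs$e[q]]
        seg <- y[seg_ix]
        depth <- max(sd_mult * bs$sd,
                     split_depth_frac * (max(seg) - bs$mean))
        sp <- split_points_at_minima(seg, depth)
        cut_at <- c(0L, sp, length(seg))
        for (p in seq_len(length(cut_at) - 1)) {
          sub <- (cut_at[p] + 1):cut_at[p + 1]
          sub_ix <- seg_ix[sub]
          amp <- max(y[sub_ix]) - bs$mean
          if (is.finite(ref) && amp < threshold_frac * ref) next
          ev[[length(ev) + 1]] <- data.frame(
            cell = cell,
            onset_s = times[sub_ix[1]],
            peak_s = times[sub_ix[which.max(y[sub_ix])]],
            amplitude = amp,
            duration_s = length(sub_ix) * dt,
            interval_index = ii, stringsAsFactors = FALSE)
        }
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(cell = character(), onset_s = numeric(), peak_s = numeric(),
               amplitude = numeric(), duration_s = numeric(),
               interval_index = integer(), stringsAsFactors = FALSE)
  events <- events[order(events$onset_s, events$cell), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(
    events = events,
    exposure = data.frame(cell = norm$cells, exposure_s = expo,
                          stringsAsFactors = FALSE),
    thresholds = do.call(rbind, thr_rows),
    params = list(threshold_frac = threshold_frac, sd_mult = sd_mult,
                  merge_gap_s = merge_gap_s,
                  split_depth_frac = split_depth_frac)),
    class = "ca_scr")
}

#' Summarize SCR events per cell and per recording
#'
#' @param scr a \code{\link{detect_scr}} result.
#' @return object of class \code{ca_scr_summary}: list with \code{per_cell}
#'   (data.frame \code{cell}, \code{n_events}, \code{exposure_s},
#'   \code{rate_hz}), \code{fraction_active} (cells with >= 1 event /
#'   n cells), \code{mean_rate_hz} (pooled: total events / total exposure),
#'   \code{n_cells}.
#' @export
summarize_scr <- function(scr) {
  stopifnot(inherits(scr, "ca_scr"))
  expo <- scr$exposure
  if (any(expo$exposure_s <= 0)) stop("zero diastolic exposure for cell(s) ",
    paste(expo$cell[expo$exposure_s <= 0], collapse = ", "))
  cnt <- table(factor(scr$events$cell, levels = expo$cell))
  per_cell <- data.frame(cell = expo$cell,
                         n_events = as.integer(cnt),
                         exposure_s = expo$exposure_s,
                         rate_hz = as.integer(cnt) / expo$exposure_s,
                         stringsAsFactors = FALSE)
  structure(list(per_cell = per_cell,
                 fraction_active = mean(per_cell$n_events >= 1),
                 mean_rate_hz = sum(per_cell$n_events) /
                   sum(per_cell$exposure_s),
                 n_cells = nrow(per_cell)),
            class = "ca_scr_summary")
}

#' Pace-stop latency to the first SCR
#'
#' For pace-stop recordings: per cell, the latency from the pacing stop time
#' to the onset of the first subsequent SCR event; cells with no post-stop
#' event are right-censored at (recording end - stop time). Events before
#' the stop are ignored.
#'
#' @param scr a \code{\link{detect_scr}} result.
#' @param protocol the recording's \code{\link{ca_protocol}} (must carry
#'   \code{stop_time}).
#' @param t_end recording end time (s).
#' @return data.frame of class \code{ca_pace_stop}: \code{cell},
#'   \code{latency_s}, \code{censored}, \code{wave} (whether the first
#'   event's amplitude reached 50% of the cell's transient reference,
#'   a crude macro-event/wave flag).
#' @export
pace_stop_latency <- function(scr, protocol, t_end) {
  stopifnot(inherits(scr, "ca_scr"))
  if (is.null(protocol$stop_time)) {
    stop("protocol has no stop_time: pace-stop latency is undefined")
  }
  stop_t <- protocol$stop_time
  cens_at <- t_end - stop_t
  rows <- lapply(seq_len(nrow(scr$exposure)), function(ci) {
    cell <- scr$exposure$cell[ci]
    e <- scr$events[scr$events$cell == cell &
                      scr$events$onset_s > stop_t, , drop = FALSE]
    if (nrow(e)) {
      first <- e[which.min(e$onset_s), ]
      ref <- scr$thresholds$ref_amplitude[scr$thresholds$cell == cell]
      data.frame(cell = cell, latency_s = first$onset_s - stop_t,
                 censored = FALSE,
                 wave = is.finite(ref) && first$amplitude >= 0.5 * ref,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cell = cell, latency_s = cens_at, censored = TRUE,
                 wave = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ca_pace_stop", "data.frame")
  attr(out, "stop_time") <- stop_t
  out
}
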