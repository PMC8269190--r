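#' Simulation configuration for a synthetic slice recording
#'
#' Defines the generative model of a multicellular slice experiment: a grid
#' of cells paced by field stimuli, each paced beat producing a
#' double-exponential calcium transient, with optional beta-adrenergic
#' (norepinephrine) modulation, spontaneous diastolic calcium release (SCR)
#' events drawn from a per-cell Poisson hazard, neighbor-coupling hazard
#' amplification (a cell whose neighbor has an ongoing SCR has its hazard
#' multiplied by \code{k}, emulating a source-sink-source interaction), and
#' beat-to-beat amplitude alternans in a configurable subset of cells.
#'
#' Defaults follow the experimental conditions the package is designed to
#' analyze: 2 Hz pacing, transient amplitude 1.0 dF/F0, decay tau 0.30 s,
#' SCR rate 0.4 events/s/cell for stimulated mutant tissue (the published
#' per-cell rate), SCR bump amplitude 30% of the transient, SCR duration
#' 0.915 +/- 0.07 s measured between 2-SD threshold crossings, and NE
#' multipliers amplitude x1.4, decay x0.7, SCR rate x4 (the reported
#' "about fourfold" rate increase).
#'
#' @param n_rows,n_cols cell grid dimensions.
#' @param duration_s recording length (s).
#' @param frame_interval_s frame interval (s); default 0.02 (50 Hz imaging).
#' @param pacing list: \code{rate_hz}, \code{start_s} (first stimulus),
#'   \code{stop_time_s} (pace-stop time, or NULL to pace throughout).
#' @param kernel list: \code{amplitude} (dF/F0), \code{tau_rise_s},
#'   \code{tau_decay_s} of the paced-transient kernel.
#' @param ne list: \code{on}, \code{amp_mult}, \code{decay_mult},
#'   \code{scr_rate_mult} (applied when \code{on = TRUE}).
#' @param scr list: \code{base_rate_hz} (per-cell diastolic Poisson hazard
#'   lambda), \code{amp_frac} (bump amplitude as fraction of the cell's
#'   transient amplitude), \code{dur_mean_s}, \code{dur_sd_s} (2-SD-crossing
#'   duration distribution), \code{refractory_s} (per-cell dead time after an
#'   event; 0 = pure Poisson), \code{tau_rise_s}, \code{tau_decay_s} (base
#'   bump shape, time-rescaled per event to hit the drawn duration),
#'   \code{post_stim_blank_s} (length of the stimulus-locked window in which
#'   no SCR onset may occur; NULL = derived from the transient kernel).
#' @param coupling list: \code{k} >= 1, hazard multiplier applied to cells
#'   with at least one neighbor whose SCR is ongoing.
#' @param alternans list: \code{cells} (integer indices of alternating
#'   cells, or NULL to use \code{fraction}), \code{fraction},
#'   \code{delta} (relative amplitude drop of small beats, scalar or one per
#'   alternating cell), \code{n_beats} (how many initial transients
#'   alternate; Inf = all; scalar or per-cell), \code{tau_large_s},
#'   \code{tau_small_s} (optional per-phase decay constants).
#' @param noise list: \code{sd} (Gaussian SD on raw F), \code{f0} (baseline
#'   raw fluorescence).
#' @param seed integer seed; mandatory (simulation is bit-reproducible).
#' @return an object of class \code{ca_sim_config}.
#' @export
sim_config <- function(n_rows = 5, n_cols = 8,
                       duration_s = 120, frame_interval_s = 0.02,
                       pacing = list(), kernel = list(), ne = list(),
                       scr = list(), coupling = list(), alternans = list(),
                       noise = list(), seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  merge1 <- function(defaults, given) {
    utils::modifyList(defaults, as.list(given))
  }
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    duration_s = duration_s, frame_interval_s = frame_interval_s,
    pacing = merge1(list(rate_hz = 2, start_s = 0.5, stop_time_s = NULL),
                    pacing),
    kernel = merge1(list(amplitude = 1.0, tau_rise_s = 0.03,
                         tau_decay_s = 0.30), kernel),
    ne = merge1(list(on = FALSE, amp_mult = 1.4, decay_mult = 0.7,
                     scr_rate_mult = 4), ne),
    scr = merge1(list(base_rate_hz = 0, amp_frac = 0.3,
                      dur_mean_s = 0.915, dur_sd_s = 0.07,
                      refractory_s = 0, tau_rise_s = 0.05,
                      tau_decay_s = 0.33, post_stim_blank_s = NULL), scr),
    coupling = merge1(list(k = 1), coupling),
    alternans = merge1(list(cells = NULL, fraction = 0, delta = 0,
                            n_beats = Inf, tau_large_s = NULL,
                            tau_small_s = NULL), alternans),
    noise = merge1(list(sd = 1.0, f0 = 100), noise),
    seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_rows >= 1, n_cols >= 1, duration_s > 0, frame_interval_s > 0,
              pacing$rate_hz > 0, kernel$amplitude > 0,
              scr$base_rate_hz >= 0, coupling$k >= 1,
              alternans$fraction >= 0, alternans$fraction <= 1,
              all(alternans$delta >= 0), noise$sd >= 0, noise$f0 > 0)
  })
  structure(cfg, class = "ca_sim_config")
}

# Effective (NE-adjusted) generative parameters
sim_effective <- function(cfg) {
  amp <- cfg$kernel$amplitude
  tau_d <- cfg$kernel$tau_decay_s
  lam <- cfg$scr$base_rate_hz
  if (isTRUE(cfg$ne$on)) {
    amp <- amp * cfg$ne$amp_mult
    tau_d <- tau_d * cfg$ne$decay_mult
    lam <- lam * cfg$ne$scr_rate_mult
  }
  list(amplitude = amp, tau_rise = cfg$kernel$tau_rise_s, tau_decay = tau_d,
       lambda = lam)
}

# Stimulus-locked blanking window (s): time from a stimulus within which the
# paced transient dominates and no SCR onset is generated. Derived so the
# kernel has decayed to the 2-SD basal band (or to 1% of its amplitude when
# the configured noise is zero).
sim_blank_window <- function(cfg, eff) {
  if (!is.null(cfg$scr$post_stim_blank_s)) return(cfg$scr$post_stim_blank_s)
  thr_rel <- max(2 * cfg$noise$sd / cfg$noise$f0, 0.01 * eff$amplitude)
  tp <- kernel_peak_time(eff$tau_rise, eff$tau_decay)
  tp + eff$tau_decay * log(max(eff$amplitude / thr_rel, 2))
}

#' Simulate a multicellular slice recording with ground truth
#'
#' Generates raw fluorescence per cell as
#' \code{F = f0 * (1 + sum(paced kernels) + sum(SCR bumps)) + noise}.
#' SCR onsets are an inhomogeneous Poisson process restricted to diastolic
#' intervals; while any adjacent cell has an ongoing SCR the per-cell hazard
#' is multiplied by \code{coupling$k}. Identical config + seed gives
#' bit-identical output.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{recording} (a
#'   \code{\link{ca_recording}}, geometry attached, grid-rook adjacency
#'   derivable) and \code{truth} (list: \code{transients}, \code{scr_events},
#'   \code{alternans} data frames plus scalars used by tests).
#' @export
simulate_slice_recording <- function(config) {
  stopifnot(inherits(config, "ca_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  eff <- sim_effective(cfg)
  dt <- cfg$frame_interval_s
  times <- seq(0, cfg$duration_s, by = dt)
  n_frames <- length(times)
  n <- cfg$n_rows * cfg$n_cols
  cells <- paste0("cell_", seq_len(n))
  if (dt > eff$tau_rise) {
    warning("frame interval exceeds rise tau: transients are undersampled")
  }

  # stimuli
  t_end_pace <- if (!is.null(cfg$pacing$stop_time_s)) {
    min(cfg$pacing$stop_time_s, cfg$duration_s)
  } else cfg$duration_s
  if (t_end_pace - 1e-9 < cfg$pacing$start_s) {
    stop("duration too short to contain one stimulus")
  }
  stims <- seq(cfg$pacing$start_s, t_end_pace - 1e-9, by = 1 / cfg$pacing$rate_hz)
  n_stims <- length(stims)

  # geometry + adjacency (grid, 20 um pitch)
  rows <- rep(seq_len(cfg$n_rows), each = cfg$n_cols)
  cols <- rep(seq_len(cfg$n_cols), times = cfg$n_rows)
  geom <- ca_geometry(cells, x_um = cols * 20, y_um = rows * 20,
                      row = rows, col = cols, diameter_um = 20)
  adj <- adjacency_from_geometry(geom, "grid-rook")
  nb_idx <- lapply(neighbor_list(adj), function(v) match(v, cells))

  # per-cell per-beat amplitudes and decay taus (alternans pattern)
  alt_cells <- cfg$alternans$cells
  if (is.null(alt_cells) && cfg$alternans$fraction > 0) {
    alt_cells <- seq_len(max(0L, round(cfg$alternans$fraction * n)))
  }
  alt_cells <- as.integer(alt_cells)
  delta <- rep_len(cfg$alternans$delta, max(1L, length(alt_cells)))
  nbeats <- rep_len(cfg$alternans$n_beats, max(1L, length(alt_cells)))
  amp_mat <- matrix(eff$amplitude, n, n_stims)
  tau_mat <- matrix(eff$tau_decay, n, n_stims)
  tau_lg <- cfg$alternans$tau_large_s
  tau_sm <- cfg$alternans$tau_small_s
  for (j in seq_along(alt_cells)) {
    c_ix <- alt_cells[j]
    small <- (seq_len(n_stims) %% 2 == 0) & (seq_len(n_stims) <= nbeats[j])
    amp_mat[c_ix, small] <- eff$amplitude * (1 - delta[j])
    if (!is.null(tau_lg) && !is.null(tau_sm)) {
      tl <- if (isTRUE(cfg$ne$on)) tau_lg * cfg$ne$decay_mult else tau_lg
      ts <- if (isTRUE(cfg$ne$on)) tau_sm * cfg$ne$decay_mult else tau_sm
      tau_mat[c_ix, ] <- ifelse(small, ts, tl)
    }
  }

  # diastolic frame mask (shared by all cells)
  blank <- sim_blank_window(cfg, eff)
  diastolic <- rep(TRUE, n_frames)
  for (s in stims) {
    diastolic[times >= s - 1e-9 & times < s + blank] <- FALSE
  }

  # --- SCR event placement ---
  lam <- eff$lambda
  k <- cfg$coupling$k
  ev_cell <- integer(0); ev_onset <- numeric(0); ev_dur <- numeric(0)
  ev_coupled <- logical(0)
  draw_dur <- function(m) {
    pmax(stats::rnorm(m, cfg$scr$dur_mean_s, cfg$scr$dur_sd_s), 4 * dt)
  }
  if (lam > 0) {
    if (k == 1 && cfg$scr$refractory_s == 0) {
      # homogeneous Poisson on the diastolic frames: sample counts then frames
      d_ix <- which(diastolic)
      exposure <- length(d_ix) * dt
      for (c_ix in seq_len(n)) {
        m <- stats::rpois(1, lam * exposure)
        if (m > 0) {
          f_ix <- sort(sample(d_ix, m, replace = TRUE))
          ev_cell <- c(ev_cell, rep(c_ix, m))
          ev_onset <- c(ev_onset, times[f_ix])
          ev_dur <- c(ev_dur, draw_dur(m))
          ev_coupled <- c(ev_coupled, rep(FALSE, m))
        }
      }
    } else {
      # frame-stepping with neighbor hazard amplification and refractoriness
      busy_until <- numeric(n)
      refrac_until <- numeric(n)
      for (i in which(diastolic)) {
        t_i <- times[i]
        active <- busy_until > t_i
        nb_active <- vapply(nb_idx, function(ix) any(active[ix]), logical(1))
        hz <- lam * ifelse(nb_active, k, 1)
        hz[t_i < refrac_until] <- 0
        p <- -expm1(-hz * dt)
        fire <- stats::runif(n) < p
        if (any(fire)) {
          for (c_ix in which(fire)) {
            dur <- draw_dur(1)
            ev_cell <- c(ev_cell, c_ix)
            ev_onset <- c(ev_onset, t_i)
            ev_dur <- c(ev_dur, dur)
            ev_coupled <- c(ev_coupled, nb_active[c_ix])
            busy_until[c_ix] <- max(busy_until[c_ix], t_i + dur)
            refrac_until[c_ix] <- busy_until[c_ix] + cfg$scr$refractory_s
          }
        }
      }
    }
  }

  # --- waveform assembly ---
  sig <- matrix(0, n, n_frames)
  tau_r <- eff$tau_rise
  for (b in seq_len(n_stims)) {
    taus <- tau_mat[, b]
    for (tau_u in unique(taus)) {
      span <- min(n_frames, floor((stims[b] + tau_u * log(1e4)) / dt) + 1)
      i0 <- floor(stims[b] / dt) + 1
      if (i0 > n_frames) next
      idx <- i0:span
      kv <- transient_kernel(times[idx] - stims[b], tau_r, tau_u)
      rows_u <- which(taus == tau_u)
      sig[rows_u, idx] <- sig[rows_u, idx] +
        matrix(kv, length(rows_u), length(idx), byrow = TRUE) *
        amp_mat[rows_u, b]
    }
  }
  ev_amp <- numeric(length(ev_cell))
  if (length(ev_cell)) {
    # bump amplitude = amp_frac x that cell's (mean) transient amplitude;
    # time-rescale the base bump so its width above the 2-SD band equals the
    # drawn duration
    cell_amp <- rowMeans(amp_mat)
    thr_rel <- 2 * cfg$noise$sd / cfg$noise$f0
    width_memo <- new.env(parent = emptyenv())
    for (e in seq_along(ev_cell)) {
      a <- cfg$scr$amp_frac * cell_amp[ev_cell[e]]
      ev_amp[e] <- a
      lev <- if (thr_rel > 0) thr_rel / a else 1 / 15
      lev <- min(max(lev, 0.005), 0.5)
      key <- sprintf("%.6g", lev)
      if (is.null(width_memo[[key]])) {
        width_memo[[key]] <- kernel_width_at_level(
          lev, cfg$scr$tau_rise_s, cfg$scr$tau_decay_s)
      }
      sc <- ev_dur[e] / width_memo[[key]]
      span_s <- sc * cfg$scr$tau_decay_s * log(1e4)
      i0 <- floor(ev_onset[e] / dt) + 1
      i1 <- min(n_frames, floor((ev_onset[e] + span_s) / dt) + 1)
      if (i0 > n_frames) next
      idx <- i0:i1
      sig[ev_cell[e], idx] <- sig[ev_cell[e], idx] +
        a * transient_kernel((times[idx] - ev_onset[e]) / sc,
                             cfg$scr$tau_rise_s, cfg$scr$tau_decay_s)
    }
  }
  fluor <- cfg$noise$f0 * (1 + sig)
  if (cfg$noise$sd > 0) {
    fluor <- fluor + matrix(stats::rnorm(n * n_frames, 0, cfg$noise$sd),
                            n, n_frames)
    fluor[fluor < 0] <- 0
  }
  rownames(fluor) <- cells

  proto <- ca_protocol(stims, cfg$pacing$rate_hz,
                       stop_time = cfg$pacing$stop_time_s)
  meta <- list(simulated = TRUE, seed = cfg$seed, ne = isTRUE(cfg$ne$on))
  rec <- ca_recording(fluor, times, proto, geometry = geom, cells = cells,
                      meta = meta)

  truth_tr <- data.frame(
    cell = rep(cells, n_stims),
    stim_index = rep(seq_len(n_stims), each = n),
    time = rep(stims, each = n),
    amplitude = as.vector(amp_mat),
    tau = as.vector(tau_mat), stringsAsFactors = FALSE)
  truth_ev <- data.frame(cell = cells[ev_cell], onset = ev_onset,
                         amplitude = ev_amp, duration = ev_dur,
                         coupled = ev_coupled, stringsAsFactors = FALSE)
  if (length(ev_cell)) truth_ev <- truth_ev[order(ev_onset, ev_cell), ,
                                            drop = FALSE]
  truth_alt <- data.frame(
    cell = cells, alternating = FALSE,
    delta = 0, n_beats = NA_real_, stringsAsFactors = FALSE)
  if (length(alt_cells)) {
    truth_alt$delta[alt_cells] <- delta
    truth_alt$n_beats[alt_cells] <- nbeats
    # a cell counts as truly alternating only if its pattern satisfies the
    # >=10% / >=10-transient rule it is meant to exercise
    truth_alt$alternating[alt_cells] <-
      delta >= 0.10 & pmin(nbeats, n_stims) >= 10
  }
  d_frames <- sum(diastolic)
  truth <- list(transients = truth_tr, scr_events = truth_ev,
                alternans = truth_alt, adjacency = adj,
                diastolic_exposure_s = d_frames * dt,
                blank_window_s = blank, effective = eff)
  list(recording = rec, truth = truth)
}

#' Simulate a line-scan kymograph of a traveling calcium wave
#'
#' Produces a position x time fluorescence matrix in which a sigmoidal
#' wavefront advances along the scanned line at a constant speed, plus
#' optional Gaussian noise. The front position at time t is
#' \code{x = speed * (t - t0)}; the half-maximum crossing of the noiseless
#' profile sits exactly on that line, which is what the wavefront detector
#' estimates.
#'
#' @param speed_um_s true propagation speed (micrometers/s); > 0.
#' @param cell_length_um scanned line length (micrometers).
#' @param pixel_um pixel size along the line (micrometers).
#' @param line_interval_s time between scanned lines (s); line-scan imaging
#'   runs at ~1 line / 1.8 ms.
#' @param amplitude fluorescence amplitude of the invaded region (raw units
#'   above basal).
#' @param basal_f basal raw fluorescence.
#' @param front_width_um sigmoid steepness parameter (micrometers).
#' @param noise_sd Gaussian noise SD (raw units).
#' @param t0_s time at which the front enters at position 0.
#' @param seed integer seed (used only when \code{noise_sd > 0}, but always
#'   set for reproducibility).
#' @return list with \code{kymograph} (class \code{ca_kymograph}: list of
#'   \code{mat} [n_positions x n_lines], \code{pixel_um},
#'   \code{line_interval_s}, \code{meta}) and \code{truth} (list with
#'   \code{speed_um_s}, \code{t0_s}).
#' @export
simulate_kymograph <- function(speed_um_s, cell_length_um = 100,
                               pixel_um = 1, line_interval_s = 0.002,
                               amplitude = 150, basal_f = 100,
                               front_width_um = 2, noise_sd = 0,
                               t0_s = 0.05, seed = 1) {
  stopifnot(speed_um_s > 0, cell_length_um / pixel_um >= 8)
  t_cross <- cell_length_um / speed_um_s
  if (t_cross < 3 * line_interval_s) {
    stop("front exits the cell before 3 lines are recorded")
  }
  set.seed(seed)
  x <- seq(0, cell_length_um - pixel_um, by = pixel_um) + pixel_um / 2
  tt <- seq(0, t0_s + t_cross + 0.1 * t_cross, by = line_interval_s)
  front <- speed_um_s * (tt - t0_s)
  mat <- basal_f + amplitude /
    (1 + exp(outer(x, front, `-`) / front_width_um))
  if (noise_sd > 0) {
    mat <- mat + matrix(stats::rnorm(length(mat), 0, noise_sd),
                        nrow(mat), ncol(mat))
  }
  kym <- structure(list(mat = mat, pixel_um = pixel_um,
                        line_interval_s = line_interval_s,
                        meta = list(simulated = TRUE, seed = seed)),
                   class = "ca_kymograph")
  list(kymograph = kym, truth = list(speed_um_s = speed_um_s, t0_s = t0_s))
}
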