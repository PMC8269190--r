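# shared helpers for synthetic-data-driven tests

# greedy one-to-one matching of detected to true SCR events by cell and
# onset proximity; returns counts for precision/recall
match_events <- function(detected, truth, tol_s) {
  used <- rep(FALSE, nrow(detected))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    j <- which(!used & detected$cell == truth$cell[i] &
                 abs(detected$onset_s - truth$onset[i]) <= tol_s + 1e-9)
    if (length(j)) {
      used[j[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_true = nrow(truth), n_detected = nrow(detected),
       matched = matched,
       recall = matched / max(nrow(truth), 1L),
       precision = matched / max(nrow(detected), 1L))
}

# ground-truth SCR events reshaped to the detector's column convention
truth_events <- function(truth) {
  data.frame(cell = truth$scr_events$cell,
             onset_s = truth$scr_events$onset,
             duration_s = truth$scr_events$duration,
             stringsAsFactors = FALSE)
}

# small paced recording built directly from the kernel (no generator RNG),
# for hand-constructed detector tests; bumps: data.frame(cell_index, onset,
# amplitude, width_s)
build_recording <- function(stims, duration_s = 20, dt = 0.01, n_cells = 1,
                            amplitude = 1, tau_rise = 0.03, tau_decay = 0.3,
                            bumps = NULL, noise_sd = 0, f0 = 100,
                            rate_hz = 1, seed = 1, stop_time = NULL) {
  times <- seq(0, duration_s, by = dt)
  sig <- matrix(0, n_cells, length(times))
  for (s in stims) {
    sig <- sig + matrix(rep(amplitude * transient_kernel(times - s, tau_rise,
                                                         tau_decay),
                            each = n_cells), n_cells)
  }
  if (!is.null(bumps)) {
    for (b in seq_len(nrow(bumps))) {
      k <- transient_kernel((times - bumps$onset[b]) / bumps$width_s[b],
                            0.05, 0.33)
      sig[bumps$cell_index[b], ] <- sig[bumps$cell_index[b], ] +
        bumps$amplitude[b] * k
    }
  }
  fl <- f0 * (1 + sig)
  if (noise_sd > 0) {
    set.seed(seed)
    fl <- fl + matrix(stats::rnorm(length(fl), 0, noise_sd), n_cells)
  }
  ca_recording(fl, times, ca_protocol(stims, rate_hz,
                                      stop_time = stop_time))
}
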