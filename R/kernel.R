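#' Double-exponential transient kernel
#'
#' Unit-peak waveform used both for paced transients and for spontaneous
#' diastolic release (SCR) bumps:
#' \deqn{g(t) = (e^{-t/\tau_d} - e^{-t/\tau_r}) / g_{max}, \quad t \ge 0}
#' with rise constant \code{tau_rise_s} and decay constant
#' \code{tau_decay_s} (\code{tau_decay_s > tau_rise_s}). The peak value is 1.
#'
#' @param t numeric vector of times (s) relative to kernel onset.
#' @param tau_rise_s rise time constant (s).
#' @param tau_decay_s decay time constant (s).
#' @return numeric vector, same length as \code{t}; 0 for \code{t < 0}.
#' @export
transient_kernel <- function(t, tau_rise_s, tau_decay_s) {
  stopifnot(tau_rise_s > 0, tau_decay_s > tau_rise_s)
  tp <- kernel_peak_time(tau_rise_s, tau_decay_s)
  gmax <- exp(-tp / tau_decay_s) - exp(-tp / tau_rise_s)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay_s) - exp(-t[pos] / tau_rise_s)) / gmax
  out
}

#' Time of the kernel peak
#' @inheritParams transient_kernel
#' @return peak time (s) after onset.
#' @export
kernel_peak_time <- function(tau_rise_s, tau_decay_s) {
  tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
}

# Width (s) of the unit-peak kernel above relative level `level` (0 < level < 1).
# Used to time-rescale SCR bumps so their threshold-crossing duration matches a
# drawn value. Root-finding on each flank of the peak.
kernel_width_at_level <- function(level, tau_rise_s, tau_decay_s) {
  stopifnot(level > 0, level < 1)
  tp <- kernel_peak_time(tau_rise_s, tau_decay_s)
  g <- function(t) transient_kernel(t, tau_rise_s, tau_decay_s) - level
  t_lo <- stats::uniroot(g, c(0, tp), tol = 1e-10)$root
  # decay flank: bracket by extending until below level
  hi <- tp
  repeat {
    hi <- hi * 2 + tau_decay_s
    if (g(hi) < 0) break
  }
  t_hi <- stats::uniroot(g, c(tp, hi), tol = 1e-10)$root
  t_hi - t_lo
}

# Local-minimum event splitting. `x`: values of one supra-threshold candidate
# region. Returns sorted integer split positions (indices of interior minima at
# which the region is cut into sub-events), or integer(0). A minimum splits a
# segment iff the maxima on both sides exceed its value by at least `depth`;
# applied recursively at the deepest qualifying interior minimum so overlapping
# events separated by a sufficiently pronounced dip are counted separately.
split_points_at_minima <- function(x, depth) {
  n <- length(x)
  if (n < 5 || depth <= 0) return(integer(0))
  # interior local minima (middle of plateaus)
  d <- diff(x)
  cand <- integer(0)
  last_dir <- 0L
  plateau_start <- NA_integer_
  for (i in seq_along(d)) {
    dir <- sign(d[i])
    if (dir == 0) {
      if (is.na(plateau_start)) plateau_start <- i
      next
    }
    if (dir > 0 && last_dir < 0) {
      lo <- if (!is.na(plateau_start)) plateau_start else i
      cand <- c(cand, (lo + i) %/% 2L)
    }
    last_dir <- dir
    plateau_start <- NA_integer_
  }
  if (!length(cand)) return(integer(0))
  # accept minima deepest-first; each must be flanked, within its current
  # sub-segment, by maxima at least `depth` above it
  splits <- integer(0)
  for (m in cand[order(x[cand])]) {
    bounds <- sort(c(0L, splits, n + 1L))
    lo <- max(bounds[bounds < m]) + 1L
    hi <- min(bounds[bounds > m]) - 1L
    if (m - lo < 1 || hi - m < 1) next
    if (max(x[lo:(m - 1)]) >= x[m] + depth &&
        max(x[(m + 1):hi]) >= x[m] + depth) {
      splits <- c(splits, m)
    }
  }
  sort(splits)
}
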