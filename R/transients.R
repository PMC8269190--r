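#' Normalize a raw fluorescence trace to F/F0
#'
#' F0 is, by default, the minimum fluorescence value of the same cell over
#' the whole recording (the standard self-ratio for single-wavelength
#' calcium dyes); a lower percentile can be used instead for noisy traces.
#'
#' @param f numeric vector of raw fluorescence, finite.
#' @param f0_method \code{"min"} (default) or \code{"percentile:p"} with p
#'   in (0, 100], e.g. \code{"percentile:5"}.
#' @return list with \code{f_over_f0}, \code{f0}, \code{f0_method}.
#' @export
normalize_trace <- function(f, f0_method = "min") {
  if (!all(is.finite(f))) stop("trace contains non-finite values")
  if (identical(f0_method, "min")) {
    f0 <- min(f)
  } else if (grepl("^percentile:", f0_method)) {
    p <- as.numeric(sub("^percentile:", "", f0_method))
    if (!is.finite(p) || p <= 0 || p > 100) stop("bad percentile")
    f0 <- as.numeric(stats::quantile(f, p / 100, names = FALSE))
  } else {
    stop("f0_method must be 'min' or 'percentile:p'")
  }
  if (f0 <= 0) stop("non-physical baseline: F0 <= 0")
  list(f_over_f0 = f / f0, f0 = f0, f0_method = f0_method)
}

#' Normalize every cell of a recording
#'
#' @param rec a \code{\link{ca_recording}}.
#' @param f0_method see \code{\link{normalize_trace}}.
#' @param smooth_width optional odd width of a centered moving average
#'   applied to F/F0 before any detection (0 = no smoothing, the default).
#' @return object of class \code{ca_norm}: list with \code{fnorm} (matrix,
#'   cells x frames), \code{f0} (per-cell vector), \code{f0_method},
#'   \code{times}, \code{protocol}, \code{cells}, \code{meta}.
#' @export
normalize_recording <- function(rec, f0_method = "min", smooth_width = 0) {
  stopifnot(inherits(rec, "ca_recording"))
  fn <- rec$fluor
  f0 <- numeric(nrow(fn))
  for (i in seq_len(nrow(fn))) {
    nt <- normalize_trace(fn[i, ], f0_method)
    fn[i, ] <- nt$f_over_f0
    f0[i] <- nt$f0
  }
  if (smooth_width > 0) {
    if (smooth_width %% 2 == 0) stop("smooth_width must be odd")
    kern <- rep(1 / smooth_width, smooth_width)
    for (i in seq_len(nrow(fn))) {
      fn[i, ] <- stats::filter(fn[i, ], kern, sides = 2)
      # edges: keep original values where the filter is undefined
      na <- is.na(fn[i, ])
      fn[i, na] <- rec$fluor[i, na] / f0[i]
    }
  }
  structure(list(fnorm = fn, f0 = stats::setNames(f0, rec$cells),
                 f0_method = f0_method, smooth_width = smooth_width,
                 times = rec$times, protocol = rec$protocol,
                 cells = rec$cells, geometry = rec$geometry,
                 meta = rec$meta),
            class = "ca_norm")
}

#' Detect and quantify stimulus-locked calcium transients
#'
#' For every stimulus and cell: the peak is the maximum F/F0 in
#' \code{(stim, stim + search_window_s]} (truncated at the next stimulus),
#' the baseline is the mean F/F0 over \code{[stim - baseline_window_s,
#' stim)}, and the amplitude is their difference (dF/F0). Candidates with
#' amplitude at or below \code{amplitude_floor} are treated as failed beats
#' and dropped. The decay time constant of each accepted transient is then
#' fitted with \code{\link{fit_decay}}.
#'
#' @param norm a \code{\link{normalize_recording}} result.
#' @param search_window_s peak search window (s); default \code{0.8 /
#'   rate_hz} so it shrinks automatically at fast pacing.
#' @param baseline_window_s pre-stimulus baseline window (s), default 50 ms.
#' @param amplitude_floor minimum accepted amplitude (dF/F0), default 0.05.
#' @param fit logical: fit decay taus (default TRUE).
#' @return data.frame of class \code{ca_transients}: one row per accepted
#'   transient with columns \code{cell}, \code{stim_index},
#'   \code{stim_time}, \code{t_onset}, \code{t_peak}, \code{peak_f},
#'   \code{baseline}, \code{amplitude}, \code{tau}, \code{fit_flag},
#'   \code{fit_rss}.
#' @export
detect_paced_transients <- function(norm, search_window_s = NULL,
                                    baseline_window_s = 0.05,
                                    amplitude_floor = 0.05, fit = TRUE) {
  stopifnot(inherits(norm, "ca_norm"))
  proto <- norm$protocol
  stims <- proto$stimulus_times
  times <- norm$times
  dt <- stats::median(diff(times))
  if (is.null(search_window_s)) search_window_s <- 0.8 / proto$rate_hz
  stopifnot(search_window_s > 0, baseline_window_s > 0)
  out <- list()
  for (ci in seq_along(norm$cells)) {
    y <- norm$fnorm[ci, ]
    for (si in seq_along(stims)) {
      s <- stims[si]
      w_end <- s + search_window_s
      if (si < length(stims)) w_end <- min(w_end, stims[si + 1])
      w_ix <- which(times > s & times <= w_end + 1e-9)
      if (!length(w_ix)) next
      b_ix <- which(times >= s - baseline_window_s - 1e-9 & times < s)
      baseline <- if (length(b_ix)) mean(y[b_ix]) else y[max(1, w_ix[1] - 1)]
      pk <- w_ix[which.max(y[w_ix])]
      amp <- y[pk] - baseline
      if (amp <= amplitude_floor) next
      # onset: first sample after the stimulus exceeding 10% of the rise
      on_ix <- w_ix[which(y[w_ix] >= baseline + 0.1 * amp)[1]]
      out[[length(out) + 1]] <- data.frame(
        cell = norm$cells[ci], stim_index = si, stim_time = s,
        t_onset = times[on_ix], t_peak = times[pk], peak_f = y[pk],
        baseline = baseline, amplitude = amp, stringsAsFactors = FALSE)
    }
  }
  tr <- if (length(out)) do.call(rbind, out) else
    data.frame(cell = character(), stim_index = integer(),
               stim_time = numeric(), t_onset = numeric(),
               t_peak = numeric(), peak_f = numeric(), baseline = numeric(),
               amplitude = numeric(), stringsAsFactors = FALSE)
  tr$tau <- rep(NA_real_, nrow(tr))
  tr$fit_flag <- rep("unfit", nrow(tr))
  tr$fit_rss <- rep(NA_real_, nrow(tr))
  if (fit && nrow(tr)) {
    for (r in seq_len(nrow(tr))) {
      ci <- match(tr$cell[r], norm$cells)
      nx <- if (tr$stim_index[r] < length(stims))
        stims[tr$stim_index[r] + 1] else Inf
      ft <- fit_decay(norm$fnorm[ci, ], times, t_peak = tr$t_peak[r],
                      baseline = tr$baseline[r], amplitude = tr$amplitude[r],
                      t_max = nx)
      tr$tau[r] <- ft$tau
      tr$fit_flag[r] <- ft$flag
      tr$fit_rss[r] <- ft$rss
    }
  }
  class(tr) <- c("ca_transients", "data.frame")
  attr(tr, "search_window_s") <- search_window_s
  attr(tr, "baseline_window_s") <- baseline_window_s
  attr(tr, "amplitude_floor") <- amplitude_floor
  tr
}

#' Fit the monoexponential decay of one transient
#'
#' Fits \code{y(t) = baseline + A exp(-(t - t_peak)/tau)} — with the offset
#' fixed at the independently measured pre-stimulus baseline — over the window from the
#' peak to the earlier of the next stimulus and the first return to
#' baseline + 10% of the amplitude, by nonlinear least squares; falls back
#' to log-linear regression (flag \code{"loglin"}) when the nonlinear fit
#' fails to converge. A window of fewer than 5 samples or a non-decaying
#' segment yields flag \code{"nofit"}.
#'
#' @param y F/F0 trace of the cell.
#' @param times frame times (s).
#' @param t_peak peak time (s).
#' @param baseline pre-stimulus baseline (F/F0).
#' @param amplitude transient amplitude (dF/F0).
#' @param t_max hard end of the fit window (s), e.g. the next stimulus.
#' @return list \code{tau}, \code{flag} ("ok", "loglin" or "nofit"),
#'   \code{rss}, \code{window} (c(start, end)).
#' @export
fit_decay <- function(y, times, t_peak, baseline, amplitude, t_max = Inf) {
  i_pk <- which.min(abs(times - t_peak))
  ret_level <- baseline + 0.1 * amplitude
  # window end found on a lightly smoothed copy so that a single noise dip
  # does not truncate the fit window early
  ys <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  i_end <- length(times)
  post <- which(times > t_peak & (times >= t_max | ys <= ret_level))
  if (length(post)) i_end <- post[1]
  ix <- i_pk:i_end
  nofit <- list(tau = NA_real_, flag = "nofit", rss = NA_real_,
                window = c(times[i_pk], times[i_end]))
  if (length(ix) < 5) return(nofit)
  tt <- times[ix] - times[i_pk]
  yy <- y[ix]
  head_m <- mean(yy[seq_len(min(3, length(yy)))])
  tail_m <- mean(yy[seq(length(yy) - min(3, length(yy)) + 1, length(yy))])
  if (tail_m >= head_m) return(nofit)  # non-decaying segment
  # log-linear start values (and fallback)
  pos <- yy - baseline > 1e-6 * max(amplitude, 1e-9)
  tau0 <- NA_real_
  if (sum(pos) >= 3) {
    lf <- stats::lm(log(yy[pos] - baseline) ~ tt[pos])
    sl <- unname(stats::coef(lf)[2])
    if (is.finite(sl) && sl < 0) tau0 <- -1 / sl
  }
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(tt[length(tt)] / 3, 1e-3)
  # offset fixed at the independently measured pre-stimulus baseline
  # (2 free parameters): much stabler tau on short, noisy windows than
  # re-estimating the asymptote from the decay segment itself
  fit <- tryCatch(
    stats::nls(yy ~ baseline + a0 * exp(-tt / tau),
               start = list(a0 = yy[1] - baseline, tau = tau0),
               control = stats::nls.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tau <- stats::coef(fit)[["tau"]]
    if (tau > 0) {
      return(list(tau = tau, flag = "ok",
                  rss = sum(stats::residuals(fit)^2),
                  window = c(times[i_pk], times[i_end])))
    }
  }
  if (is.finite(tau0) && sum(pos) >= 3) {
    pred <- baseline + (yy[1] - baseline) * exp(-tt / tau0)
    return(list(tau = tau0, flag = "loglin", rss = sum((yy - pred)^2),
                window = c(times[i_pk], times[i_end])))
  }
  nofit
}
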