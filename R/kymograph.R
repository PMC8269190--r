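#' Construct a kymograph object
#'
#' @param mat numeric matrix, positions (rows) x lines (columns), raw
#'   fluorescence.
#' @param pixel_um pixel size along the scanned line (micrometers).
#' @param line_interval_s time between lines (s).
#' @param meta free-form list.
#' @return object of class \code{ca_kymograph}.
#' @export
ca_kymograph <- function(mat, pixel_um, line_interval_s, meta = list()) {
  mat <- as.matrix(mat)
  stopifnot(pixel_um > 0, line_interval_s > 0,
            nrow(mat) >= 8, ncol(mat) >= 3)
  structure(list(mat = mat, pixel_um = pixel_um,
                 line_interval_s = line_interval_s, meta = meta),
            class = "ca_kymograph")
}

#' Detect the traveling wavefront in a kymograph
#'
#' Per scanned line, the front position is the level crossing of
#' \code{basal + level * (max - basal)} (half-maximum by default) on the
#' invasion boundary, with linear sub-pixel interpolation. Lines before
#' wave initiation or after full invasion (no crossing) are excluded. When
#' noise produces several crossings on one line, the crossing closest to
#' the previous line's front is kept (the first usable line takes the
#' median crossing).
#'
#' @param kymo a \code{\link{ca_kymograph}}.
#' @param level relative threshold level in (0, 1), default 0.5.
#' @param smooth_px optional odd moving-average width applied to each line
#'   before crossing detection (0 = none).
#' @return data.frame \code{time_s}, \code{position_um} of front points.
#' @export
detect_wavefront <- function(kymo, level = 0.5, smooth_px = 0) {
  stopifnot(inherits(kymo, "ca_kymograph"), level > 0, level < 1)
  m <- kymo$mat
  # basal statistics from the dimmest quartile of pixels
  q <- stats::quantile(m, 0.25, names = FALSE)
  basal <- mean(m[m <= q])
  basal_sd <- stats::sd(m[m <= q])
  top <- max(m)
  if (!is.finite(basal_sd) || top - basal <= 4 * basal_sd) {
    stop("no front: kymograph has no wave (max - basal <= 4 basal SD)")
  }
  thr <- basal + level * (top - basal)
  x <- (seq_len(nrow(m)) - 0.5) * kymo$pixel_um
  if (smooth_px > 0) {
    if (smooth_px %% 2 == 0) stop("smooth_px must be odd")
    kern <- rep(1 / smooth_px, smooth_px)
  }
  t_out <- numeric(0); p_out <- numeric(0)
  prev <- NA_real_
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (smooth_px > 0) {
      vs <- stats::filter(v, kern, sides = 2)
      v[!is.na(vs)] <- vs[!is.na(vs)]
    }
    s <- v - thr
    cross <- which(s[-length(s)] * s[-1] < 0)
    if (!length(cross)) {
      # a line exactly at threshold on a pixel: rare; treat as no crossing
      next
    }
    xc <- x[cross] + (0 - s[cross]) / (s[cross + 1] - s[cross]) *
      (x[cross + 1] - x[cross])
    pos <- if (is.na(prev)) stats::median(xc) else xc[which.min(abs(xc - prev))]
    prev <- pos
    t_out <- c(t_out, (j - 1) * kymo$line_interval_s)
    p_out <- c(p_out, pos)
  }
  if (length(t_out) < 3) stop("no front: fewer than 3 lines with a crossing")
  data.frame(time_s = t_out, position_um = p_out)
}

#' Estimate wave speed from front positions
#'
#' Ordinary least squares of front position (micrometers) on time (s);
#' speed is the absolute slope, with the propagation direction recorded as
#' its sign.
#'
#' @param front data.frame \code{time_s}, \code{position_um}
#'   (\code{\link{detect_wavefront}} output).
#' @return object of class \code{ca_wavefit}: list \code{speed_um_s},
#'   \code{direction} (+1/-1), \code{intercept}, \code{r_squared},
#'   \code{n_points}, \code{front}, \code{method}.
#' @export
wave_speed <- function(front) {
  if (nrow(front) < 3) stop("need at least 3 front points")
  if (diff(range(front$time_s)) <= 0) stop("zero time spread")
  fit <- stats::lm(position_um ~ time_s, data = front)
  sl <- unname(stats::coef(fit)[2])
  # noiseless fronts are exactly collinear; summary.lm warns about it
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(speed_um_s = abs(sl), direction = sign(sl),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = nrow(front), front = front,
                 method = "halfmax-ols"),
            class = "ca_wavefit")
}

#' Cross-correlation wave-speed estimator
#'
#' Alternative estimator for low-SNR kymographs: the lag (in lines)
#' maximizing the cross-correlation between the time courses of pixel pairs
#' a fixed distance apart gives distance / (lag * line interval); the
#' median over pairs is reported.
#'
#' @param kymo a \code{\link{ca_kymograph}}.
#' @param sep_px pixel separation of correlated pairs (default a quarter of
#'   the scan length).
#' @return a \code{ca_wavefit} (with \code{r_squared = NA} and
#'   \code{method = "xcorr"}).
#' @export
wave_speed_xcorr <- function(kymo, sep_px = NULL) {
  m <- kymo$mat
  n <- nrow(m)
  if (is.null(sep_px)) sep_px <- max(2L, n %/% 4)
  lags <- numeric(0)
  for (i in seq_len(n - sep_px)) {
    # correlate the upstroke (first difference) time courses: a localized
    # pulse gives a crisp correlation peak at the propagation lag
    cc <- stats::ccf(diff(m[i, ]), diff(m[i + sep_px, ]),
                     lag.max = ncol(m) - 3, plot = FALSE)
    lg <- cc$lag[which.max(cc$acf)]
    if (lg != 0) lags <- c(lags, abs(lg))
  }
  if (!length(lags)) stop("no usable lag between pixel pairs")
  speed <- sep_px * kymo$pixel_um / (stats::median(lags) * kymo$line_interval_s)
  structure(list(speed_um_s = speed, direction = NA_real_,
                 intercept = NA_real_, r_squared = NA_real_,
                 n_points = length(lags), front = NULL, method = "xcorr"),
            class = "ca_wavefit")
}
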