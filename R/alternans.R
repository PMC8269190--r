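#' Classify beat-to-beat calcium alternans for one cell
#'
#' Alternans is called when two consecutive transient amplitudes differ by
#' at least \code{diff_frac} (relative difference, inclusive boundary) and
#' this alternating behavior is maintained for at least \code{min_run}
#' transients. Formally: with amplitudes \eqn{A_i} in stimulus order, the
#' pair difference is \eqn{d_i = |A_i - A_{i+1}| / denom_i}; a qualifying
#' run is a maximal stretch of consecutive transients in which every
#' adjacent pair has \eqn{d_i \ge} \code{diff_frac} and the sign of
#' \eqn{A_{i+1} - A_i} strictly alternates (ABAB); the call is positive iff
#' the longest run spans at least \code{min_run} transients (10 transients
#' = 9 qualifying pairs).
#'
#' @param transients_of_cell rows of a \code{\link{detect_paced_transients}}
#'   result for one cell (any order; sorted internally by stimulus index).
#' @param diff_frac relative-difference threshold, default 0.10.
#' @param min_run minimum run length in transients, default 10.
#' @param denom denominator of the relative difference: \code{"max"}
#'   (default: symmetric and conservative), \code{"min"} or \code{"mean"}.
#' @return one-row data.frame of class \code{ca_alternans_call}:
#'   \code{cell}, \code{positive}, \code{run_len}, \code{A_large},
#'   \code{A_small}, \code{tau_large}, \code{tau_small}, \code{phase}
#'   ("even"/"odd": parity of the large beats' stimulus indices), and
#'   \code{flag} ("ok" or "insufficient beats").
#' @export
classify_alternans <- function(transients_of_cell, diff_frac = 0.10,
                               min_run = 10, denom = c("max", "min", "mean")) {
  denom <- match.arg(denom)
  tr <- transients_of_cell[order(transients_of_cell$stim_index), ,
                           drop = FALSE]
  cell <- if (nrow(tr)) tr$cell[1] else NA_character_
  empty <- data.frame(cell = cell, positive = FALSE, run_len = 0L,
                      A_large = NA_real_, A_small = NA_real_,
                      tau_large = NA_real_, tau_small = NA_real_,
                      phase = NA_character_, flag = "insufficient beats",
                      stringsAsFactors = FALSE)
  class(empty) <- c("ca_alternans_call", "data.frame")
  n <- nrow(tr)
  if (n < min_run) return(empty)
  A <- tr$amplitude
  dd <- abs(diff(A)) / switch(denom,
    max = pmax(A[-n], A[-1]),
    min = pmin(A[-n], A[-1]),
    mean = (A[-n] + A[-1]) / 2)
  sg <- sign(diff(A))
  # the "at least" boundary is inclusive; the 1e-12 guard keeps pairs like
  # (1.0, 0.9) qualifying despite binary floating point
  qual <- dd >= diff_frac - 1e-12 & sg != 0
  # consecutive stimulus indices only: a missed beat breaks the run
  contig <- diff(tr$stim_index) == 1
  # runs of pairs: pair i joins pair i-1 when both qualify, are contiguous,
  # and the sign alternates
  best_len <- 0L; best_start <- NA_integer_
  cur_len <- 0L; cur_start <- NA_integer_
  for (i in seq_along(qual)) {
    if (qual[i] && contig[i]) {
      if (cur_len > 0 && sg[i] == -sg[i - 1]) {
        cur_len <- cur_len + 1L
      } else {
        cur_len <- 1L
        cur_start <- i
      }
    } else {
      cur_len <- 0L
    }
    if (cur_len > best_len) { best_len <- cur_len; best_start <- cur_start }
  }
  run_len <- if (best_len > 0) best_len + 1L else 0L  # pairs -> transients
  positive <- run_len >= min_run
  out <- empty
  out$flag <- "ok"
  out$run_len <- run_len
  out$positive <- positive
  if (run_len >= 2) {
    run_ix <- best_start:(best_start + best_len)   # transient rows
    sub <- tr[run_ix, , drop = FALSE]
    # phase split at the amplitude midrange: within a qualifying run the two
    # phases form well-separated clusters, so the midrange always falls in
    # the gap between them
    is_large <- sub$amplitude >=
      (max(sub$amplitude) + min(sub$amplitude)) / 2
    if (all(is_large) || !any(is_large)) {
      is_large <- seq_len(nrow(sub)) %% 2 == 1
    }
    out$A_large <- mean(sub$amplitude[is_large])
    out$A_small <- mean(sub$amplitude[!is_large])
    out$tau_large <- mean(sub$tau[is_large], na.rm = TRUE)
    out$tau_small <- mean(sub$tau[!is_large], na.rm = TRUE)
    par_large <- sub$stim_index[is_large] %% 2
    out$phase <- if (stats::median(par_large) == 0) "even" else "odd"
  }
  out
}

#' Classify alternans for every cell of a recording
#'
#' @param transients a \code{\link{detect_paced_transients}} result.
#' @param cells optional character vector of cells to report (defaults to
#'   the cells present in \code{transients}).
#' @inheritParams classify_alternans
#' @return data.frame: one \code{\link{classify_alternans}} row per cell.
#' @export
classify_alternans_all <- function(transients, cells = NULL,
                                   diff_frac = 0.10, min_run = 10,
                                   denom = "max") {
  if (is.null(cells)) cells <- unique(transients$cell)
  rows <- lapply(cells, function(cl) {
    call <- classify_alternans(
      transients[transients$cell == cl, , drop = FALSE],
      diff_frac = diff_frac, min_run = min_run, denom = denom)
    call$cell <- cl
    call
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of alternans-positive cells
#'
#' @param calls a \code{\link{classify_alternans_all}} result.
#' @return list \code{n_positive}, \code{n_total}, \code{percentage}
#'   (unrounded, 0-100).
#' @export
alternans_fraction <- function(calls) {
  if (!nrow(calls)) stop("no alternans calls")
  n_pos <- sum(calls$positive)
  n_tot <- nrow(calls)
  list(n_positive = n_pos, n_total = n_tot,
       percentage = 100 * n_pos / n_tot)
}

#' Paired comparison of decay kinetics: large vs small alternans beats
#'
#' For every alternans-positive cell with valid decay-tau estimates on both
#' phases, reports tau(large) - tau(small), plus a paired summary (mean
#' difference, 95% CI and p from a paired t test when at least two cells
#' are available).
#'
#' @param calls a \code{\link{classify_alternans_all}} result.
#' @return list with \code{per_cell} (data.frame \code{cell},
#'   \code{tau_large}, \code{tau_small}, \code{diff}), \code{mean_diff},
#'   \code{ci}, \code{p_value} (NA with flag \code{"single cell"} when only
#'   one positive cell), \code{direction} (+1 when large beats decay more
#'   slowly), \code{flag}.
#' @export
compare_decay_large_small <- function(calls) {
  pos <- calls[calls$positive & is.finite(calls$tau_large) &
                 is.finite(calls$tau_small), , drop = FALSE]
  per_cell <- data.frame(cell = pos$cell, tau_large = pos$tau_large,
                         tau_small = pos$tau_small,
                         diff = pos$tau_large - pos$tau_small,
                         stringsAsFactors = FALSE)
  if (!nrow(per_cell)) {
    return(list(per_cell = per_cell, mean_diff = NA_real_,
                ci = c(NA_real_, NA_real_), p_value = NA_real_,
                direction = NA_real_, flag = "no positive cells"))
  }
  if (nrow(per_cell) == 1) {
    return(list(per_cell = per_cell, mean_diff = per_cell$diff,
                ci = c(NA_real_, NA_real_), p_value = NA_real_,
                direction = sign(per_cell$diff), flag = "single cell"))
  }
  tt <- stats::t.test(per_cell$diff)
  list(per_cell = per_cell, mean_diff = mean(per_cell$diff),
       ci = as.numeric(tt$conf.int), p_value = tt$p.value,
       direction = sign(mean(per_cell$diff)), flag = "ok")
}
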