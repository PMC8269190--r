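#' Pacing protocol
#'
#' Describes the field-stimulation protocol applied to a slice: the times of
#' the voltage pulses, the nominal pacing rate, and, for pace-stop
#' experiments, the time at which pacing was paused.
#'
#' @param stimulus_times numeric, stimulus onset times (s), sorted.
#' @param rate_hz nominal pacing rate (Hz), > 0. Typical slice experiments
#'   pace at 1-5 Hz.
#' @param stop_time time (s) at which pacing was paused, or \code{NULL} for
#'   continuously paced recordings. All stimuli must precede it.
#' @param pulse_width stimulus pulse width (s); metadata only (field pulses
#'   are ~5 ms square waves).
#' @return an object of class \code{ca_protocol}.
#' @export
ca_protocol <- function(stimulus_times, rate_hz, stop_time = NULL,
                        pulse_width = 0.005) {
  stimulus_times <- as.numeric(stimulus_times)
  if (is.unsorted(stimulus_times, strictly = TRUE)) {
    stop("stimulus_times must be strictly increasing")
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  if (!is.null(stop_time)) {
    stop_time <- as.numeric(stop_time)
    if (length(stimulus_times) && any(stimulus_times >= stop_time)) {
      stop("all stimulus_times must precede stop_time")
    }
  }
  structure(list(stimulus_times = stimulus_times, rate_hz = rate_hz,
                 stop_time = stop_time, pulse_width = pulse_width),
            class = "ca_protocol")
}

#' Cell geometry table
#'
#' Per-cell centroid positions and (optionally) grid coordinates used to
#' derive which cells are neighbors.
#'
#' @param cell character vector of cell ids.
#' @param x_um,y_um centroid coordinates (micrometers).
#' @param row,col optional integer grid coordinates (for synthetic grids).
#' @param diameter_um optional characteristic cell diameter (micrometers).
#' @return a \code{data.frame} of class \code{ca_geometry}.
#' @export
ca_geometry <- function(cell, x_um, y_um, row = NA_integer_,
                        col = NA_integer_, diameter_um = NA_real_) {
  cell <- as.character(cell)
  if (anyDuplicated(cell)) stop("duplicate cell ids in geometry")
  if (!all(is.finite(x_um)) || !all(is.finite(y_um))) {
    stop("geometry centroids must be finite")
  }
  g <- data.frame(cell = cell, x_um = as.numeric(x_um),
                  y_um = as.numeric(y_um),
                  row = as.integer(row), col = as.integer(col),
                  diameter_um = as.numeric(diameter_um),
                  stringsAsFactors = FALSE)
  class(g) <- c("ca_geometry", "data.frame")
  g
}

#' Multicellular calcium recording
#'
#' The central container: one raw fluorescence trace per cell on a uniform
#' time grid, the pacing protocol, and (optionally) cell geometry. Raw
#' fluorescence is in arbitrary detector units; normalization to F/F0 is a
#' separate, explicit step (\code{\link{normalize_recording}}).
#'
#' @param fluor numeric matrix, \code{n_cells x n_frames}, raw fluorescence,
#'   non-negative. Row names, if present, are used as cell ids.
#' @param times numeric vector of frame times (s), strictly increasing and
#'   uniformly spaced (tolerance 1e-6 s).
#' @param protocol a \code{\link{ca_protocol}}.
#' @param geometry optional \code{\link{ca_geometry}} whose cell ids match.
#' @param cells optional character vector of cell ids (defaults to row names
#'   or \code{"cell_1"}, ...).
#' @param meta free-form named list (genotype, treatment, ...).
#' @param allow_na allow explicit NA frames (off by default: every
#'   downstream detector assumes gap-free traces).
#' @return an object of class \code{ca_recording}.
#' @export
ca_recording <- function(fluor, times, protocol, geometry = NULL,
                         cells = NULL, meta = list(), allow_na = FALSE) {
  fluor <- as.matrix(fluor)
  times <- as.numeric(times)
  if (ncol(fluor) != length(times)) {
    stop("fluor must have one column per frame (", length(times), ")")
  }
  check_uniform_grid(times)
  if (!allow_na && anyNA(fluor)) {
    stop("fluor contains NA frames; use allow_na = TRUE to flag them explicitly")
  }
  if (any(fluor < 0, na.rm = TRUE)) stop("raw fluorescence must be >= 0")
  if (is.null(cells)) {
    cells <- rownames(fluor)
    if (is.null(cells)) cells <- paste0("cell_", seq_len(nrow(fluor)))
  }
  cells <- as.character(cells)
  if (length(cells) != nrow(fluor)) stop("cells must match nrow(fluor)")
  rownames(fluor) <- cells
  if (!inherits(protocol, "ca_protocol")) stop("protocol must be a ca_protocol")
  if (length(protocol$stimulus_times)) {
    st <- protocol$stimulus_times
    if (min(st) < times[1] - 1e-9 || max(st) > times[length(times)] + 1e-9) {
      stop("stimulus times fall outside the recording window")
    }
  }
  if (!is.null(geometry)) {
    if (!setequal(geometry$cell, cells)) {
      stop("geometry cell ids must match recording cells exactly")
    }
  }
  structure(list(cells = cells, times = times, fluor = fluor,
                 protocol = protocol, geometry = geometry, meta = meta),
            class = "ca_recording")
}

# error names the first offending interval, per the strict-grid contract
check_uniform_grid <- function(times, tol = 1e-6) {
  if (length(times) < 2) stop("need at least 2 frames")
  dt <- diff(times)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1]
    stop("times not strictly increasing at interval ", i)
  }
  ref <- stats::median(dt)
  bad <- which(abs(dt - ref) > tol)
  if (length(bad)) {
    stop(sprintf(
      "non-uniform time grid: interval %d (%.6f..%.6f s) has width %.6g, expected %.6g",
      bad[1], times[bad[1]], times[bad[1] + 1], dt[bad[1]], ref))
  }
  invisible(ref)
}

#' @export
print.ca_recording <- function(x, ...) {
  cat("ca_recording:", length(x$cells), "cells x", length(x$times), "frames\n")
  cat("  duration", sprintf("%.3f", diff(range(x$times))), "s, frame interval",
      sprintf("%.4f", frame_interval(x)), "s\n")
  cat("  pacing", x$protocol$rate_hz, "Hz,", length(x$protocol$stimulus_times),
      "stimuli", if (!is.null(x$protocol$stop_time))
        sprintf("(stop at %.2f s)", x$protocol$stop_time) else "", "\n")
  invisible(x)
}

#' Frame interval of a recording
#' @param rec a \code{ca_recording}.
#' @return frame interval (s).
#' @export
frame_interval <- function(rec) {
  stats::median(diff(rec$times))
}

#' Cell adjacency from geometry
#'
#' Builds the undirected neighbor graph used by the coupling analysis. Two
#' rules are supported: \code{"grid-rook"} links 4-neighbors of integer grid
#' coordinates (the natural choice for synthetic grids), and
#' \code{"centroid-distance"} links every pair of cells whose centroid
#' distance is at most \code{threshold_um} (for real ROIs the field has no
#' standard definition of "neighboring"; a threshold of 1.5x the median cell
#' diameter is a reasonable default). The rule used is recorded in the result
#' so it can be reported alongside any coupling statistic.
#'
#' @param geometry a \code{\link{ca_geometry}}.
#' @param rule \code{"grid-rook"} or \code{"centroid-distance"}.
#' @param threshold_um distance threshold (micrometers); required for
#'   \code{"centroid-distance"}.
#' @return an object of class \code{ca_adjacency}: list with \code{edges}
#'   (data.frame \code{from}, \code{to}, cell ids, from < to), \code{cells},
#'   and \code{rule} tag.
#' @export
adjacency_from_geometry <- function(geometry,
                                    rule = c("grid-rook", "centroid-distance"),
                                    threshold_um = NULL) {
  rule <- match.arg(rule)
  cells <- geometry$cell
  n <- length(cells)
  if (rule == "grid-rook") {
    if (anyNA(geometry$row) || anyNA(geometry$col)) {
      stop("grid-rook rule requires row/col grid coordinates for every cell")
    }
    key <- paste(geometry$row, geometry$col)
    idx <- seq_len(n)
    names(idx) <- key
    from <- integer(0); to <- integer(0)
    for (i in seq_len(n)) {
      for (d in list(c(0, 1), c(1, 0))) {
        k <- paste(geometry$row[i] + d[1], geometry$col[i] + d[2])
        j <- idx[k]
        if (!is.na(j)) { from <- c(from, i); to <- c(to, j) }
      }
    }
    tag <- "grid-rook"
  } else {
    if (is.null(threshold_um)) {
      stop("threshold_um is required for centroid-distance adjacency")
    }
    d <- as.matrix(stats::dist(cbind(geometry$x_um, geometry$y_um)))
    hit <- which(d <= threshold_um & upper.tri(d), arr.ind = TRUE)
    from <- hit[, 1]; to <- hit[, 2]
    tag <- sprintf("centroid-distance:%g", threshold_um)
  }
  a <- pmin(from, to); b <- pmax(from, to)
  ord <- order(a, b)
  edges <- data.frame(from = cells[a][ord], to = cells[b][ord],
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  structure(list(edges = edges, cells = cells, rule = tag),
            class = "ca_adjacency")
}

#' Neighbor list from an adjacency graph
#' @param adjacency a \code{ca_adjacency}.
#' @return named list: for each cell, the character vector of its neighbors.
#' @export
neighbor_list <- function(adjacency) {
  nb <- stats::setNames(vector("list", length(adjacency$cells)),
                        adjacency$cells)
  for (i in seq_len(nrow(adjacency$edges))) {
    f <- adjacency$edges$from[i]; t <- adjacency$edges$to[i]
    nb[[f]] <- c(nb[[f]], t)
    nb[[t]] <- c(nb[[t]], f)
  }
  nb
}

#' Degree of each cell
#' @param adjacency a \code{ca_adjacency}.
#' @return named integer vector of degrees.
#' @export
adjacency_degree <- function(adjacency) {
  deg <- stats::setNames(integer(length(adjacency$cells)), adjacency$cells)
  tab <- table(c(adjacency$edges$from, adjacency$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}
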