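#' Load a recording from tabular traces plus a protocol file
#'
#' Accepts wide (\code{time, cell_1, ..., cell_n}) or long
#' (\code{cell, time, F}) CSV/TSV trace tables; the dialect is sniffed from
#' the header unless declared. Times must form a strictly increasing,
#' uniform grid (tolerance 1e-6 s) — jittered timestamps are a hard error
#' naming the first offending interval. The pacing protocol is read from a
#' JSON sidecar (\code{stimulus_times}, \code{rate_hz}, optional
#' \code{stop_time}, \code{pulse_width}).
#'
#' @param path trace table path (.csv or .tsv; separator sniffed from the
#'   extension and first line).
#' @param protocol_path protocol JSON path; default
#'   \code{<path>_protocol.json} next to the traces. A missing protocol is
#'   an error (use \code{\link{infer_protocol}} to reconstruct stimulus
#'   times from the traces themselves).
#' @param format_hint \code{"auto"}, \code{"wide"} or \code{"long"}.
#' @param geometry_path optional geometry CSV
#'   (\code{cell,x_um,y_um,row,col,diameter_um}).
#' @param meta free-form list attached to the recording.
#' @return a \code{\link{ca_recording}}.
#' @export
load_recording <- function(path, protocol_path = NULL,
                           format_hint = c("auto", "wide", "long"),
                           geometry_path = NULL, meta = list()) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cn <- tolower(names(tab))
  fmt <- format_hint
  if (fmt == "auto") {
    fmt <- if (all(c("cell", "time") %in% cn) && ncol(tab) == 3) "long"
           else "wide"
  }
  if (fmt == "long") {
    names(tab) <- cn
    fcol <- setdiff(names(tab), c("cell", "time"))[1]
    key <- paste(tab$cell, format(tab$time, digits = 12))
    if (anyDuplicated(key)) {
      stop("duplicate (cell, time) rows in long table")
    }
    cells <- unique(tab$cell)
    times <- sort(unique(tab$time))
    fl <- matrix(NA_real_, length(cells), length(times),
                 dimnames = list(cells, NULL))
    fl[cbind(match(tab$cell, cells), match(tab$time, times))] <- tab[[fcol]]
    if (anyNA(fl)) stop("long table is not a complete cell x time grid")
  } else {
    if (!"time" %in% cn) stop("wide table must have a 'time' column")
    t_ix <- which(cn == "time")[1]
    times <- tab[[t_ix]]
    fl <- t(as.matrix(tab[, -t_ix, drop = FALSE]))
  }
  check_uniform_grid(times)
  if (is.null(protocol_path)) {
    protocol_path <- sub("\\.(csv|tsv)$", "_protocol.json", path)
  }
  if (!file.exists(protocol_path)) {
    stop("missing protocol file '", protocol_path,
         "'; supply protocol_path or reconstruct stimuli with infer_protocol()")
  }
  pj <- jsonlite::read_json(protocol_path, simplifyVector = TRUE)
  proto <- ca_protocol(pj$stimulus_times, pj$rate_hz,
                       stop_time = pj$stop_time,
                       pulse_width = if (!is.null(pj$pulse_width))
                         pj$pulse_width else 0.005)
  geom <- NULL
  if (!is.null(geometry_path)) {
    g <- utils::read.csv(geometry_path, stringsAsFactors = FALSE)
    geom <- ca_geometry(g$cell, g$x_um, g$y_um, row = g$row, col = g$col,
                        diameter_um = g$diameter_um)
  }
  ca_recording(fl, times, proto, geometry = geom, meta = meta)
}

#' Write a recording to disk (wide CSV + protocol JSON [+ geometry CSV])
#'
#' Wide format is canonical on output. Returns the trace path invisibly.
#'
#' @param rec a \code{\link{ca_recording}}.
#' @param path output CSV path for the traces.
#' @export
write_recording <- function(rec, path) {
  wide <- data.frame(time = rec$times, t(rec$fluor), check.names = FALSE)
  names(wide) <- c("time", rec$cells)
  utils::write.csv(wide, path, row.names = FALSE)
  pj <- list(stimulus_times = rec$protocol$stimulus_times,
             rate_hz = rec$protocol$rate_hz,
             stop_time = rec$protocol$stop_time,
             pulse_width = rec$protocol$pulse_width)
  jsonlite::write_json(pj, sub("\\.(csv|tsv)$", "_protocol.json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(rec$geometry)) {
    utils::write.csv(as.data.frame(rec$geometry),
                     sub("\\.(csv|tsv)$", "_geometry.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Reconstruct stimulus times from the population-mean trace
#'
#' Fallback for recordings delivered without a protocol sidecar: stimulus
#' onsets are detected as upstrokes of the cell-averaged trace (derivative
#' above half its maximum, debounced by half the expected cycle length).
#'
#' @param fluor cells x frames raw fluorescence matrix.
#' @param times frame times (s).
#' @param rate_hz nominal pacing rate, used for debouncing and recorded in
#'   the protocol.
#' @param stop_time optional pace-stop time.
#' @return a \code{\link{ca_protocol}}.
#' @export
infer_protocol <- function(fluor, times, rate_hz, stop_time = NULL) {
  avg <- colMeans(fluor)
  dv <- c(0, diff(avg))
  thr <- max(dv) / 2
  cand <- which(dv > thr)
  if (!length(cand)) stop("no upstrokes found")
  min_gap <- 0.5 / rate_hz
  keep <- cand[c(TRUE, diff(times[cand]) > min_gap)]
  st <- times[keep] - stats::median(diff(times))
  if (!is.null(stop_time)) st <- st[st < stop_time]
  ca_protocol(st, rate_hz, stop_time = stop_time)
}

#' Extract per-ROI traces from an image stack
#'
#' Produces the mean pixel value of every labeled ROI per frame. The stack
#' is a T x H x W array (e.g. read from a multi-page TIFF by any image
#' reader); the label map is an H x W integer matrix with 0 = background.
#' Cells are ordered by ascending label.
#'
#' @param stack numeric array, frames x height x width.
#' @param roi_labels integer matrix, height x width.
#' @param frame_interval_s frame interval (s).
#' @param protocol a \code{\link{ca_protocol}}.
#' @param meta free-form list.
#' @return a \code{\link{ca_recording}} with cells \code{"roi_<label>"}.
#' @export
extract_traces <- function(stack, roi_labels, frame_interval_s, protocol,
                           meta = list()) {
  d <- dim(stack)
  if (length(d) != 3) stop("stack must be a T x H x W array")
  if (!all(dim(roi_labels) == d[2:3])) {
    stop("label map shape ", paste(dim(roi_labels), collapse = "x"),
         " does not match stack frames ", d[2], "x", d[3])
  }
  labs <- sort(unique(as.integer(roi_labels[roi_labels > 0])))
  if (!length(labs)) stop("label map contains no ROI (all background)")
  fl <- matrix(NA_real_, length(labs), d[1])
  for (k in seq_along(labs)) {
    mask <- roi_labels == labs[k]
    if (!any(mask)) stop("empty ROI label ", labs[k])
    fl[k, ] <- apply(stack, 1, function(fr) mean(fr[mask]))
  }
  rownames(fl) <- paste0("roi_", labs)
  times <- (seq_len(d[1]) - 1) * frame_interval_s
  ca_recording(fl, times, protocol, meta = meta)
}

#' Read/write a kymograph as CSV matrix + JSON metadata
#'
#' @param kymo a \code{\link{ca_kymograph}}.
#' @param path CSV path (positions as rows); metadata goes to
#'   \code{<path>_meta.json}.
#' @export
write_kymograph <- function(kymo, path) {
  utils::write.table(kymo$mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(pixel_um = kymo$pixel_um,
                            line_interval_s = kymo$line_interval_s),
                       sub("\\.csv$", "_meta.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(sub("\\.csv$", "_meta.json", path),
                              simplifyVector = TRUE)
  ca_kymograph(m, meta$pixel_um, meta$line_interval_s)
}

#' Write an analysis result bundle to a directory
#'
#' Writes the typed outputs of \code{\link{run_pipeline}} as CSV tables
#' plus a JSON manifest carrying the configuration, its MD5 hash, the seed
#' and the package version. Reloading with \code{\link{read_results}}
#' reproduces integer/string fields exactly and floats to better than
#' 1e-12 (full-precision decimal round-trip).
#'
#' @param bundle a \code{\link{run_pipeline}} result.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("cannot write to directory ", out_dir)
  }
  w <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    p
  }
  written <- character(0)
  if (!is.null(bundle$transients)) {
    written["transients"] <- w(bundle$transients, "transients")
  }
  if (!is.null(bundle$scr)) {
    written["scr_events"] <- w(bundle$scr$events, "scr_events")
    written["scr_exposure"] <- w(bundle$scr$exposure, "scr_exposure")
  }
  if (!is.null(bundle$scr_summary)) {
    written["scr_summary"] <- w(bundle$scr_summary$per_cell, "scr_summary")
  }
  if (!is.null(bundle$alternans)) {
    written["alternans_calls"] <- w(bundle$alternans, "alternans_calls")
  }
  if (!is.null(bundle$pace_stop)) {
    written["pace_stop"] <- w(bundle$pace_stop, "pace_stop")
  }
  if (!is.null(bundle$coupling)) {
    written["coupling_records"] <- w(bundle$coupling$latencies$records,
                                     "coupling_records")
    cj <- bundle$coupling
    cj$latencies <- NULL
    jsonlite::write_json(unclass(cj), file.path(out_dir, "coupling.json"),
                         auto_unbox = TRUE, digits = NA)
    written["coupling"] <- file.path(out_dir, "coupling.json")
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(bundle$config, cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    package = "caslice",
    version = as.character(utils::packageVersion("caslice")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = bundle$config$seed,
    outputs = as.list(vapply(written, basename, character(1))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_results
#' @param dir directory previously written by \code{write_results}.
#' @export
read_results <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  rd <- function(name) {
    p <- file.path(dir, paste0(name, ".csv"))
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE)
    else NULL
  }
  list(manifest = manifest,
       config = jsonlite::read_json(file.path(dir, "config.json"),
                                    simplifyVector = TRUE),
       transients = rd("transients"), scr_events = rd("scr_events"),
       scr_exposure = rd("scr_exposure"), scr_summary = rd("scr_summary"),
       alternans = rd("alternans_calls"), pace_stop = rd("pace_stop"),
       coupling = if (file.exists(file.path(dir, "coupling.json")))
         jsonlite::read_json(file.path(dir, "coupling.json"),
                             simplifyVector = TRUE) else NULL,
       coupling_records = rd("coupling_records"))
}
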