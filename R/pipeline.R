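#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline. The defaults are the
#' published constants of the analysis this package implements: SCR events
#' must reach at least 10% of the triggered transient amplitude
#' (\code{threshold_frac}), alternans requires consecutive amplitudes
#' differing by at least 10% (\code{diff_frac}) sustained for at least 10
#' transients (\code{min_run}), and events/durations are bounded by
#' crossings of basal mean + 2 SD (\code{sd_mult}). The remaining knobs are
#' implementation defaults (see \code{\link{show_config}}).
#'
#' @param threshold_frac SCR amplitude threshold as a fraction of the mean
#'   triggered-transient amplitude (0.10).
#' @param diff_frac alternans relative amplitude difference (0.10).
#' @param min_run alternans minimum run length in transients (10).
#' @param sd_mult basal-SD multiplier for event bounds (2).
#' @param merge_gap_s sub-threshold gap merged into one event (0.05 s).
#' @param smooth_width odd moving-average width applied to F/F0 before all
#'   detectors (0 = none).
#' @param search_window_s transient peak search window; NULL = 0.8/rate.
#' @param baseline_window_s pre-stimulus baseline window (0.05 s).
#' @param amplitude_floor minimum accepted transient amplitude (0.05).
#' @param f0_method F0 definition ("min").
#' @param window_rule coupling window rule ("per-event-duration").
#' @param adjacency_rule "grid-rook" or "centroid-distance".
#' @param adjacency_threshold_um threshold for centroid-distance; NULL =
#'   1.5 x median cell diameter.
#' @param alternans_denom denominator of the alternans rule ("max").
#' @param seed seed for any resampling step.
#' @return object of class \code{ca_config} (a named list).
#' @export
analysis_config <- function(threshold_frac = 0.10, diff_frac = 0.10,
                            min_run = 10, sd_mult = 2, merge_gap_s = 0.05,
                            smooth_width = 0, search_window_s = NULL,
                            baseline_window_s = 0.05,
                            amplitude_floor = 0.05, f0_method = "min",
                            window_rule = "per-event-duration",
                            adjacency_rule = "grid-rook",
                            adjacency_threshold_um = NULL,
                            alternans_denom = "max", seed = 1L) {
  cfg <- list(threshold_frac = threshold_frac, diff_frac = diff_frac,
              min_run = min_run, sd_mult = sd_mult,
              merge_gap_s = merge_gap_s, smooth_width = smooth_width,
              search_window_s = search_window_s,
              baseline_window_s = baseline_window_s,
              amplitude_floor = amplitude_floor, f0_method = f0_method,
              window_rule = window_rule, adjacency_rule = adjacency_rule,
              adjacency_threshold_um = adjacency_threshold_um,
              alternans_denom = alternans_denom, seed = as.integer(seed))
  stopifnot(cfg$threshold_frac > 0, cfg$diff_frac > 0, cfg$min_run > 0,
            cfg$sd_mult > 0, cfg$merge_gap_s >= 0,
            cfg$baseline_window_s > 0, cfg$amplitude_floor >= 0)
  class(cfg) <- "ca_config"
  cfg
}

#' Provenance of every configuration default
#'
#' Prints each \code{\link{analysis_config}} value together with whether it
#' is a published constant of the analysis or an implementation default.
#'
#' @param config a \code{ca_config}.
#' @return data.frame \code{name}, \code{value}, \code{provenance}
#'   (invisibly; also printed).
#' @export
show_config <- function(config = analysis_config()) {
  published <- c(threshold_frac = "published: SCR >= 10% of transient",
                 diff_frac = "published: alternans >= 10% difference",
                 min_run = "published: >= 10 transients",
                 sd_mult = "published: 2 SD of basal fluorescence")
  rows <- lapply(names(unclass(config)), function(nm) {
    v <- config[[nm]]
    data.frame(name = nm,
               value = if (is.null(v)) "NULL" else paste(v, collapse = ","),
               provenance = if (nm %in% names(published)) published[[nm]]
                            else "implementation default",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  print(out, row.names = FALSE)
  invisible(out)
}

#' Run the full slice-analysis pipeline on one recording
#'
#' Executes, in order: F/F0 normalization, paced-transient detection and
#' decay fitting, SCR detection and summary, alternans classification,
#' pace-stop latency (when the protocol has a stop time) and the
#' intercellular coupling report (when geometry is available). Stage errors
#' abort with the stage name prefixed.
#'
#' @param rec a \code{\link{ca_recording}} (or a path loadable by
#'   \code{\link{load_recording}}).
#' @param config an \code{\link{analysis_config}}.
#' @param out_dir optional output directory passed to
#'   \code{\link{write_results}}.
#' @return a result bundle: list \code{norm}, \code{transients},
#'   \code{scr}, \code{scr_summary}, \code{alternans}, \code{pace_stop},
#'   \code{adjacency}, \code{coupling}, \code{config}, \code{log}.
#' @export
run_pipeline <- function(rec, config = analysis_config(), out_dir = NULL) {
  if (is.character(rec)) rec <- load_recording(rec)
  stopifnot(inherits(rec, "ca_recording"))
  log <- character(0)
  say <- function(...) {
    log <<- c(log, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  norm <- stage("normalize", normalize_recording(
    rec, f0_method = config$f0_method, smooth_width = config$smooth_width))
  say("normalize: %d cells, F0 method %s", length(norm$cells),
      config$f0_method)
  tr <- stage("transients", detect_paced_transients(
    norm, search_window_s = config$search_window_s,
    baseline_window_s = config$baseline_window_s,
    amplitude_floor = config$amplitude_floor))
  say("transients: %d accepted over %d stimuli", nrow(tr),
      length(rec$protocol$stimulus_times))
  scr <- stage("scr", detect_scr(
    norm, tr, threshold_frac = config$threshold_frac,
    sd_mult = config$sd_mult, merge_gap_s = config$merge_gap_s))
  say("scr: %d events, %.1f s total diastolic exposure",
      nrow(scr$events), sum(scr$exposure$exposure_s))
  scr_sum <- stage("scr_summary", summarize_scr(scr))
  alt <- stage("alternans", classify_alternans_all(
    tr, cells = rec$cells, diff_frac = config$diff_frac,
    min_run = config$min_run, denom = config$alternans_denom))
  say("alternans: %d/%d positive", sum(alt$positive), nrow(alt))
  ps <- NULL
  if (!is.null(rec$protocol$stop_time)) {
    ps <- stage("pace_stop", pace_stop_latency(
      scr, rec$protocol, t_end = rec$times[length(rec$times)]))
    say("pace_stop: %d/%d cells censored", sum(ps$censored), nrow(ps))
  }
  adj <- NULL; cpl <- NULL
  if (!is.null(rec$geometry)) {
    adj <- stage("adjacency", {
      if (config$adjacency_rule == "grid-rook") {
        adjacency_from_geometry(rec$geometry, "grid-rook")
      } else {
        thr <- config$adjacency_threshold_um
        if (is.null(thr)) {
          thr <- 1.5 * stats::median(rec$geometry$diameter_um, na.rm = TRUE)
        }
        adjacency_from_geometry(rec$geometry, "centroid-distance",
                                threshold_um = thr)
      }
    })
    if (nrow(scr$events) > 0) {
      cpl <- stage("coupling", coupling_report(
        scr$events, adj, scr_sum, window_rule = config$window_rule))
      say("coupling: p_obs %.3f vs p_null %.3f over %d sources",
          cpl$p_obs, cpl$p_null, cpl$n_source_events)
    }
  }
  bundle <- list(norm = norm, transients = tr, scr = scr,
                 scr_summary = scr_sum, alternans = alt, pace_stop = ps,
                 adjacency = adj, coupling = cpl,
                 config = unclass(config), log = log)
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

#' Group comparison of a per-cell metric
#'
#' Routine two-group / multi-group comparison: a Shapiro-Wilk normality
#' check per group (alpha = 0.05, recorded), Welch's unequal-variance t
#' test by default for two groups (or a plain unpaired t test on request),
#' one-way ANOVA (Welch form) for more than two. Values are summarized as
#' mean +/- SD.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length, >= 2 levels with
#'   >= 3 values each.
#' @param metric name of the metric (reporting only).
#' @param test \code{"welch"} (default), \code{"student"} or
#'   \code{"anova"} (forced ANOVA even for 2 groups).
#' @return object of class \code{ca_group_comparison}: list \code{metric},
#'   \code{groups} (data.frame \code{group}, \code{n}, \code{mean},
#'   \code{sd}, \code{shapiro_p}), \code{test}, \code{statistic},
#'   \code{p_value}.
#' @export
compare_groups <- function(values, groups, metric = "metric",
                           test = c("welch", "student", "anova")) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  tab <- split(values, groups)
  if (any(vapply(tab, length, 1L) < 3)) {
    stop("every group needs at least 3 values")
  }
  gsum <- do.call(rbind, lapply(names(tab), function(g) {
    x <- tab[[g]]
    sw <- if (length(unique(x)) > 1 && length(x) >= 3 && length(x) <= 5000) {
      stats::shapiro.test(x)$p.value
    } else NA_real_
    data.frame(group = g, n = length(x), mean = mean(x), sd = stats::sd(x),
               shapiro_p = sw, stringsAsFactors = FALSE)
  }))
  if (nlevels(groups) == 2 && test != "anova") {
    ht <- stats::t.test(tab[[1]], tab[[2]], var.equal = (test == "student"))
    used <- if (test == "student") "unpaired t" else "Welch two-sample"
  } else {
    ht <- stats::oneway.test(values ~ groups)
    used <- "one-way ANOVA (Welch)"
  }
  structure(list(metric = metric, groups = gsum, test = used,
                 statistic = unname(ht$statistic), p_value = ht$p.value),
            class = "ca_group_comparison")
}

#' @export
print.ca_group_comparison <- function(x, ...) {
  cat(x$metric, "by group (mean +/- SD):\n")
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %s: %.4g +/- %.4g (n = %d, Shapiro p = %.3g)\n",
                g$group, g$mean, g$sd, g$n, g$shapiro_p))
  }
  cat(sprintf("  %s: statistic %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  invisible(x)
}
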