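test_that("basal statistics are estimated robustly from diastolic samples", {
  set.seed(31)
  times <- seq(0, 9.99, by = 0.01)
  proto <- ca_protocol(numeric(0), rate_hz = 1)
  y <- rnorm(1000, 1.0, 0.01)
  bs <- estimate_basal_stats(y, times, proto)
  expect_equal(bs$mean, 1.0, tolerance = 0.002)
  expect_lt(abs(bs$sd - 0.01) / 0.01, 0.20)

  # a large square event must not inflate the SD (iterative exclusion)
  y_ev <- y
  y_ev[300:390] <- y_ev[300:390] + 0.5
  bs_ev <- estimate_basal_stats(y_ev, times, proto)
  expect_lt(abs(bs_ev$sd - bs$sd) / bs$sd, 0.25)
  expect_equal(bs_ev$mean, bs$mean, tolerance = 0.005)

  # constant trace: degenerate flag for the amplitude-rule fallback
  bs_c <- estimate_basal_stats(rep(2, 1000), times, proto)
  expect_true(bs_c$degenerate)
  expect_equal(bs_c$sd, 0)

  expect_error(estimate_basal_stats(y[1:10], times[1:10], proto),
               "20 diastolic samples")
})

test_that("the 10%-of-transient amplitude rule gates SCR inclusion", {
  # transient amplitude 1.0; two diastolic bumps at 5% and 15% of it
  bumps <- data.frame(cell_index = c(1, 1), onset = c(4, 10),
                      amplitude = c(0.05, 0.15), width_s = c(0.9, 0.9))
  rec <- build_recording(stims = c(1, 16), duration_s = 18, amplitude = 1,
                         bumps = bumps, noise_sd = 0.1, seed = 6)
  b <- run_pipeline(rec)
  ev <- b$scr$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 10, tolerance = 0.1)
  expect_equal(ev$amplitude, 0.15, tolerance = 0.03)
})

test_that("event duration spans the bounding 2-SD crossings", {
  times <- seq(0, 19.99, by = 0.01)
  set.seed(7)
  y <- 100 + rnorm(length(times), 0, 0.1)
  y[times >= 2.0 & times < 2.9] <- y[times >= 2.0 & times < 2.9] + 50
  y <- y + 100 * transient_kernel(times - 16, 0.03, 0.3)  # one transient
  rec <- ca_recording(matrix(y, 1), times, ca_protocol(16, 1))
  b <- run_pipeline(rec)
  ev <- b$scr$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 0.9, tolerance = 0.011)
  expect_equal(ev$onset_s, 2.0, tolerance = 0.011)
})

test_that("detection is exact on high-SNR, well-separated events", {
  cfg <- sim_config(n_rows = 4, n_cols = 5, duration_s = 60,
                    pacing = list(stop_time_s = 5.5), ne = list(on = TRUE),
                    scr = list(base_rate_hz = 0.05 / 4, refractory_s = 2),
                    noise = list(sd = 1, f0 = 100), seed = 13)
  out <- simulate_slice_recording(cfg)
  b <- run_pipeline(out$recording)
  m <- match_events(b$scr$events, out$truth$scr_events,
                    tol_s = 2 * frame_interval(out$recording))
  expect_gt(m$n_true, 15)
  expect_equal(m$recall, 1.0)
  expect_equal(m$precision, 1.0)
})

test_that("detection is invariant to a positive rescaling of raw F", {
  cfg <- sim_config(n_rows = 2, n_cols = 3, duration_s = 40,
                    pacing = list(stop_time_s = 4.5),
                    scr = list(base_rate_hz = 0.2), seed = 9)
  out <- simulate_slice_recording(cfg)
  rec2 <- out$recording
  rec2$fluor <- rec2$fluor * 3.7
  b1 <- run_pipeline(out$recording)
  b2 <- run_pipeline(rec2)
  expect_equal(b1$scr$events$onset_s, b2$scr$events$onset_s)
  expect_equal(b1$scr$events$amplitude, b2$scr$events$amplitude,
               tolerance = 1e-9)
})

test_that("no detected event overlaps a stimulus-locked transient window", {
  fx <- make_fixture("pace_stop_basic")
  b <- run_pipeline(fx$recording)
  stims <- fx$recording$protocol$stimulus_times
  win <- 0.8 / fx$recording$protocol$rate_hz
  for (on in b$scr$events$onset_s) {
    expect_false(any(on >= stims & on < stims + win))
  }
})

test_that("false positives on event-free noise are below 0.01 /s/cell", {
  cfg <- sim_config(n_rows = 4, n_cols = 5, duration_s = 120,
                    pacing = list(stop_time_s = 8.5),
                    scr = list(base_rate_hz = 0),
                    noise = list(sd = 1, f0 = 100), seed = 30)
  out <- simulate_slice_recording(cfg)
  b <- run_pipeline(out$recording)
  fp_rate <- nrow(b$scr$events) / sum(b$scr$exposure$exposure_s)
  expect_lt(fp_rate, 0.01)
})

test_that("summaries divide events by diastolic exposure", {
  scr <- structure(list(
    events = data.frame(cell = rep("a", 3), onset_s = c(1, 2, 3),
                        peak_s = c(1.1, 2.1, 3.1), amplitude = rep(0.5, 3),
                        duration_s = rep(0.9, 3), interval_index = 1:3),
    exposure = data.frame(cell = c("a", "b"), exposure_s = c(7.5, 7.5)),
    thresholds = NULL, params = list()), class = "ca_scr")
  s <- summarize_scr(scr)
  expect_equal(s$per_cell$rate_hz[s$per_cell$cell == "a"], 0.4)
  expect_equal(s$per_cell$rate_hz[s$per_cell$cell == "b"], 0)
  expect_equal(s$fraction_active, 0.5)
  scr0 <- scr
  scr0$events <- scr$events[0, ]
  s0 <- summarize_scr(scr0)
  expect_true(all(s0$per_cell$rate_hz == 0))
  expect_equal(s0$fraction_active, 0)
  scr_bad <- scr
  scr_bad$exposure$exposure_s[1] <- 0
  expect_error(summarize_scr(scr_bad), "exposure")
})

test_that("pace-stop latency is measured from the stop time", {
  scr <- structure(list(
    events = data.frame(cell = c("a", "a"), onset_s = c(5, 13),
                        peak_s = c(5.2, 13.2), amplitude = c(0.5, 0.5),
                        duration_s = c(0.9, 0.9), interval_index = c(1, 2)),
    exposure = data.frame(cell = c("a", "b"), exposure_s = c(20, 20)),
    thresholds = data.frame(cell = c("a", "b"),
                            ref_amplitude = c(1, 1)),
    params = list()), class = "ca_scr")
  proto <- ca_protocol(c(1, 2), 2, stop_time = 10)
  ps <- pace_stop_latency(scr, proto, t_end = 30)
  expect_equal(ps$latency_s[ps$cell == "a"], 3.0)  # 13 - 10; event at 5 ignored
  expect_false(ps$censored[ps$cell == "a"])
  expect_equal(ps$latency_s[ps$cell == "b"], 20)   # censored at end - stop
  expect_true(ps$censored[ps$cell == "b"])
  expect_error(pace_stop_latency(scr, ca_protocol(c(1, 2), 2), 30),
               "stop_time")
})

test_that("mean pace-stop latency matches the exponential oracle", {
  # first-event times after diastole onset are Exp(lambda); the analytic
  # mean latency from stop_time adds the post-stimulus blanking dead time
  lat <- c(); expect_mean <- NULL
  for (s in 1:3) {
    cfg <- sim_config(n_rows = 10, n_cols = 20, duration_s = 70,
                      frame_interval_s = 0.02,
                      pacing = list(rate_hz = 2, start_s = 0.5,
                                    stop_time_s = 8.5),
                      ne = list(on = TRUE),
                      scr = list(base_rate_hz = 0.5 / 4),
                      noise = list(sd = 1, f0 = 100), seed = s)
    out <- simulate_slice_recording(cfg)
    b <- run_pipeline(out$recording)
    lat <- c(lat, b$pace_stop$latency_s[!b$pace_stop$censored])
    if (is.null(expect_mean)) {
      last_stim <- max(out$recording$protocol$stimulus_times)
      dead <- last_stim + out$truth$blank_window_s - 8.5
      expect_mean <- dead + 1 / 0.5
    }
  }
  expect_gt(length(lat), 500)
  expect_lt(abs(mean(lat) - expect_mean) / expect_mean, 0.10)
})
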