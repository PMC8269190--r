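test_that("wide and long trace tables load to identical recordings", {
  dir <- withr::local_tempdir()
  times <- seq(0, 0.99, by = 0.01)
  set.seed(4)
  fl <- matrix(runif(3 * 100, 90, 200), 3, 100,
               dimnames = list(c("a", "b", "c"), NULL))
  proto <- ca_protocol(c(0.2, 0.7), rate_hz = 2)
  rec <- ca_recording(fl, times, proto)
  wide_p <- file.path(dir, "traces.csv")
  write_recording(rec, wide_p)
  long <- data.frame(cell = rep(rec$cells, each = 100),
                     time = rep(times, 3),
                     F = as.vector(t(fl)))
  long_p <- file.path(dir, "long.csv")
  write.csv(long, long_p, row.names = FALSE)
  file.copy(file.path(dir, "traces_protocol.json"),
            file.path(dir, "long_protocol.json"))

  r_wide <- load_recording(wide_p)
  r_long <- load_recording(long_p)
  expect_equal(r_wide$cells, rec$cells)
  expect_equal(r_long$cells, rec$cells)
  expect_equal(r_wide$fluor, r_long$fluor, tolerance = 1e-12)
  expect_equal(r_wide$times, r_long$times)
  expect_equal(r_wide$protocol$stimulus_times, proto$stimulus_times)
  expect_equal(frame_interval(r_wide), 0.01, tolerance = 1e-9)
})

test_that("grid violations and missing metadata are hard errors", {
  dir <- withr::local_tempdir()
  times <- c(seq(0, 0.5, by = 0.01), 0.52)  # jittered last interval
  tab <- data.frame(time = times, cell_1 = seq_along(times) + 100)
  p <- file.path(dir, "bad.csv")
  write.csv(tab, p, row.names = FALSE)
  jsonlite::write_json(list(stimulus_times = 0.1, rate_hz = 1),
                       file.path(dir, "bad_protocol.json"),
                       auto_unbox = TRUE)
  expect_error(load_recording(p), "non-uniform time grid")

  long <- data.frame(cell = c("a", "a"), time = c(0, 0), F = c(1, 2))
  p2 <- file.path(dir, "dup.csv")
  write.csv(long, p2, row.names = FALSE)
  jsonlite::write_json(list(stimulus_times = 0, rate_hz = 1),
                       file.path(dir, "dup_protocol.json"),
                       auto_unbox = TRUE)
  expect_error(load_recording(p2), "duplicate")

  ok <- data.frame(time = seq(0, 1, by = 0.1), cell_1 = 1:11 + 100)
  p3 <- file.path(dir, "noproto.csv")
  write.csv(ok, p3, row.names = FALSE)
  expect_error(load_recording(p3), "infer_protocol")
})

test_that("extract_traces averages ROI pixels per frame", {
  # 2 frames of 2x2: ROI 1 = left column
  stack <- array(0, c(2, 2, 2))
  stack[1, , ] <- matrix(c(10, 20, 0, 5), 2)   # frame 1: col1 = (10,20)
  stack[2, , ] <- matrix(c(30, 40, 0, 5), 2)
  labels <- matrix(c(1, 1, 0, 0), 2)
  proto <- ca_protocol(numeric(0), rate_hz = 1)
  rec <- extract_traces(stack, labels, frame_interval_s = 0.01,
                        protocol = proto)
  expect_equal(unname(rec$fluor[1, ]), c(15, 35))

  # single-pixel ROI is the pixel's own series
  labels2 <- matrix(c(0, 0, 0, 2), 2)
  rec2 <- extract_traces(stack, labels2, 0.01, proto)
  expect_equal(unname(rec2$fluor[1, ]), c(stack[1, 2, 2], stack[2, 2, 2]))

  expect_error(extract_traces(stack, matrix(0, 2, 2), 0.01, proto),
               "no ROI")
  expect_error(extract_traces(stack, matrix(1, 3, 3), 0.01, proto),
               "shape")
  # constant frames give constant traces at the ROI mean
  cst <- array(7, c(3, 2, 2))
  rc <- extract_traces(cst, labels, 0.01, proto)
  expect_equal(unname(rc$fluor[1, ]), rep(7, 3))
})

test_that("adjacency rules enumerate the expected edges", {
  g <- ca_geometry(paste0("c", 1:4), x_um = c(0, 20, 0, 20),
                   y_um = c(0, 0, 20, 20), row = c(1, 1, 2, 2),
                   col = c(1, 2, 1, 2), diameter_um = 20)
  a <- adjacency_from_geometry(g, "grid-rook")
  expect_equal(nrow(a$edges), 4)
  expect_equal(a$rule, "grid-rook")

  g3 <- ca_geometry(paste0("c", 1:3), x_um = c(0, 20, 40), y_um = c(0, 0, 0))
  a3 <- adjacency_from_geometry(g3, "centroid-distance", threshold_um = 25)
  expect_equal(nrow(a3$edges), 2)
  expect_setequal(paste(a3$edges$from, a3$edges$to),
                  c("c1 c2", "c2 c3"))

  g1 <- ca_geometry("solo", 0, 0)
  a1 <- adjacency_from_geometry(g1, "centroid-distance", threshold_um = 50)
  expect_equal(nrow(a1$edges), 0)
  expect_error(adjacency_from_geometry(g3, "grid-rook"), "grid")
})

test_that("random geometries give symmetric, self-edge-free graphs", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(5:25, 1)
    g <- ca_geometry(paste0("c", seq_len(n)), runif(n, 0, 100),
                     runif(n, 0, 100))
    a <- adjacency_from_geometry(g, "centroid-distance",
                                 threshold_um = runif(1, 10, 50))
    expect_true(all(a$edges$from != a$edges$to))
    expect_false(any(duplicated(a$edges)))
    deg <- adjacency_degree(a)
    expect_equal(sum(deg), 2 * nrow(a$edges))
    # symmetry: neighbor lists mirror each other
    nb <- neighbor_list(a)
    for (e in seq_len(nrow(a$edges))) {
      expect_true(a$edges$from[e] %in% nb[[a$edges$to[e]]])
    }
  }
})

test_that("result bundles round-trip through write_results/read_results", {
  dir <- withr::local_tempdir()
  fx <- make_fixture("pace_stop_basic")
  b <- run_pipeline(fx$recording, analysis_config(seed = 7),
                    out_dir = file.path(dir, "out"))
  rt <- read_results(file.path(dir, "out"))
  expect_equal(rt$manifest$seed, 7)
  expect_equal(rt$scr_events$onset_s, b$scr$events$onset_s,
               tolerance = 1e-12)
  expect_equal(rt$scr_events$cell, b$scr$events$cell)
  expect_equal(rt$alternans$positive, b$alternans$positive)
  expect_equal(rt$pace_stop$latency_s, b$pace_stop$latency_s,
               tolerance = 1e-12)
  # empty event table still writes a header-only CSV
  empty <- b
  empty$scr$events <- b$scr$events[0, ]
  write_results(empty, file.path(dir, "empty"))
  re <- read_results(file.path(dir, "empty"))
  expect_equal(nrow(re$scr_events), 0)
  expect_named(re$scr_events, names(b$scr$events))
})

test_that("kymographs round-trip through CSV + JSON", {
  dir <- withr::local_tempdir()
  k <- simulate_kymograph(50, seed = 3, noise_sd = 5)$kymograph
  p <- file.path(dir, "kymo.csv")
  write_kymograph(k, p)
  k2 <- read_kymograph(p)
  expect_equal(k2$mat, k$mat, tolerance = 1e-12)
  expect_equal(k2$pixel_um, k$pixel_um)
  expect_equal(k2$line_interval_s, k$line_interval_s)
})

test_that("infer_protocol recovers stimulus times from clean traces", {
  rec <- build_recording(stims = c(1, 2, 3, 4), duration_s = 5,
                         n_cells = 3, rate_hz = 1)
  pr <- infer_protocol(rec$fluor, rec$times, rate_hz = 1)
  expect_equal(length(pr$stimulus_times), 4)
  expect_true(all(abs(pr$stimulus_times - c(1, 2, 3, 4)) <= 0.03))
})
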