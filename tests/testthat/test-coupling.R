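grid_adj <- function(nr, nc) {
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  cells <- paste0("cell_", seq_len(nr * nc))
  adjacency_from_geometry(
    ca_geometry(cells, cols * 20, rows * 20, row = rows, col = cols),
    "grid-rook")
}

test_that("neighbor latencies respect the coupling window", {
  adj <- grid_adj(1, 3)  # chain: cell_1 - cell_2 - cell_3
  ev <- data.frame(cell = c("cell_2", "cell_1", "cell_3"),
                   onset_s = c(5.0, 5.4, 6.1),
                   duration_s = c(0.9, 0.9, 0.9))
  nl <- neighbor_latencies(ev, adj)
  r <- nl$records[nl$records$source_cell == "cell_2", ]
  expect_equal(r$latency_s[r$neighbor_cell == "cell_1"], 0.4)
  # cell_3 at 6.1 is outside [5.0, 5.9]
  expect_false("cell_3" %in% r$neighbor_cell)
  # a neighbor with no events contributes no record
  ev2 <- ev[1, ]
  nl2 <- neighbor_latencies(ev2, adj)
  expect_equal(nrow(nl2$records), 0)
  expect_equal(nl2$n_source_events, 1)
  expect_error(neighbor_latencies(ev, structure(
    list(edges = data.frame(from = character(), to = character()),
         cells = adj$cells, rule = "x"), class = "ca_adjacency")),
    "empty")
})

test_that("secondary events are attributed to the earliest source", {
  adj <- grid_adj(1, 3)
  # two sources (cells 1 and 3) flank cell_2, whose single event falls in
  # both windows: only the earlier source gets the attribution
  ev <- data.frame(cell = c("cell_1", "cell_3", "cell_2"),
                   onset_s = c(5.0, 5.1, 5.5),
                   duration_s = c(0.9, 0.9, 0.9))
  nl <- neighbor_latencies(ev, adj)
  att <- nl$records[nl$records$attributed, ]
  expect_equal(sum(att$neighbor_cell == "cell_2"), 1)
  expect_equal(att$source_cell[att$neighbor_cell == "cell_2"], "cell_1")
  # but both sources count cell_2 as a within-window secondary for p_obs
  expect_equal(sum(nl$per_source$n_within[nl$per_source$cell
                                          %in% c("cell_1", "cell_3")]),
               2)
})

test_that("the closed-form null matches process-level simulation", {
  expect_equal(poisson_null_probability(0, 0.9), 0)
  expect_gt(poisson_null_probability(100, 1), 0.999)
  expect_error(poisson_null_probability(-1, 0.9), "lambda")

  p_closed <- poisson_null_probability(0.4, 0.915, 1)
  expect_equal(p_closed, 1 - exp(-0.366), tolerance = 1e-12)
  # oracle: homogeneous Poisson trains built from exponential gaps
  set.seed(18)
  hits <- vapply(1:20000, function(i) {
    t <- 0; hit <- FALSE
    while (t < 0.915) {
      t <- t + rexp(1, 0.4)
      if (t < 0.915) { hit <- TRUE; break }
    }
    hit
  }, logical(1))
  expect_lt(abs(mean(hits) - p_closed), 0.01)
})

test_that("the uncoupled world matches the independent-events null", {
  fx <- make_fixture("coupling_null")
  rep0 <- coupling_report(truth_events(fx$truth), fx$truth$adjacency,
                          summary = length(fx$recording$cells) *
                            fx$truth$diastolic_exposure_s)
  se <- sqrt(rep0$p_obs * (1 - rep0$p_obs) / rep0$n_source_events)
  expect_gt(rep0$n_source_events, 200)
  expect_lt(abs(rep0$p_obs - rep0$p_null), 3 * se)
})

test_that("observed probability rises monotonically with coupling k", {
  p <- vapply(c(1, 5, 20), function(k) {
    cfg <- sim_config(n_rows = 4, n_cols = 5, duration_s = 60,
                      pacing = list(stop_time_s = 4.5),
                      scr = list(base_rate_hz = 0.2),
                      coupling = list(k = k), seed = 19)
    out <- simulate_slice_recording(cfg)
    nl <- neighbor_latencies(truth_events(out$truth), out$truth$adjacency)
    observed_neighbor_probability(nl)$p_obs
  }, numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("p_obs is invariant under cell relabeling", {
  fx <- make_fixture("coupling_null")
  ev <- truth_events(fx$truth)
  adj <- fx$truth$adjacency
  # reverse the labels consistently
  relabel <- setNames(rev(adj$cells), adj$cells)
  ev2 <- ev; ev2$cell <- unname(relabel[ev$cell])
  adj2 <- adj
  adj2$edges$from <- unname(relabel[adj$edges$from])
  adj2$edges$to <- unname(relabel[adj$edges$to])
  p1 <- observed_neighbor_probability(neighbor_latencies(ev, adj))$p_obs
  p2 <- observed_neighbor_probability(neighbor_latencies(ev2, adj2))$p_obs
  expect_equal(p1, p2)
  expect_true(all(neighbor_latencies(ev, adj)$records$latency_s >= 0))
})

test_that("strong coupling separates sharply from the null", {
  fx <- make_fixture("coupling_strong")
  b <- run_pipeline(fx$recording)
  expect_gt(b$coupling$p_obs, 0.8)
  expect_gt(b$coupling$p_obs - b$coupling$p_null, 0.3)
  # leave-one-out null is lower still (secondaries removed from the rate)
  rep_loo <- coupling_report(b$scr$events, b$adjacency, b$scr_summary,
                             leave_one_out = TRUE)
  expect_lt(rep_loo$p_null_loo, rep_loo$p_null)
})

test_that("only the coupled group shows short neighbor latencies", {
  mk <- function(k, seed) {
    cfg <- sim_config(n_rows = 4, n_cols = 5, duration_s = 60,
                      pacing = list(stop_time_s = 4.5), ne = list(on = TRUE),
                      scr = list(base_rate_hz = 0.1,
                                 refractory_s = if (k > 1) 4 else 0),
                      coupling = list(k = k), seed = seed)
    out <- simulate_slice_recording(cfg)
    b <- run_pipeline(out$recording)
    b$coupling
  }
  reports <- list("CPVT+NE" = mk(20, 23), "WT+NE" = mk(1, 24))
  tab <- coupling_group_table(reports)
  expect_lt(tab$mean_latency_s[tab$group == "CPVT+NE"],
            tab$mean_latency_s[tab$group == "WT+NE"])
})
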