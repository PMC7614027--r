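fake_records <- function(plugin, complete, exec, input = NA_real_) {
  data.frame(plugin = plugin, frame_id = seq_along(complete) - 1L,
             input_time = if (all(is.na(input))) complete - exec - 0.01 else input,
             arrival_time = complete - exec - 0.005,
             dispatch_time = complete - exec,
             complete_time = complete, exec_time = exec,
             stringsAsFactors = FALSE)
}

test_that("execution-time summaries match hand arithmetic", {
  r <- fake_records("pa", complete = c(3, 4), exec = c(0.010, 0.020))
  s <- execution_time_summary(r, "pa")
  expect_equal(s$mean, 0.015)
  expect_equal(s$sd, 0.0070710678, tolerance = 1e-6)
  expect_equal(s$n, 2L)

  same <- fake_records("pa", complete = 3:7, exec = rep(0.010, 5))
  expect_equal(execution_time_summary(same, "pa")$mean, 0.010)
  expect_equal(execution_time_summary(same, "pa")$sd, 0)

  empty <- execution_time_summary(r, "other")
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
})

test_that("effective rate counts completions in a steady-state window", {
  r <- fake_records("pa", complete = seq(0.1, 12, by = 0.1), exec = 0.01)
  expect_equal(effective_rate(r, "pa", window = 10, warmup = 2), 10)
  expect_equal(effective_rate(r, "pa", window = 10, warmup = 2) / 2,
               effective_rate(fake_records("pa", seq(0.2, 12, 0.2), 0.01),
                              "pa", window = 10, warmup = 2))
  expect_error(effective_rate(r, "pa", window = 60), "exceeds the recorded run")
})

test_that("delay to input tracks frames across the pipeline and skips unmatched ones", {
  run <- run_pipeline(delay_pipeline(wait = 0.1, rate = 20, duration = 20),
                      duration = 20)
  d <- delay_to_input(run, "pythonalgorithm")
  T <- 0.125; p <- 1 / 20
  expect_true(all(d >= T - 1e-9))
  expect_true(all(d <= T + p + 1e-9))
  expect_equal(attr(d, "skipped"), 0L)

  r <- fake_records("pa", complete = c(3, 4, 5), exec = 0.01)
  r$input_time[2L] <- NA
  d2 <- delay_to_input(r, "pa")
  expect_length(d2, 2L)
  expect_equal(attr(d2, "skipped"), 1L)
})

test_that("in a sequential chain, delays are ordered along the pipeline", {
  run <- bench_pipeline(wait = 0.1, rate = 20, wiring = "sequential",
                        duration = 30)
  d_pa <- median(delay_to_input(run, "pythonalgorithm"))
  d_ca <- median(delay_to_input(run, "cppalgorithm"))
  d_spd <- median(delay_to_input(run, "standardplanedetection"))
  expect_lte(d_pa, d_ca)
  expect_lte(d_ca, d_spd)
})

test_that("report layouts pivot the benchmark grid into the expected shapes", {
  grid <- run_delay_grid(waits = c(0, 0.1), rates = 20,
                         wiring = c("parallel", "sequential"), duration = 12)
  t3 <- telemetry_report(grid, "table3")
  expect_identical(sort(unique(t3$wiring)), c("parallel", "sequential"))
  expect_true(all(c("wait_0ms", "wait_100ms") %in% names(t3)))
  expect_equal(nrow(t3), 6L)   # 2 wirings x 3 plug-ins
  expect_match(t3$wait_0ms[1L], "^[0-9.]+ ± [0-9.]+$")

  t2 <- telemetry_report(grid, "table2")
  expect_equal(nrow(t2), 6L)
  # wait-dominated execution times: mean is the wait plus small task cost
  s <- grid$summary
  pa <- s[s$plugin == "pythonalgorithm" & s$wait == 0.1 &
            s$wiring == "sequential", ]
  expect_equal(pa$exec_mean_ms, 125, tolerance = 1e-6)

  f3 <- telemetry_report(grid, "fig3")
  expect_true(all(c("delay_median", "rate", "wait") %in% names(f3)))

  csv <- withr::local_tempfile(fileext = ".csv")
  telemetry_report(grid, "table3", file = csv)
  expect_true(file.exists(csv))
  expect_equal(nrow(utils::read.csv(csv, check.names = FALSE)), 6L)
})

test_that("empty telemetry produces headers only", {
  empty_grid <- list(summary = data.frame(
    wiring = character(0), rate = numeric(0), wait = numeric(0),
    plugin = character(0), rate_cell = character(0), exec_cell = character(0),
    delay_q25 = numeric(0), delay_median = numeric(0), delay_q75 = numeric(0)))
  t3 <- telemetry_report(empty_grid, "table3")
  expect_equal(nrow(t3), 0L)
})
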