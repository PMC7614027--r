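test_that("tick/drop law: predicted effective rate", {
  # sub-period tasks keep the full requested rate
  expect_equal(predicted_effective_rate(20, 0), 20)
  expect_equal(predicted_effective_rate(40, 0.01), 40)
  # a task slightly over k periods costs k+1 ticks
  expect_equal(predicted_effective_rate(20, 0.101), 20 / 3)
  expect_equal(predicted_effective_rate(10, 0.201), 10 / 3)
  # a task of exactly k periods completes at a tick, which dispatches
  expect_equal(predicted_effective_rate(20, 0.100), 10)
  expect_error(predicted_effective_rate(0, 0.1))
  expect_error(predicted_effective_rate(20, -1))
})

test_that("latest-frame admission replaces and drop-counts pending frames", {
  pl <- new.env(parent = emptyenv())
  pl$token <- "probe"
  pl$drop_disabled <- FALSE
  pulsestream:::sched_init(pl)
  f1 <- make_frame(matrix(1, 2, 2)); f2 <- make_frame(matrix(2, 2, 2))

  expect_warning(pulsestream:::sched_receive(pl, f1, TRUE), "before activation")
  pl$active <- TRUE
  pulsestream:::sched_receive(pl, f1, TRUE)
  pulsestream:::sched_receive(pl, f2, TRUE)
  expect_equal(pl$received, 2L)
  expect_equal(pl$dropped, 1L)
  expect_identical(pl$pending, f2)      # latest frame wins

  pulsestream:::sched_receive(pl, f1, FALSE)   # not accepted: no counters
  expect_equal(pl$received, 2L)

  got <- pulsestream:::sched_take(pl)
  expect_identical(got, f2)
  expect_null(pl$pending)
  pl$busy <- TRUE
  expect_null(pulsestream:::sched_take(pl))    # busy worker: tick is a no-op
  pulsestream:::sched_complete(pl)
  expect_false(pl$busy)
  expect_equal(pl$processed, 1L)
})

test_that("process-all mode queues every frame in order", {
  pl <- new.env(parent = emptyenv())
  pl$token <- "writer"
  pl$drop_disabled <- TRUE
  pulsestream:::sched_init(pl)
  pl$active <- TRUE
  frames <- lapply(1:5, function(k) make_frame(matrix(k, 2, 2)))
  for (f in frames) pulsestream:::sched_receive(pl, f, TRUE)
  expect_equal(pl$dropped, 0L)
  expect_equal(pulsestream:::n_pending(pl), 5L)
  taken <- vapply(1:5, function(k) pulsestream:::sched_take(pl)$layers[[1]][1, 1],
                  numeric(1))
  expect_equal(taken, 1:5)   # FIFO
})

test_that("engine matches the ceil-law and keeps frame conservation", {
  run <- run_pipeline(delay_pipeline(wait = 0.1, rate = 20, duration = 30),
                      duration = 30)
  r <- run$records[run$records$plugin == "pythonalgorithm", ]
  # steady-state dispatch interval is exactly ceil(T/p) ticks
  gaps <- diff(r$dispatch_time[r$dispatch_time > 2])
  expect_equal(unique(round(gaps, 9)), 0.15)
  expect_equal(1 / median(gaps), predicted_effective_rate(20, 0.125),
               tolerance = 1e-9)
  # conservation: received = processed + dropped + pending (+ busy in-flight)
  cnt <- run$counters[run$counters$plugin == "pythonalgorithm", ]
  expect_equal(cnt$received,
               cnt$processed + cnt$dropped + cnt$pending + cnt$busy)
})

test_that("no-drift: a dispatched frame is the latest arrival and never stale", {
  run <- run_pipeline(delay_pipeline(wait = 0.1, rate = 20, duration = 20),
                      duration = 20)
  r <- run$records[run$records$plugin == "pythonalgorithm", ]
  age <- r$dispatch_time - r$arrival_time
  p <- 1 / 20
  expect_true(all(age >= -1e-9))
  expect_true(all(age <= p + 1e-9))        # stronger than the T + p bound
  expect_true(all(diff(r$frame_id) > 0))   # monotone source ids
})

test_that("a failing worker drops its frame but never stalls siblings", {
  cfg <- list(framesource = list(duration = 5, fps = 30, width = 8, height = 8),
              pythonalgorithm = list(framerate = 20, sigma = 1, layer = 5L),
              cppalgorithm = list(framerate = 20))
  pls <- build_pipeline("framesource>pythonalgorithm>cppalgorithm", cfg)
  run <- run_pipeline(pls, duration = 5)
  cnt <- run$counters
  expect_equal(cnt$processed[cnt$plugin == "pythonalgorithm"], 0L)
  expect_gt(cnt$dropped[cnt$plugin == "pythonalgorithm"], 0L)
  # sibling on 'Input' keeps its full requested rate
  expect_gt(cnt$processed[cnt$plugin == "cppalgorithm"], 50L)
})

test_that("completion with a pending frame waits for the next tick", {
  # discrete-event trace: T = 0.12, p = 0.1 -> dispatches at 0.1, 0.3, 0.5...
  pls <- build_pipeline("framesource>pythonalgorithm", list(
    framesource = list(duration = 1.05, fps = 30, width = 8, height = 8),
    pythonalgorithm = list(delay = 0.095, framerate = 10, sigma = 1)))
  run <- run_pipeline(pls, duration = 1.05)
  r <- run$records[run$records$plugin == "pythonalgorithm", ]
  # cost 0.025 + delay 0.095 = 0.12 s task; completions at dispatch + 0.12,
  # next dispatch at the following tick
  expect_equal(r$dispatch_time, seq(0.1, 0.9, by = 0.2), tolerance = 1e-9)
  expect_equal(r$complete_time - r$dispatch_time, rep(0.12, nrow(r)),
               tolerance = 1e-9)
})
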