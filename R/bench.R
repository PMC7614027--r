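#' Frame-rate and delay benchmark harness
#'
#' Reproduces the platform's characterisation experiments: a synthetic
#' source emitting at 30 Hz feeds the blur plug-in (carrying an artificial
#' wait), the threshold plug-in and the classifier, wired either in
#' parallel (all three subscribed to `'Input'`) or in sequence (each
#' subscribed to the previous plug-in's stream, last layer). The harness
#' runs this pipeline over a grid of wait times and requested frame rates
#' and summarises per-plugin execution time, effective frame rate and
#' delay-to-input.
#'
#' @name benchmark
NULL

#' Build and run one benchmark pipeline
#'
#' @param wait Artificial wait in the first processing plug-in, seconds.
#' @param rate Requested frame rate for all three processing plug-ins, Hz.
#' @param wiring `"sequential"` or `"parallel"`.
#' @param duration Session length in engine-clock seconds.
#' @param clock `"simulated"` or `"wall"`.
#' @param source_fps Source emission rate in Hz.
#' @param seed Seed for the synthetic source.
#' @param size Frame side length in pixels.
#' @return A `ps_run`.
#' @export
bench_pipeline <- function(wait = 0, rate = 20,
                           wiring = c("sequential", "parallel"),
                           duration = 120, clock = "simulated",
                           source_fps = 30, seed = 1L, size = 24L) {
  wiring <- match.arg(wiring)
  cfg <- list(
    framesource = list(duration = duration, fps = source_fps, seed = seed,
                       width = size, height = size),
    pythonalgorithm = list(delay = wait, framerate = rate, sigma = 2),
    cppalgorithm = list(framerate = rate),
    standardplanedetection = list(framerate = rate, taverage = 5L)
  )
  if (wiring == "sequential") {
    cfg$cppalgorithm$stream <- "pythonalgorithm"
    cfg$cppalgorithm$layer <- -1L
    cfg$standardplanedetection$stream <- "cppalgorithm"
    cfg$standardplanedetection$layer <- -1L
  }
  pl <- build_pipeline(
    "framesource>pythonalgorithm>cppalgorithm>standardplanedetection", cfg)
  run_pipeline(pl, duration = duration, clock = clock)
}

#' Run the benchmark grid
#'
#' Runs [bench_pipeline()] over every combination of `waits`, `rates` and
#' `wiring`, and summarises each plug-in in each configuration.
#'
#' @param waits Wait times in seconds, default the characterisation grid
#'   `c(0, 0.05, 0.1, 0.15, 0.2)`.
#' @param rates Requested frame rates in Hz, default `c(10, 20, 30, 40)`
#'   for sequential wiring; parallel runs use 20 Hz.
#' @param wiring Character vector, subset of
#'   `c("parallel", "sequential")`.
#' @param duration Session length per run, seconds.
#' @param clock `"simulated"` or `"wall"`.
#' @param warmup Seconds excluded from steady-state statistics.
#' @param seed Source seed.
#' @inheritParams bench_pipeline
#' @return List with `summary` (one row per run x plug-in: measured rate,
#'   `mean +/- sd` cells for rate and execution time, delay quartiles,
#'   predicted ceil-law rate) and `runs` (the `ps_run` objects, named
#'   `wiring_rate_waitms`).
#' @export
run_delay_grid <- function(waits = c(0, 0.05, 0.1, 0.15, 0.2),
                           rates = c(10, 20, 30, 40),
                           wiring = c("parallel", "sequential"),
                           duration = 120, clock = "simulated", warmup = 2,
                           source_fps = 30, seed = 1L, size = 24L) {
  wiring <- match.arg(wiring, c("parallel", "sequential"), several.ok = TRUE)
  runs <- list()
  rows <- list()
  plugin_streams <- c("pythonalgorithm", "cppalgorithm", "standardplanedetection")
  for (wr in wiring) {
    wr_rates <- if (wr == "parallel") intersect(20, c(rates, 20)) else rates
    for (f in wr_rates) {
      for (w in waits) {
        key <- sprintf("%s_%ghz_%dms", wr, f, round(w * 1000))
        run <- bench_pipeline(wait = w, rate = f, wiring = wr,
                              duration = duration, clock = clock,
                              source_fps = source_fps, seed = seed,
                              size = size)
        runs[[key]] <- run
        pred <- predicted_bench_rates(f, w, wiring = wr,
                                      source_fps = source_fps)
        for (pg in plugin_streams) {
          rt <- effective_rate(run, pg, warmup = warmup)
          wrt <- windowed_rates(run, pg, warmup = warmup)
          wsd <- if (length(wrt) > 1L) stats::sd(wrt) else 0
          ex <- execution_time_summary(run, pg)
          dl <- delay_to_input(run, pg, warmup = warmup)
          qs <- if (length(dl)) stats::quantile(dl, c(0.25, 0.5, 0.75))
                else rep(NA_real_, 3)
          rows[[length(rows) + 1L]] <- data.frame(
            wiring = wr, rate = f, wait = w, plugin = pg,
            rate_hz = rt, predicted_hz = pred[[pg]],
            rate_cell = sprintf("%.1f ± %.1f", mean(wrt), wsd),
            exec_mean_ms = ex$mean * 1000, exec_sd_ms = ex$sd * 1000,
            exec_cell = sprintf("%.1f ± %.1f", ex$mean * 1000,
                                ex$sd * 1000),
            delay_q25 = qs[1L], delay_median = qs[2L], delay_q75 = qs[3L],
            n_processed = ex$n,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(summary = do.call(rbind, rows), runs = runs,
       config = list(waits = waits, rates = rates, wiring = wiring,
                     duration = duration, clock = clock, warmup = warmup,
                     source_fps = source_fps, seed = seed))
}
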