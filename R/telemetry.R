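#' Telemetry
#'
#' Every completed task is recorded by the engine as one row: the plug-in's
#' stream name, the source frame id of the processed frame, the original
#' input-stream timestamp of that frame, the dispatch and completion
#' timestamps, and the execution time (completion minus dispatch). All
#' timestamps come from the engine clock (simulated or wall, never mixed).
#' Rate and delay statistics exclude a 2 s warm-up by default, since the
#' quantities of interest are steady-state behaviour.
#'
#' @name telemetry
NULL

get_records <- function(records) {
  if (inherits(records, "ps_run")) records$records else records
}

#' Execution-time summary for one plug-in
#'
#' @param records Telemetry data frame (or a `ps_run`).
#' @param plugin Plug-in stream name.
#' @return List with `mean`, `sd` (seconds) and `n`; `n = 0` and `NA`
#'   statistics when the plug-in has no records.
#' @export
execution_time_summary <- function(records, plugin) {
  records <- get_records(records)
  x <- records$exec_time[records$plugin == plugin]
  if (length(x) == 0L) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Measured effective frame rate
#'
#' Completed-task count over a steady-state window: tasks completing in
#' `(warmup, warmup + window]` divided by `window`.
#'
#' @param records Telemetry data frame (or a `ps_run`).
#' @param plugin Plug-in stream name.
#' @param window Window length in seconds; default runs to the end of the
#'   recorded session.
#' @param warmup Seconds excluded at the start (default 2).
#' @return Effective rate in Hz.
#' @export
effective_rate <- function(records, plugin, window = NULL, warmup = 2) {
  records <- get_records(records)
  run_end <- if (nrow(records)) max(records$complete_time) else 0
  if (is.null(window)) window <- run_end - warmup
  if (warmup + window > run_end + 1e-9) {
    stop("window of ", window, " s (after ", warmup,
         " s warm-up) exceeds the recorded run of ", round(run_end, 3), " s",
         call. = FALSE)
  }
  ct <- records$complete_time[records$plugin == plugin]
  sum(ct > warmup & ct <= warmup + window) / window
}

#' Per-frame delay relative to the input stream
#'
#' For each processed frame: completion timestamp minus the timestamp at
#' which that frame was emitted on the input stream (tracked through the
#' frame id as the frame travels down the pipeline).
#'
#' @param records Telemetry data frame (or a `ps_run`).
#' @param plugin Plug-in stream name.
#' @param warmup Seconds excluded at the start (default 2).
#' @return Numeric vector of delays in seconds, with a `skipped` attribute
#'   counting records whose input timestamp was unavailable.
#' @export
delay_to_input <- function(records, plugin, warmup = 2) {
  records <- get_records(records)
  r <- records[records$plugin == plugin & records$complete_time > warmup, ]
  ok <- is.finite(r$input_time)
  structure(r$complete_time[ok] - r$input_time[ok],
            skipped = sum(!ok))
}

# Effective rate in consecutive sub-windows, for a mean +/- sd shaped like a
# long-run report.
windowed_rates <- function(records, plugin, subwindow = 10, warmup = 2) {
  records <- get_records(records)
  run_end <- max(records$complete_time)
  starts <- seq(warmup, max(warmup, run_end - subwindow), by = subwindow)
  ct <- records$complete_time[records$plugin == plugin]
  vapply(starts, function(s) sum(ct > s & ct <= s + subwindow) / subwindow,
         numeric(1))
}

#' Shape benchmark telemetry into report tables
#'
#' Takes the long data frame produced by [run_delay_grid()] and pivots it
#' into one of the benchmark report layouts:
#' * `"table2"` -- execution time (ms, `mean +/- sd`) per plug-in, one column
#'   per wait level;
#' * `"table3"` -- effective frame rate (Hz, `mean +/- sd` over 10 s
#'   sub-windows) per configuration x plug-in, one column per wait level;
#' * `"fig3"` -- long table of delay-to-input summaries (median and
#'   quartiles) per plug-in x requested rate x wait, for delay-vs-rate
#'   curves.
#'
#' @param grid Result of [run_delay_grid()].
#' @param layout `"table2"`, `"table3"` or `"fig3"`.
#' @param file Optional path; when given the table is also written as CSV.
#' @return A data frame in the requested layout.
#' @export
telemetry_report <- function(grid, layout = c("table3", "table2", "fig3"),
                             file = NULL) {
  layout <- match.arg(layout)
  s <- grid$summary
  out <- switch(layout,
    table2 = pivot_cells(s, "exec_cell", "Time (ms)"),
    table3 = pivot_cells(s, "rate_cell", "Rate (Hz)"),
    fig3 = s[order(s$wiring, s$rate, s$plugin, s$wait),
             c("wiring", "rate", "plugin", "wait", "delay_q25", "delay_median",
               "delay_q75")])
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

pivot_cells <- function(s, cell_col, what) {
  waits <- sort(unique(s$wait))
  confs <- unique(s[, c("wiring", "rate", "plugin")])
  rows <- lapply(seq_len(nrow(confs)), function(i) {
    cf <- confs[i, ]
    row <- data.frame(quantity = what, wiring = cf$wiring, rate_hz = cf$rate,
                      plugin = cf$plugin, stringsAsFactors = FALSE)
    for (w in waits) {
      cell <- s[s$wiring == cf$wiring & s$rate == cf$rate &
                  s$plugin == cf$plugin & s$wait == w, cell_col]
      row[[sprintf("wait_%dms", round(w * 1000))]] <-
        if (length(cell)) cell else NA_character_
    }
    row
  })
  if (length(rows) == 0L) {
    return(data.frame(quantity = character(0), wiring = character(0),
                      rate_hz = numeric(0), plugin = character(0)))
  }
  do.call(rbind, rows)
}

#' Plot delay-to-input against requested frame rate
#'
#' Draws the delay curves a benchmark grid produces: one line per plug-in
#' and wait level, median delay (seconds) against requested rate. Requires
#' ggplot2.
#'
#' @param grid Result of [run_delay_grid()] (sequential wiring).
#' @return A ggplot object.
#' @export
plot_delay_curves <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_delay_curves requires ggplot2", call. = FALSE)
  }
  s <- grid$summary
  s$wait_ms <- factor(round(s$wait * 1000))
  ggplot2::ggplot(s, ggplot2::aes(x = rate, y = delay_median,
                                  colour = plugin, linetype = wait_ms)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "requested frame rate (Hz)",
                  y = "median delay to input (s)",
                  colour = "plug-in", linetype = "wait (ms)")
}
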