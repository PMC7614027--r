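#' Pipeline engine
#'
#' The engine runs a wired pipeline of plug-ins as a timed event system with
#' three event kinds: source emissions, periodic per-plugin ticks, and worker
#' completions. Two clocks are available:
#'
#' * `"simulated"` -- time advances only through events, so runs are exactly
#'   reproducible and a 15-minute session executes in seconds. Worker
#'   completions are scheduled at dispatch time plus the task's modelled
#'   execution time, which represents each plug-in's worker running
#'   concurrently on its own thread.
#' * `"wall"` -- events are paced against the real clock and tasks execute
#'   inline (an artificial-delay task really sleeps). Ticks that come up
#'   stale -- late because the loop was blocked by a worker -- are skipped,
#'   which is exactly the behaviour of a periodic timer firing while the
#'   worker is busy.
#'
#' At equal timestamps under the simulated clock, frame arrivals are
#' processed before worker completions, and completions before ticks.
#'
#' @name engine
NULL

ps_clock <- function(mode = c("simulated", "wall")) {
  mode <- match.arg(mode)
  ck <- new.env(parent = emptyenv())
  ck$mode <- mode
  ck$now <- 0
  ck$origin <- NA_real_
  ck
}

clock_now <- function(ck) {
  if (ck$mode == "wall") as.numeric(Sys.time()) - ck$origin else ck$now
}

# --- telemetry accumulator -------------------------------------------------

new_recorder <- function() {
  rec <- new.env(parent = emptyenv())
  rec$n <- 0L
  rec$cap <- 256L
  rec$plugin <- character(256)
  rec$frame_id <- integer(256)
  rec$input_time <- numeric(256)
  rec$arrival_time <- numeric(256)
  rec$dispatch_time <- numeric(256)
  rec$complete_time <- numeric(256)
  rec$exec_time <- numeric(256)
  rec
}

rec_add <- function(rec, plugin, frame_id, input_time, arrival_time,
                    dispatch_time, complete_time) {
  n <- rec$n + 1L
  if (n > rec$cap) {
    rec$cap <- rec$cap * 2L
    length(rec$plugin) <- rec$cap
    length(rec$frame_id) <- rec$cap
    length(rec$input_time) <- rec$cap
    length(rec$arrival_time) <- rec$cap
    length(rec$dispatch_time) <- rec$cap
    length(rec$complete_time) <- rec$cap
    length(rec$exec_time) <- rec$cap
  }
  rec$plugin[n] <- plugin
  rec$frame_id[n] <- frame_id
  rec$input_time[n] <- input_time
  rec$arrival_time[n] <- if (is.null(arrival_time)) NA_real_ else arrival_time
  rec$dispatch_time[n] <- dispatch_time
  rec$complete_time[n] <- complete_time
  rec$exec_time[n] <- complete_time - dispatch_time
  rec$n <- n
  invisible(rec)
}

rec_df <- function(rec) {
  i <- seq_len(rec$n)
  data.frame(plugin = rec$plugin[i], frame_id = rec$frame_id[i],
              input_time = rec$input_time[i],
              arrival_time = rec$arrival_time[i],
              dispatch_time = rec$dispatch_time[i],
              complete_time = rec$complete_time[i],
              exec_time = rec$exec_time[i],
              stringsAsFactors = FALSE)
}

# --- engine ----------------------------------------------------------------

new_engine <- function(plugins, clock = "simulated", duration = Inf,
                       quiet = TRUE) {
  en <- new.env(parent = emptyenv())
  en$plugins <- plugins
  en$clock <- ps_clock(clock)
  en$queue <- new_event_queue(quantize = en$clock$mode == "simulated")
  en$duration <- duration
  en$recorder <- new_recorder()
  en$registry <- assign_stream_names(plugins)
  en$sources_active <- 0L
  en$stop <- FALSE
  en$quiet <- quiet
  en$poll <- NULL          # optional callback, run between events (wall mode)
  en
}

engine_log <- function(en, ...) {
  if (!isTRUE(en$quiet)) message(...)
  invisible(NULL)
}

# Activation: plug-ins in pipeline order (configuration flows downstream
# before any frame does), sources started last so no frame can precede a
# consumer's activation.
engine_activate <- function(en) {
  for (pl in en$plugins) {
    if (!pl$is_input) {
      pl$active <- TRUE
      if (is.function(pl$on_activate)) pl$on_activate(pl, en)
      pl$tick_anchor <- 0
      schedule_tick(en, pl, 1L)
    }
  }
  for (pl in en$plugins) {
    if (pl$is_input) {
      pl$active <- TRUE
      if (is.function(pl$on_activate)) pl$on_activate(pl, en)
      pl$emit_index <- 0L
      en$sources_active <- en$sources_active + 1L
      eq_push(en$queue, 0, EV_EMIT, list(kind = "emit", i = pl$position))
    }
  }
  invisible(en)
}

schedule_tick <- function(en, pl, k) {
  t <- pl$tick_anchor + k * pl$period
  if (t <= en$duration) {
    pl$tick_index <- k
    eq_push(en$queue, t, EV_TICK, list(kind = "tick", i = pl$position))
    TRUE
  } else FALSE
}

deliver <- function(en, from_pos, frame) {
  plugins <- en$plugins
  n <- length(plugins)
  frame$arrival_time <- en$clock$now
  if (from_pos >= n) return(invisible(NULL))
  for (j in (from_pos + 1L):n) {
    pl <- plugins[[j]]
    sched_receive(pl, frame, accepts_frame(pl, frame))
  }
  invisible(NULL)
}

handle_emit <- function(en, ev) {
  pl <- en$plugins[[ev$payload$i]]
  t <- ev$time
  nx <- pl$fn_next(pl, t)
  if (is.null(nx)) {
    pl$source_done <- TRUE
    en$sources_active <- en$sources_active - 1L
    engine_log(en, pl$display, ": end of stream after ", pl$emit_index,
               " frame(s)")
    return(invisible(NULL))
  }
  fr <- make_frame(nx$pixels, stream_name = pl$out_stream,
                   frame_id = pl$emit_index, acq_time = t, fps = pl$fps)
  if (!is.null(nx$meta)) for (k in names(nx$meta)) set_frame_meta(fr, k, nx$meta[[k]])
  pl$emit_index <- pl$emit_index + 1L
  deliver(en, pl$position, fr)
  t_next <- pl$t0 + pl$emit_index / pl$fps
  if (t_next <= en$duration) {
    eq_push(en$queue, t_next, EV_EMIT, list(kind = "emit", i = pl$position))
  } else {
    pl$source_done <- TRUE
    en$sources_active <- en$sources_active - 1L
  }
  invisible(NULL)
}

handle_tick <- function(en, ev, stale = FALSE) {
  pl <- en$plugins[[ev$payload$i]]
  if (en$clock$mode == "wall") {
    # re-anchor to the real-time tick grid, like a wall-clock timer: the
    # next tick is the first grid point strictly after now
    now <- max(en$clock$now, ev$time)
    k <- max(pl$tick_index + 1L,
             as.integer(floor((now - pl$tick_anchor) / pl$period + 1e-9)) + 1L)
    schedule_tick(en, pl, k)
  } else {
    schedule_tick(en, pl, pl$tick_index + 1L)
  }
  if (stale) return(invisible(NULL))  # timer fired while the loop was blocked
  fr <- sched_take(pl)
  if (is.null(fr)) return(invisible(NULL))
  dispatch(en, pl, fr, ev$time)
  invisible(NULL)
}

dispatch <- function(en, pl, frame, t) {
  pl$busy <- TRUE
  view <- frame_view(frame)
  if (en$clock$mode == "simulated") {
    out <- tryCatch(pl$fn_task(pl, view, en),
                    error = function(e) structure(list(error = e), class = "ps_task_error"))
    dur <- pl$fn_exec_time(pl, frame)
    pl$inflight <- list(out = out, frame_id = frame$frame_id,
                        input_time = frame$input_time, dispatch = t,
                        arrival = frame$arrival_time)
    eq_push(en$queue, t + dur, EV_COMPLETE, list(kind = "complete", i = pl$position))
  } else {
    t_disp <- clock_now(en$clock)
    pl$last_dispatch_wall <- t_disp
    out <- tryCatch(pl$fn_task(pl, view, en),
                    error = function(e) structure(list(error = e), class = "ps_task_error"))
    pl$inflight <- list(out = out, frame_id = frame$frame_id,
                        input_time = frame$input_time, dispatch = t_disp,
                        arrival = frame$arrival_time)
    t_done <- clock_now(en$clock)
    pl$last_complete_wall <- t_done
    handle_complete(en, list(time = t_done, payload = list(i = pl$position)))
  }
  invisible(NULL)
}

handle_complete <- function(en, ev) {
  pl <- en$plugins[[ev$payload$i]]
  inf <- pl$inflight
  pl$inflight <- NULL
  if (inherits(inf$out, "ps_task_error")) {
    sched_complete(pl, failed = TRUE)
    engine_log(en, pl$display, ": worker error, frame ", inf$frame_id,
               " dropped (", conditionMessage(inf$out$error), ")")
    return(invisible(NULL))
  }
  sched_complete(pl)
  rec_add(en$recorder, pl$out_stream, inf$frame_id, inf$input_time,
          inf$arrival, inf$dispatch, ev$time)
  out <- inf$out
  if (inherits(out, "stream_frame")) {
    out$stream_name <- pl$out_stream
    deliver(en, pl$position, out)
  }
  invisible(NULL)
}

engine_quiescent <- function(en) {
  if (en$sources_active > 0L) return(FALSE)
  for (pl in en$plugins) {
    if (isTRUE(pl$busy) || n_pending(pl) > 0L) return(FALSE)
  }
  !eq_has_work(en$queue)
}

engine_run <- function(en) {
  wall <- en$clock$mode == "wall"
  if (wall) en$clock$origin <- as.numeric(Sys.time())
  n_ev <- 0L
  repeat {
    if (isTRUE(en$stop)) break
    ev <- eq_pop(en$queue)
    if (is.null(ev)) break
    if (ev$time > en$duration) break
    stale <- FALSE
    if (wall) {
      dt <- ev$time - clock_now(en$clock)
      if (dt > 0) Sys.sleep(dt)
      else if (ev$prio == EV_TICK) {
        # A timer firing while its worker is busy drops the tick. Inline
        # execution means such ticks are only observed after the blocking
        # task returns: a tick processed well past its scheduled time is
        # stale. The tolerance absorbs normal sleep jitter.
        p <- en$plugins[[ev$payload$i]]$period
        if (-dt > min(0.01, 0.25 * p)) stale <- TRUE
      }
      en$clock$now <- clock_now(en$clock)
    } else {
      en$clock$now <- ev$time
    }
    switch(ev$payload$kind,
           emit = handle_emit(en, ev),
           tick = handle_tick(en, ev, stale = stale),
           complete = handle_complete(en, ev))
    n_ev <- n_ev + 1L
    if (!is.null(en$poll) && (wall || n_ev %% 256L == 0L)) en$poll(en)
    if (en$sources_active == 0L && engine_quiescent(en)) break
  }
  invisible(en)
}

#' Run a wired pipeline
#'
#' Activates the plug-ins (pipeline order, sources last) and runs the event
#' loop until `duration` engine-seconds have elapsed, or every source has
#' finished and all workers have drained.
#'
#' @param plugins List of plug-in objects from [instantiate_plugin()] /
#'   [build_pipeline()].
#' @param duration Session length in engine-clock seconds.
#' @param clock `"simulated"` (deterministic, faster than real time) or
#'   `"wall"`.
#' @param quiet Suppress per-event log messages.
#' @return A `ps_run` object: `records` (telemetry data frame, one row per
#'   completed task), `counters` (per-plugin received / processed / dropped /
#'   pending), `plugins`, `registry`, `duration`, `clock`.
#' @examples
#' pl <- build_pipeline("framesource>pythonalgorithm>gui",
#'                      list(framesource = list(duration = 2)))
#' run <- run_pipeline(pl, duration = 2)
#' run$counters
#' @export
run_pipeline <- function(plugins, duration = Inf, clock = "simulated",
                         quiet = TRUE) {
  en <- new_engine(plugins, clock = clock, duration = duration, quiet = quiet)
  engine_activate(en)
  engine_run(en)
  ps_run(en)
}

ps_run <- function(en) {
  counters <- do.call(rbind, lapply(en$plugins, function(pl) {
    data.frame(plugin = pl$token, stream = if (is.null(pl$out_stream)) NA_character_ else pl$out_stream,
               is_input = pl$is_input,
               emitted = if (pl$is_input) pl$emit_index else NA_integer_,
               received = pl$received, processed = pl$processed,
               dropped = pl$dropped, pending = n_pending(pl),
               busy = isTRUE(pl$busy),
               stringsAsFactors = FALSE)
  }))
  structure(list(records = rec_df(en$recorder), counters = counters,
                 plugins = en$plugins, registry = en$registry,
                 duration = en$duration, clock = en$clock$mode,
                 engine = en),
            class = "ps_run")
}

#' @export
print.ps_run <- function(x, ...) {
  cat("<ps_run> clock=", x$clock, "  ", nrow(x$records),
      " completed task(s)\n", sep = "")
  print(x$counters, row.names = FALSE)
  invisible(x)
}
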