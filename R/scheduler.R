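#' Latest-frame scheduling
#'
#' Each plug-in owns one worker: at most one task is in flight per plug-in,
#' and frame forwarding through the pipeline is never blocked by any worker.
#' A plug-in checks for its latest accepted input frame periodically, at its
#' requested frame rate `f` (tick period `p = 1/f`, default `f = 20` Hz).
#' Frames that arrive while an earlier frame is still pending replace it and
#' are counted as dropped, so a slow task trades frame rate for zero temporal
#' drift: the frame dispatched at any tick is always the most recent one.
#' Process-all mode (`processall`) overrides dropping with an unbounded FIFO
#' for plug-ins, such as file writers, that need every frame.
#'
#' @name scheduling
NULL

# Per-plugin scheduler state lives on the plug-in environment itself:
#   busy (logical), pending (<=1 stream_frame), fifo (list, process-all mode),
#   received / processed / dropped counters, period, tick_index, inflight.

sched_init <- function(pl) {
  pl$busy <- FALSE
  pl$pending <- NULL
  pl$fifo <- list()
  pl$received <- 0L
  pl$processed <- 0L
  pl$dropped <- 0L
  pl$tick_index <- 0L
  pl$inflight <- NULL
  pl$active <- FALSE
  pl$last_dispatch_wall <- -Inf
  pl$last_complete_wall <- -Inf
  invisible(pl)
}

# Frame delivered to a plug-in. Forwarding further downstream is the engine's
# job and happens unconditionally; this only handles admission.
sched_receive <- function(pl, frame, accepted) {
  if (!accepted) return(invisible(pl))
  if (!isTRUE(pl$active)) {
    warning("plug-in ", pl$token, " received a frame before activation; discarded",
            call. = FALSE)
    return(invisible(pl))
  }
  pl$received <- pl$received + 1L
  if (isTRUE(pl$drop_disabled)) {
    pl$fifo[[length(pl$fifo) + 1L]] <- frame
    if (length(pl$fifo) == 1000L) {
      warning("plug-in ", pl$token, " has 1000 frames queued in process-all mode",
              call. = FALSE)
    }
  } else {
    if (!is.null(pl$pending)) pl$dropped <- pl$dropped + 1L
    pl$pending <- frame
  }
  invisible(pl)
}

# Periodic input check: returns the frame to dispatch, or NULL for a no-op
# (worker busy, or nothing pending).
sched_take <- function(pl) {
  if (isTRUE(pl$busy)) return(NULL)
  if (isTRUE(pl$drop_disabled)) {
    if (length(pl$fifo) == 0L) return(NULL)
    fr <- pl$fifo[[1L]]
    pl$fifo[[1L]] <- NULL
    return(fr)
  }
  fr <- pl$pending
  pl$pending <- NULL
  fr
}

# Scheduler bookkeeping at completion; output emission is the engine's job.
sched_complete <- function(pl, failed = FALSE) {
  pl$busy <- FALSE
  if (failed) pl$dropped <- pl$dropped + 1L else pl$processed <- pl$processed + 1L
  invisible(pl)
}

n_pending <- function(pl) {
  if (isTRUE(pl$drop_disabled)) length(pl$fifo) else as.integer(!is.null(pl$pending))
}

#' Steady-state effective frame rate under the tick/drop law
#'
#' A plug-in ticking at `f` Hz (period `p = 1/f`) whose task takes a constant
#' `T` seconds dispatches a new frame at the first tick at or after each
#' completion, so in steady state it processes one frame every
#' `ceiling(T / p)` ticks. The effective rate is therefore
#' `f / ceiling(T / p)` (and `f` itself when `T <= p`), assuming a fresh
#' frame is always available (input stream faster than the processed rate).
#'
#' @param f Requested frame rate in Hz (`> 0`).
#' @param T Constant task execution time in seconds (`>= 0`).
#' @return Steady-state processed frames per second, in Hz.
#' @examples
#' predicted_effective_rate(20, 0.125)  # 20/3 = 6.67 Hz
#' predicted_effective_rate(10, 0.225)  # 10/3 = 3.33 Hz
#' @export
predicted_effective_rate <- function(f, T) {
  stopifnot(is.numeric(f), f > 0, is.numeric(T), T >= 0)
  if (T <= 0) return(f)
  # guard the ratio against float error: a task time equal to a whole number
  # of periods completes exactly at a tick, which dispatches the next frame
  f / max(1, ceiling(T * f - 1e-9))
}
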