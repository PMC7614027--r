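# Binary min-heap of timed events, ordered by (time, priority, insertion seq).
# Simulated-clock times are quantised to integer nanoseconds before insertion
# so that coinciding ticks, arrivals and completions compare exactly and the
# documented ordering (arrival < completion < tick at equal time) is
# deterministic rather than at the mercy of floating-point jitter.

EV_EMIT <- 0L      # source emission / frame arrival
EV_COMPLETE <- 1L  # worker completion
EV_TICK <- 2L      # periodic input check

new_event_queue <- function(quantize = TRUE) {
  q <- new.env(parent = emptyenv())
  q$time <- numeric(64)    # nanoseconds (quantized) or raw seconds
  q$prio <- integer(64)
  q$seq <- integer(64)
  q$payload <- vector("list", 64)
  q$n <- 0L
  q$counter <- 0L
  q$quantize <- quantize
  q
}

eq_size <- function(q) q$n

eq_less <- function(q, a, b) {
  if (q$time[a] != q$time[b]) return(q$time[a] < q$time[b])
  if (q$prio[a] != q$prio[b]) return(q$prio[a] < q$prio[b])
  q$seq[a] < q$seq[b]
}

eq_swap <- function(q, a, b) {
  tt <- q$time[a]; q$time[a] <- q$time[b]; q$time[b] <- tt
  tp <- q$prio[a]; q$prio[a] <- q$prio[b]; q$prio[b] <- tp
  ts <- q$seq[a]; q$seq[a] <- q$seq[b]; q$seq[b] <- ts
  tl <- q$payload[[a]]; q$payload[[a]] <- q$payload[[b]]; q$payload[[b]] <- tl
}

eq_push <- function(q, time, prio, payload) {
  if (q$quantize) time <- round(time * 1e9)
  n <- q$n + 1L
  if (n > length(q$time)) {
    len <- 2L * length(q$time)
    q$time <- c(q$time, numeric(len - length(q$time)))
    q$prio <- c(q$prio, integer(len - length(q$prio)))
    q$seq <- c(q$seq, integer(len - length(q$seq)))
    length(q$payload) <- len
  }
  q$counter <- q$counter + 1L
  q$time[n] <- time; q$prio[n] <- prio; q$seq[n] <- q$counter
  q$payload[[n]] <- payload
  q$n <- n
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (eq_less(q, i, p)) { eq_swap(q, i, p); i <- p } else break
  }
  invisible(q)
}

eq_pop <- function(q) {
  n <- q$n
  if (n == 0L) return(NULL)
  out <- list(time = if (q$quantize) q$time[1L] / 1e9 else q$time[1L],
              prio = q$prio[1L], payload = q$payload[[1L]])
  eq_swap(q, 1L, n)
  q$payload[n] <- list(NULL)
  q$n <- n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L; m <- i
    if (l <= q$n && eq_less(q, l, m)) m <- l
    if (r <= q$n && eq_less(q, r, m)) m <- r
    if (m == i) break
    eq_swap(q, i, m); i <- m
  }
  out
}

eq_peek_time <- function(q) {
  if (q$n == 0L) return(Inf)
  if (q$quantize) q$time[1L] / 1e9 else q$time[1L]
}

# Any non-tick event left? Used for quiescence detection at end of stream.
eq_has_work <- function(q) {
  n <- q$n
  n > 0L && any(q$prio[seq_len(n)] != EV_TICK)
}
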