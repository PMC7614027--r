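#' Stream naming and routing
#'
#' Every plug-in produces one named stream. Non-input plug-ins produce a
#' stream named after the plug-in (display name lowercased, non-alphanumerics
#' stripped); input plug-ins produce `'Input'`, and when several input
#' plug-ins appear in one pipeline the second, third, ... produce `'Input1'`,
#' `'Input2'`, ... in order of appearance. Every non-input plug-in subscribes
#' to exactly one stream (default `'Input'`) and one layer of it (default
#' `-1`, the last layer).
#'
#' @name streams
NULL

#' Normalize a plug-in display name into a stream token
#'
#' Lowercases and strips all non-alphanumeric characters, so
#' `"Python Algorithm"` becomes `"pythonalgorithm"`. The mapping is
#' idempotent and deterministic; it is also how command-line prefixes
#' (`--pythonalgorithm_delay`) are matched to plug-ins.
#'
#' @param display_name Non-empty plug-in display name.
#' @return Lowercase token.
#' @export
normalize_plugin_name <- function(display_name) {
  if (!is.character(display_name) || length(display_name) != 1L ||
      is.na(display_name) || !nzchar(display_name)) {
    stop("plug-in name must be a non-empty string", call. = FALSE)
  }
  token <- tolower(gsub("[^[:alnum:]]", "", display_name))
  if (!nzchar(token)) {
    stop("plug-in name ", sQuote(display_name),
         " normalizes to an empty token", call. = FALSE)
  }
  token
}

#' Assign output stream names and default subscriptions
#'
#' Walks the pipeline in order. The first input plug-in's output stream is
#' `'Input'`; the k-th subsequent input plug-in's is `'Input<k>'`. Each
#' non-input plug-in's output stream is its normalized name; a collision
#' between two non-input plug-ins of the same type is resolved with a
#' deterministic `-2`, `-3`, ... suffix. Every non-input plug-in gets the
#' default subscription (`'Input'`, layer `-1`) unless it already carries a
#' configured one.
#'
#' @param plugins Ordered list of plug-in objects (see [instantiate_plugin()])
#'   or bare lists with `display`, `is_input` and optionally `sub_stream`,
#'   `sub_layer` fields.
#' @return A `stream_registry`: list with `producers` (stream name ->
#'   pipeline position) and `subscriptions` (per plug-in list of
#'   `stream`/`layer`). Plug-in objects passed as environments are updated in
#'   place with their `out_stream`, `sub_stream` and `sub_layer`.
#' @export
assign_stream_names <- function(plugins) {
  producers <- character(0)
  subs <- vector("list", length(plugins))
  n_inputs <- 0L
  for (i in seq_along(plugins)) {
    pl <- plugins[[i]]
    if (isTRUE(pl$is_input)) {
      out <- if (n_inputs == 0L) "Input" else paste0("Input", n_inputs)
      n_inputs <- n_inputs + 1L
      sub <- NULL
    } else {
      out <- normalize_plugin_name(pl$display)
      if (out %in% names(producers)) {
        k <- 2L
        while (paste0(out, "-", k) %in% names(producers)) k <- k + 1L
        out <- paste0(out, "-", k)
      }
      sub <- list(stream = if (is.null(pl$sub_stream)) "Input" else pl$sub_stream,
                  layer = if (is.null(pl$sub_layer)) -1L else as.integer(pl$sub_layer))
    }
    producers[[out]] <- i
    subs[[i]] <- sub
    if (is.environment(pl)) {
      pl$out_stream <- out
      if (!is.null(sub)) {
        pl$sub_stream <- sub$stream
        pl$sub_layer <- sub$layer
      }
      pl$position <- i
    }
  }
  structure(list(producers = producers, subscriptions = subs),
            class = "stream_registry")
}

#' Does a plug-in accept this frame?
#'
#' Pure predicate: `TRUE` iff the frame's stream equals the plug-in's
#' subscribed stream. Acceptance only controls whether the frame enters the
#' plug-in's scheduler; the frame is forwarded to downstream plug-ins
#' regardless.
#'
#' @param plugin Plug-in object with a `sub_stream` field (input plug-ins
#'   accept nothing).
#' @param frame A `stream_frame`.
#' @export
accepts_frame <- function(plugin, frame) {
  if (isTRUE(plugin$is_input) || is.null(plugin$sub_stream)) return(FALSE)
  identical(frame$stream_name, plugin$sub_stream)
}

#' Re-subscribe a plug-in at run time
#'
#' Changes the accepted stream and/or layer. The change is atomic with
#' respect to frame delivery: frames already pending keep flowing, and the
#' new subscription applies from the next delivered frame on. Plug-ins whose
#' task keeps per-stream state (e.g. the temporal-averaging classifier) reset
#' that state when the stream changes.
#'
#' @param plugin Plug-in environment.
#' @param stream New accepted stream name (or `NULL` to keep).
#' @param layer New accepted layer index (or `NULL` to keep).
#' @export
resubscribe <- function(plugin, stream = NULL, layer = NULL) {
  if (isTRUE(plugin$is_input)) {
    stop("input plug-ins do not subscribe to streams", call. = FALSE)
  }
  if (!is.null(stream) && !identical(stream, plugin$sub_stream)) {
    plugin$sub_stream <- stream
    if (is.function(plugin$on_stream_change)) plugin$on_stream_change(plugin)
  }
  if (!is.null(layer)) plugin$sub_layer <- as.integer(layer)
  invisible(plugin)
}
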