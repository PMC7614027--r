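#' Layered stream frames
#'
#' A `stream_frame` is the record that travels through a pipeline: an ordered
#' stack of 2D pixel layers that all share the same height and width, plus a
#' string-keyed metadata map, the name of the stream the frame currently
#' belongs to, a per-source monotonically increasing frame id, the acquisition
#' timestamp (engine-clock seconds) and the source frame rate.
#'
#' Frames are environments, so layer appends mutate the frame in place and
#' layer pixel buffers are shared -- never copied -- between the plug-ins that
#' hold a reference to the frame. Plug-ins append their result as a new layer
#' rather than emitting a fresh image, which keeps the association between an
#' input frame and everything computed from it, even when downstream plug-ins
#' run at different rates.
#'
#' @name stream_frame
NULL

#' Create a one-layer stream frame
#'
#' @param pixels Non-empty 2D numeric matrix. Sources conventionally emit
#'   8-bit grayscale intensities in `[0, 255]`; processing layers may be float.
#' @param stream_name Name of the stream the frame is emitted on.
#' @param frame_id Non-negative integer, strictly increasing per source.
#' @param acq_time Acquisition time in engine-clock seconds.
#' @param fps Source frame rate in Hz.
#' @return A `stream_frame` with one layer and the reserved metadata keys
#'   (`stream`, `frame_id`, `acq_time`, `fps`) populated.
#' @examples
#' f <- make_frame(matrix(0, 4, 4), "Input", 0L, 0, 30)
#' n_layers(f)
#' frame_meta(f, "stream")
#' @export
make_frame <- function(pixels, stream_name = "Input", frame_id = 0L,
                       acq_time = 0, fps = 30) {
  if (!is.matrix(pixels) || any(dim(pixels) == 0L)) {
    stop("pixels must be a non-empty 2D matrix, got dimensions [",
         paste(if (is.matrix(pixels)) dim(pixels) else length(pixels),
               collapse = "x"), "]", call. = FALSE)
  }
  f <- new.env(parent = emptyenv())
  f$layers <- list(pixels)
  f$meta <- list(stream = stream_name, frame_id = as.integer(frame_id),
                 acq_time = acq_time, fps = fps)
  f$stream_name <- stream_name
  f$frame_id <- as.integer(frame_id)
  f$acq_time <- acq_time
  # provenance of the original source emission, preserved across re-emission
  f$input_time <- acq_time
  f$source_fps <- fps
  class(f) <- "stream_frame"
  f
}

#' Append a result layer to a frame
#'
#' Appends `result` as a new last layer. Existing layer buffers are untouched
#' and not copied; the same frame object is returned, mutated in place.
#'
#' @param frame A `stream_frame`.
#' @param result 2D matrix with the same spatial dimensions as the frame.
#' @return `frame`, with one more layer.
#' @export
add_layer <- function(frame, result) {
  stopifnot(inherits(frame, "stream_frame"))
  d0 <- dim(frame$layers[[1L]])
  if (!is.matrix(result) || !identical(dim(result), d0)) {
    stop("layer dimension mismatch: frame is [", paste(d0, collapse = "x"),
         "], result is [",
         paste(if (is.matrix(result)) dim(result) else length(result),
               collapse = "x"), "]", call. = FALSE)
  }
  frame$layers[[length(frame$layers) + 1L]] <- result
  invisible(frame)
}

#' Number of layers in a frame
#' @param frame A `stream_frame`.
#' @export
n_layers <- function(frame) length(frame$layers)

#' Extract a layer from a frame
#'
#' Layer indexing is 0-based with negative wrap-around, mirroring the
#' command-line convention where `-1` selects the last (most recently
#' appended) layer.
#'
#' @param frame A `stream_frame`.
#' @param index Integer in `[-L, L - 1]` for `L` layers; `-1` is the last.
#' @return The layer's pixel matrix (no copy is made on access).
#' @export
get_layer <- function(frame, index = -1L) {
  L <- length(frame$layers)
  i <- as.integer(index)
  if (is.na(i) || i < -L || i >= L) {
    stop("layer index ", index, " out of range: frame has ", L,
         " layer(s), valid indices are ", -L, "..", L - 1L, call. = FALSE)
  }
  if (i < 0L) i <- i + L
  frame$layers[[i + 1L]]
}

#' Read or write frame metadata
#'
#' Metadata values are restricted to scalars and strings so a frame can be
#' persisted losslessly as a JSON sidecar. Keys written by plug-ins are
#' conventionally namespaced by the plug-in's stream name
#' (e.g. `"standardplanedetection.label"`).
#'
#' @param frame A `stream_frame`.
#' @param key Metadata key.
#' @param value Scalar or string to store.
#' @return `frame_meta()` returns the stored value, or `NULL` when absent.
#' @export
frame_meta <- function(frame, key) frame$meta[[key]]

#' @rdname frame_meta
#' @export
set_frame_meta <- function(frame, key, value) {
  if (length(value) != 1L || !(is.numeric(value) || is.character(value) ||
                               is.logical(value))) {
    stop("metadata values must be length-1 scalars or strings", call. = FALSE)
  }
  frame$meta[[key]] <- value
  invisible(frame)
}

# Shallow view of a frame: shares every layer buffer and the metadata map but
# carries its own stream name, so a plug-in can relabel and extend its copy of
# the frame without perturbing siblings holding the original.
frame_view <- function(frame, stream_name = frame$stream_name) {
  v <- new.env(parent = emptyenv())
  v$layers <- frame$layers          # shallow: list cells reference same matrices
  v$meta <- frame$meta
  v$stream_name <- stream_name
  v$frame_id <- frame$frame_id
  v$acq_time <- frame$acq_time
  v$input_time <- frame$input_time
  v$source_fps <- frame$source_fps
  class(v) <- "stream_frame"
  v
}

#' @export
print.stream_frame <- function(x, ...) {
  d <- dim(x$layers[[1L]])
  cat(sprintf("<stream_frame> stream=%s id=%d  %d layer(s) of %dx%d  t=%.4fs\n",
              x$stream_name, x$frame_id, length(x$layers), d[1L], d[2L],
              x$acq_time))
  invisible(x)
}
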