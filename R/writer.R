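#' Frame persistence: PNG layers + JSON metadata sidecar
#'
#' The image file writer saves each frame as one PNG per requested layer plus
#' a JSON sidecar holding the metadata map, provenance (stream, frame id,
#' acquisition time, source rate) and the layer file names. Frames land
#' under `out_dir/<label>/`; the label can be switched at run time (the
#' interactive `set` command) to annotate frame sequences by class while
#' recording. 8-bit layers round-trip exactly through PNG.
#'
#' @name frame-writer
NULL

#' Write one frame to disk
#'
#' @param frame A `stream_frame`.
#' @param out_dir Output directory (created if needed).
#' @param label Subfolder label.
#' @param layers `"all"` or a single layer index (0-based, negatives wrap).
#' @return Invisibly, the sidecar path.
#' @export
write_frame <- function(frame, out_dir, label = "default", layers = "all") {
  dir <- file.path(out_dir, label)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%06d_%010.4f", frame$stream_name, frame$frame_id,
                  frame$acq_time)
  idx <- if (identical(layers, "all")) seq_len(n_layers(frame)) - 1L
         else as.integer(layers)
  files <- character(length(idx))
  for (j in seq_along(idx)) {
    x <- get_layer(frame, idx[j])
    # sources emit 8-bit [0,255]; float layers (e.g. masks in [0,1]) are
    # saved on their own scale
    scale <- if (max(x) > 1) 255 else 1
    files[j] <- sprintf("%s_L%d.png", stem, idx[j])
    png::writePNG(pmin(pmax(x / scale, 0), 1), file.path(dir, files[j]))
  }
  sidecar <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(stream = frame$stream_name, frame_id = frame$frame_id,
         acq_time = frame$acq_time, fps = frame$source_fps,
         height = nrow(get_layer(frame, 0L)), width = ncol(get_layer(frame, 0L)),
         layer_files = as.list(files), layer_indices = as.list(idx),
         layer_scales = as.list(vapply(idx, function(i)
           if (max(get_layer(frame, i)) > 1) 255 else 1, numeric(1))),
         metadata = frame$meta),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Reload a saved frame from its JSON sidecar
#'
#' Reconstructs the layers (on their original intensity scale) and metadata
#' written by [write_frame()].
#'
#' @param sidecar Path to the `.json` sidecar.
#' @return A `stream_frame`.
#' @export
read_saved_frame <- function(sidecar) {
  info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  layers <- lapply(seq_along(info$layer_files), function(j) {
    px <- png::readPNG(file.path(dir, info$layer_files[[j]]))
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    round(px * 255) / 255 * info$layer_scales[[j]]
  })
  f <- make_frame(layers[[1L]], stream_name = info$stream,
                  frame_id = info$frame_id, acq_time = info$acq_time,
                  fps = info$fps)
  if (length(layers) > 1L) for (j in 2:length(layers)) add_layer(f, layers[[j]])
  f$meta <- info$metadata
  f
}
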