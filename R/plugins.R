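#' Built-in plug-ins
#'
#' The package ships eight plug-ins. Sources: a file manager (folder of
#' images played back at a given rate), a video manager (multi-page TIFF,
#' image folder or synthetic stream spec), and a synthetic frame source (the
#' stand-in for a hardware frame grabber). Processing: the Python Algorithm
#' (Gaussian blur, plus an optional artificial wait used by the benchmark
#' harness), the Cpp Algorithm (binary threshold), and the Standard plane
#' detection plug-in (deterministic mock classifier with temporal score
#' averaging). Sinks: an image file writer (PNG per layer plus JSON metadata
#' sidecar) and a headless display sink.
#'
#' Every plug-in understands the universal parameters `stream`, `layer`,
#' `framerate`, `time`, `verbose` and `processall`, set on the command line
#' as `--<pluginname>_<param> <value>`.
#'
#' @name builtin-plugins
NULL

#' Declare a plug-in parameter
#'
#' @param type `"numeric"`, `"integer"` or `"character"`.
#' @param default Default value (`NULL` for "required, no default").
#' @param help One-line description shown to plug-in users.
#' @return Parameter definition for [plugin_descriptor()].
#' @export
plugin_param <- function(type, default, help) {
  list(type = type, default = default, help = help)
}

universal_processor_params <- function(drop_disabled = FALSE) {
  list(
    stream = plugin_param("character", NULL, "accepted input stream name"),
    layer = plugin_param("integer", -1L, "accepted layer of the input stream (-1 = last)"),
    framerate = plugin_param("numeric", 20, "requested tick rate in Hz"),
    time = plugin_param("integer", 0L, "1 to log worker execution times"),
    verbose = plugin_param("integer", 0L, "1 for verbose logging"),
    processall = plugin_param("integer", as.integer(drop_disabled),
                              "1 to queue every frame instead of dropping stale ones")
  )
}

universal_source_params <- function() {
  list(verbose = plugin_param("integer", 0L, "1 for verbose logging"))
}

#' Define a plug-in descriptor
#'
#' @param display Human-readable plug-in name; its normalized form is the
#'   plug-in's command-line token and output stream name.
#' @param is_input `TRUE` for source plug-ins (their output stream is named
#'   `'Input'`, `'Input1'`, ... regardless of the plug-in name).
#' @param params Named list of parameter definitions (see examples in the
#'   package sources); universal parameters are added automatically.
#' @param init Function `(plugin)` called at instantiation to attach the
#'   task (`fn_task`), modelled execution time (`fn_exec_time`) or source
#'   emission (`fn_next`) functions.
#' @param drop_disabled Default for process-all mode.
#' @return A `plugin_descriptor`.
#' @export
plugin_descriptor <- function(display, is_input = FALSE, params = list(),
                              init = NULL, drop_disabled = FALSE) {
  token <- normalize_plugin_name(display)
  all_params <- c(params, if (is_input) universal_source_params()
                  else universal_processor_params(drop_disabled))
  structure(list(display = display, token = token, is_input = is_input,
                 params = all_params, init = init,
                 drop_disabled = drop_disabled),
            class = "plugin_descriptor")
}

#' @export
print.plugin_descriptor <- function(x, ...) {
  cat(sprintf("<plugin_descriptor> %s (%s)%s\n", x$display, x$token,
              if (x$is_input) " [input]" else ""))
  invisible(x)
}

#' Instantiate a plug-in from its descriptor
#'
#' Applies parameter defaults, coerces and validates the supplied
#' configuration, and initializes scheduler state. Unknown parameters are
#' rejected; values that cannot be coerced to the declared type are an error.
#'
#' @param desc A [plugin_descriptor()].
#' @param config Named list of parameter values.
#' @return A plug-in environment ready for [assign_stream_names()] and
#'   [run_pipeline()].
#' @export
instantiate_plugin <- function(desc, config = list()) {
  pl <- new.env(parent = emptyenv())
  pl$display <- desc$display
  pl$token <- desc$token
  pl$is_input <- desc$is_input
  pl$params <- desc$params
  unknown <- setdiff(names(config), names(desc$params))
  if (length(unknown)) {
    stop("unknown parameter(s) for ", desc$token, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(desc$params)) {
    def <- desc$params[[nm]]
    val <- if (nm %in% names(config)) coerce_param(config[[nm]], def$type, nm, desc$token)
           else def$default
    assign(nm, val, envir = pl)
  }
  if (!desc$is_input) {
    pl$sub_stream <- pl$stream        # NULL -> default 'Input' at wiring time
    pl$sub_layer <- pl$layer
    pl$period <- 1 / pl$framerate
    pl$drop_disabled <- pl$processall >= 1L
    pl$time_enabled <- pl$time >= 1L
  } else {
    pl$t0 <- 0
  }
  sched_init(pl)
  class(pl) <- c(paste0("plugin_", desc$token), "ps_plugin")
  if (is.function(desc$init)) desc$init(pl)
  if (!desc$is_input && !is.function(pl$fn_exec_time)) {
    pl$fn_exec_time <- function(pl, frame) 0.001
  }
  pl
}

coerce_param <- function(value, type, name, token) {
  out <- switch(type,
                numeric = suppressWarnings(as.numeric(value)),
                integer = suppressWarnings(as.integer(value)),
                character = as.character(value),
                value)
  if (type %in% c("numeric", "integer") && (length(out) != 1L || is.na(out))) {
    stop("parameter --", token, "_", name, " expects a ", type,
         " value, got ", sQuote(as.character(value)), call. = FALSE)
  }
  out
}

#' @export
print.ps_plugin <- function(x, ...) {
  cat(sprintf("<plugin> %s (%s)%s\n", x$display, x$token,
              if (x$is_input) " [input]" else
                sprintf("  stream=%s layer=%d f=%g Hz",
                        if (is.null(x$sub_stream)) "Input" else x$sub_stream,
                        x$sub_layer, x$framerate)))
  invisible(x)
}

# --- processing tasks ------------------------------------------------------

#' Gaussian blur of one layer
#'
#' Separable Gaussian convolution with symmetric (reflective) boundary
#' handling, which preserves total intensity exactly for the normalized
#' kernel. Kernel radius is `ceiling(3 * sigma)`.
#'
#' @param x Numeric matrix.
#' @param sigma Kernel standard deviation in pixels (`> 0`).
#' @return Blurred matrix, same dimensions.
#' @export
gaussian_blur <- function(x, sigma = 5) {
  stopifnot(is.matrix(x), sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  blur_axis <- function(m) {    # along rows (dim 1), symmetric extension
    n <- nrow(m)
    idx <- reflect_index(seq(1L - r, n + r), n)
    p <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in 0:(2L * r)) out <- out + k[j + 1L] * p[(1L + j):(n + j), , drop = FALSE]
    out
  }
  t(blur_axis(t(blur_axis(x))))
}

# Fold an out-of-range index back into 1..n by symmetric (mirror) extension
# with edge repeat; bounces as many times as needed, so kernels wider than
# the image remain mass-preserving.
reflect_index <- function(i, n) {
  m <- (i - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

#' Apply the blur task to a frame
#'
#' Appends the Gaussian-blurred selected layer as a new layer; existing
#' layers are untouched.
#'
#' @param frame A `stream_frame`.
#' @param layer_index Layer to blur (negative indices wrap; `-1` = last).
#' @param sigma Kernel standard deviation in pixels.
#' @return `frame`, with the blurred layer appended.
#' @export
blur_task <- function(frame, layer_index = -1L, sigma = 5) {
  add_layer(frame, gaussian_blur(get_layer(frame, layer_index), sigma))
}

#' Apply the binary-threshold task to a frame
#'
#' Appends a 0/1 mask layer: 1 where the selected layer exceeds `level`.
#'
#' @param frame A `stream_frame`.
#' @param layer_index Layer to threshold.
#' @param level Threshold intensity; default half of the 8-bit range.
#' @return `frame`, with the mask layer appended.
#' @export
threshold_task <- function(frame, layer_index = -1L, level = 127.5) {
  x <- get_layer(frame, layer_index)
  add_layer(frame, (x > level) * 1)
}

#' Artificial-delay task
#'
#' Passes the frame through unchanged after occupying the worker for `wait`
#' seconds (really sleeping under the wall clock; under the simulated clock
#' the wait is part of the plug-in's modelled execution time). A
#' `"<stream>.passes"` metadata key counts how many times the plug-in has
#' fired.
#'
#' @param frame A `stream_frame`.
#' @param wait Wait time in seconds (`>= 0`).
#' @param sleep Whether to actually sleep (wall-clock mode).
#' @return `frame`, unchanged apart from the pass-count metadata key.
#' @export
delay_task <- function(frame, wait = 0, sleep = FALSE) {
  stopifnot(wait >= 0)
  if (sleep && wait > 0) Sys.sleep(wait)
  frame
}

# --- built-in registry -----------------------------------------------------

builtin_registry <- new.env(parent = emptyenv())

register_builtin <- function(desc) {
  builtin_registry[[desc$token]] <- desc
  invisible(desc)
}

#' List the built-in plug-in descriptors
#'
#' @return Named list of [plugin_descriptor()] objects in their fixed
#'   discovery order.
#' @export
builtin_plugins <- function() {
  if (length(ls(builtin_registry)) == 0L) register_builtins()
  order <- c("filemanager", "imagefilewriter", "videomanager", "cppalgorithm",
             "framesource", "pythonalgorithm", "standardplanedetection", "gui")
  lapply_named(order, function(tk) builtin_registry[[tk]])
}

lapply_named <- function(x, f) {
  out <- lapply(x, f)
  names(out) <- x
  out
}

# Attach source behaviour backed by a pre-computed list of frames or a
# generator function of the 0-based frame index.
source_init <- function(pl, get_frame, n_frames, fps, loop = FALSE) {
  pl$fps <- fps
  pl$n_frames <- n_frames
  pl$fn_next <- function(pl, t) {
    k <- pl$emit_index
    if (!loop && k >= pl$n_frames) return(NULL)
    idx <- k %% pl$n_frames
    wrap <- k %/% pl$n_frames
    px <- get_frame(idx)
    meta <- if (loop && wrap > 0L) list(wrap = wrap) else NULL
    list(pixels = px, meta = meta,
         frame_id = if (loop) idx else k)
  }
  invisible(pl)
}

register_builtins <- function() {
  # Frame source: seeded synthetic sequence (frame-grabber stand-in)
  register_builtin(plugin_descriptor(
    "Frame source", is_input = TRUE,
    params = list(
      duration = plugin_param("numeric", 10, "stream length in seconds"),
      fps = plugin_param("numeric", 30, "emission rate in Hz"),
      width = plugin_param("integer", 32L, "frame width in pixels"),
      height = plugin_param("integer", 32L, "frame height in pixels"),
      pattern = plugin_param("character", "blobs", "'blobs' or 'blank'"),
      seed = plugin_param("integer", 1L, "noise seed")
    ),
    init = function(pl) {
      if (pl$fps <= 0) stop("framesource fps must be > 0", call. = FALSE)
      gen <- NULL
      pl$on_activate <- function(pl, en) {
        gen <<- synthetic_frame_gen(pl$width, pl$height, pl$pattern, pl$seed)
      }
      source_init(pl, function(k) gen(k), round(pl$duration * pl$fps), pl$fps)
    }))

  # Video manager: multi-page TIFF file, image folder, or synthetic spec
  register_builtin(plugin_descriptor(
    "Video manager", is_input = TRUE,
    params = list(
      input = plugin_param("character", NULL,
                           "video file (multi-page TIFF), image folder, or synthetic:... spec"),
      framerate = plugin_param("numeric", 0, "playback rate override in Hz (0 = native 30)"),
      loop = plugin_param("integer", 0L, "1 to loop the video"),
      rgb = plugin_param("integer", 0L, "1 to keep RGB as 3 layers instead of luminance average")
    ),
    init = function(pl) {
      pl$on_activate <- function(pl, en) {
        inp <- pl$input
        if (is.null(inp)) stop("videomanager requires --videomanager_input", call. = FALSE)
        if (startsWith(inp, "synthetic:")) {
          sp <- parse_synthetic_spec(inp)
          gen <- synthetic_frame_gen(sp$width, sp$height, sp$pattern, sp$seed)
          fps <- if (pl$framerate > 0) pl$framerate else sp$fps
          source_init(pl, gen, round(sp$duration * sp$fps), fps,
                      loop = pl$loop >= 1L)
        } else if (dir.exists(inp)) {
          frames <- load_image_folder(inp)
          fps <- if (pl$framerate > 0) pl$framerate else 30
          source_init(pl, function(k) frames[[k + 1L]], length(frames), fps,
                      loop = pl$loop >= 1L)
        } else if (file.exists(inp)) {
          frames <- load_tiff_stack(inp)
          fps <- if (pl$framerate > 0) pl$framerate else 30
          source_init(pl, function(k) frames[[k + 1L]], length(frames), fps,
                      loop = pl$loop >= 1L)
        } else {
          stop("videomanager input not found: ", inp, call. = FALSE)
        }
        engine_log(en, sprintf("Video manager: loaded %s, FPS = %g, frames = %d",
                               inp, pl$fps, pl$n_frames))
      }
    }))

  # File manager: folder of 2D images played back at a given frame rate
  register_builtin(plugin_descriptor(
    "File manager", is_input = TRUE,
    params = list(
      input = plugin_param("character", NULL, "folder of PNG/TIFF images"),
      framerate = plugin_param("numeric", 20, "playback rate in Hz"),
      loop = plugin_param("integer", 0L, "1 to loop the sequence")
    ),
    init = function(pl) {
      pl$on_activate <- function(pl, en) {
        if (is.null(pl$input)) stop("filemanager requires --filemanager_input", call. = FALSE)
        if (pl$framerate <= 0) stop("filemanager framerate must be > 0", call. = FALSE)
        frames <- load_image_folder(pl$input)
        source_init(pl, function(k) frames[[k + 1L]], length(frames),
                    pl$framerate, loop = pl$loop >= 1L)
      }
    }))

  # Python Algorithm: Gaussian blur + optional artificial wait
  register_builtin(plugin_descriptor(
    "Python Algorithm",
    params = list(
      sigma = plugin_param("numeric", 5, "blur kernel standard deviation in pixels"),
      delay = plugin_param("numeric", 0, "artificial wait time in seconds"),
      cost = plugin_param("numeric", 0.025, "modelled worker cost in seconds (simulated clock)")
    ),
    init = function(pl) {
      pl$fn_task <- function(pl, frame, en) {
        if (pl$delay < 0) stop("delay must be >= 0", call. = FALSE)
        delay_task(frame, pl$delay, sleep = en$clock$mode == "wall")
        out <- blur_task(frame, pl$sub_layer, pl$sigma)
        key <- paste0(pl$out_stream, ".passes")
        pl$passes <- (if (is.null(pl$passes)) 0L else pl$passes) + 1L
        set_frame_meta(out, key, pl$passes)
        out
      }
      pl$fn_exec_time <- function(pl, frame) pl$cost + pl$delay
    }))

  # Cpp Algorithm: binary threshold
  register_builtin(plugin_descriptor(
    "Cpp Algorithm",
    params = list(
      level = plugin_param("numeric", 127.5, "threshold intensity"),
      cost = plugin_param("numeric", 0.001, "modelled worker cost in seconds (simulated clock)")
    ),
    init = function(pl) {
      pl$fn_task <- function(pl, frame, en) threshold_task(frame, pl$sub_layer, pl$level)
      pl$fn_exec_time <- function(pl, frame) pl$cost
    }))

  # Standard plane detection: mock classifier with temporal averaging
  register_builtin(plugin_descriptor(
    "Standard plane detection",
    params = list(
      taverage = plugin_param("integer", 1L, "temporal averaging window (frames)"),
      cost = plugin_param("numeric", 0.015, "modelled worker cost in seconds (simulated clock)")
    ),
    init = function(pl) {
      pl$score_window <- list()
      pl$model <- NULL   # drop-in scorer: function(pixels) -> named scores
      pl$on_stream_change <- function(pl) pl$score_window <- list()
      pl$fn_task <- function(pl, frame, en) classify_task(frame, pl, en)
      pl$fn_exec_time <- function(pl, frame) pl$cost
    }))

  # Image file writer: PNG per layer + JSON metadata sidecar
  register_builtin(plugin_descriptor(
    "Image file writer", drop_disabled = TRUE,
    params = list(
      folder = plugin_param("character", NULL, "output directory"),
      label = plugin_param("character", "default",
                           "subfolder label; switchable at run time"),
      layers = plugin_param("character", "all", "'all' or a single layer index")
    ),
    init = function(pl) {
      pl$on_activate <- function(pl, en) {
        if (is.null(pl$folder)) stop("imagefilewriter requires --imagefilewriter_folder", call. = FALSE)
        dir.create(pl$folder, recursive = TRUE, showWarnings = FALSE)
        if (!dir.exists(pl$folder) || file.access(pl$folder, 2L) != 0L) {
          stop("imagefilewriter folder is not writable: ", pl$folder, call. = FALSE)
        }
      }
      pl$fn_task <- function(pl, frame, en) {
        write_frame(frame, pl$folder, pl$label, pl$layers)
        frame
      }
      pl$fn_exec_time <- function(pl, frame) 0.002
    }))

  # GUI: headless display sink
  register_builtin(plugin_descriptor(
    "GUI",
    params = list(),
    init = function(pl) {
      pl$seen <- new.env(parent = emptyenv())
      pl$fn_task <- function(pl, frame, en) {
        tryCatch({
          s <- frame$stream_name
          info <- if (is.null(pl$seen[[s]])) list(count = 0L) else pl$seen[[s]]
          info$count <- info$count + 1L
          info$last_id <- frame$frame_id
          info$last_time <- frame$acq_time
          info$layers <- n_layers(frame)
          lk <- grep("\\.label$", names(frame$meta), value = TRUE)
          if (length(lk)) info$label <- frame$meta[[lk[[1L]]]]
          ck <- grep("\\.confidence$", names(frame$meta), value = TRUE)
          if (length(ck)) info$confidence <- frame$meta[[ck[[1L]]]]
          pl$seen[[s]] <- info
        }, error = function(e) NULL)   # a display must never stall the pipeline
        frame
      }
      pl$fn_exec_time <- function(pl, frame) 0.001
    }))
}

#' Per-stream summary collected by the display sink
#'
#' @param plugin A `gui` plug-in instance (e.g. from a finished run's
#'   `plugins` list).
#' @return Data frame with one row per stream the sink displayed: frames
#'   shown, last frame id and time, layer count, last classifier label and
#'   confidence if present.
#' @export
sink_summary <- function(plugin) {
  streams <- ls(plugin$seen)
  if (length(streams) == 0L) {
    return(data.frame(stream = character(0), shown = integer(0)))
  }
  do.call(rbind, lapply(streams, function(s) {
    info <- plugin$seen[[s]]
    data.frame(stream = s, shown = info$count, last_id = info$last_id,
               last_time = info$last_time, layers = info$layers,
               label = if (is.null(info$label)) NA_character_ else info$label,
               confidence = if (is.null(info$confidence)) NA_real_ else info$confidence,
               stringsAsFactors = FALSE)
  }))
}
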