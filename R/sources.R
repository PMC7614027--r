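#' Synthetic frame sequences
#'
#' The synthetic generator stands in for a hardware frame grabber: it emits a
#' deterministic, seeded sequence of 8-bit grayscale frames. The `"blobs"`
#' pattern draws two Gaussian blobs drifting across the field over additive
#' seeded noise, clipped and rounded to `[0, 255]` -- enough texture for the
#' blur, threshold and classifier plug-ins to produce non-trivial output,
#' while remaining cheap to generate faster than real time. The `"blank"`
#' pattern is a constant mid-gray frame for pure throughput measurements.
#'
#' Frame `k` of a given `(seed, pattern, width, height)` specification is
#' bit-identical across runs and does not perturb the caller's RNG state.
#'
#' @param width,height Frame size in pixels.
#' @param pattern `"blobs"` or `"blank"`.
#' @param seed Integer seed for the noise sequence.
#' @return A function of the 0-based frame index `k` returning a
#'   `height x width` numeric matrix with integer values in `[0, 255]`.
#' @examples
#' gen <- synthetic_frame_gen(16, 16, seed = 1)
#' f0 <- gen(0)
#' range(f0)
#' @export
synthetic_frame_gen <- function(width = 32, height = 32,
                                pattern = c("blobs", "blank"), seed = 1L) {
  pattern <- match.arg(pattern)
  seed <- as.integer(seed)
  xs <- matrix(seq_len(width), height, width, byrow = TRUE)
  ys <- matrix(seq_len(height), height, width)
  function(k) {
    if (pattern == "blank") {
      return(matrix(128, height, width))
    }
    # drifting blob centres, deterministic in k
    cx1 <- width * (0.5 + 0.35 * sin(2 * pi * k / 240))
    cy1 <- height * (0.5 + 0.35 * cos(2 * pi * k / 311))
    cx2 <- width * (0.5 + 0.30 * cos(2 * pi * k / 173))
    cy2 <- height * (0.5 + 0.30 * sin(2 * pi * k / 197))
    s1 <- 0.12 * width
    s2 <- 0.08 * width
    img <- 40 +
      150 * exp(-((xs - cx1)^2 + (ys - cy1)^2) / (2 * s1^2)) +
      110 * exp(-((xs - cx2)^2 + (ys - cy2)^2) / (2 * s2^2))
    noise <- with_frame_rng(seed, k, stats::rnorm(height * width, 0, 10))
    img <- img + matrix(noise, height, width)
    matrix(pmin(255, pmax(0, round(img))), height, width)
  }
}

# Run `expr` under a per-frame RNG stream derived from (seed, k), restoring
# the caller's RNG state afterwards.
with_frame_rng <- function(seed, k, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed((abs(seed) * 100003 + k * 7919) %% 2147483647)
  expr
}

# Parse a synthetic source spec string such as
# "synthetic:duration=900,fps=30,seed=1,width=32,height=32,pattern=blobs".
parse_synthetic_spec <- function(spec) {
  body <- sub("^synthetic:", "", spec)
  out <- list(duration = 10, fps = 30, seed = 1L, width = 32L, height = 32L,
              pattern = "blobs")
  if (nzchar(body)) {
    for (kv in strsplit(body, ",", fixed = TRUE)[[1L]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) stop("bad synthetic spec element: ", kv, call. = FALSE)
      key <- parts[1L]
      if (!key %in% names(out)) stop("unknown synthetic spec key: ", key, call. = FALSE)
      out[[key]] <- if (key == "pattern") parts[2L] else as.numeric(parts[2L])
    }
  }
  out
}

# Load a folder of 2D image files (PNG / TIFF), lexical order, as grayscale
# matrices in [0, 255].
load_image_folder <- function(path, rgb = FALSE) {
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    stop("no PNG/TIFF images found in ", path, call. = FALSE)
  }
  lapply(files, read_gray_image, rgb = rgb)
}

# Read one image file into a grayscale matrix in [0, 255]; colour images are
# collapsed by luminance average unless `rgb` (then a list of 3 layers).
read_gray_image <- function(file, rgb = FALSE) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
                png = png::readPNG(file),
                tif = ,
                tiff = tiff::readTIFF(file),
                stop("unsupported image format: ", ext, call. = FALSE))
  to_gray_255(img, rgb = rgb)
}

to_gray_255 <- function(img, rgb = FALSE) {
  if (length(dim(img)) == 3L) {
    if (rgb) {
      return(lapply(seq_len(dim(img)[3L]), function(c) img[, , c] * 255))
    }
    img <- apply(img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE],
                 c(1L, 2L), mean)
  }
  img * 255
}

# Load a multi-page TIFF "video" file as a list of grayscale matrices.
load_tiff_stack <- function(path, rgb = FALSE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, to_gray_255, rgb = rgb)
}
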