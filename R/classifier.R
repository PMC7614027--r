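#' Mock standard-plane classifier
#'
#' A deterministic stand-in for a trained standard-plane detection network,
#' exposing the same interface: per-frame class scores over a label space of
#' `"Background"` plus 13 fetal standard views, normalized to sum to 1, with
#' an optional temporal sliding mean over the last `taverage` frames to
#' stabilize the prediction at high acquisition rates. Any user model can be
#' dropped in by assigning a `function(pixels) -> named numeric scores` to
#' the plug-in's `model` field; the mock scorer maps six global image
#' features (intensity moments, gradient energy, histogram entropy,
#' foreground fraction) through a fixed linear map and a softmax. The
#' coefficients are closed-form constants, so the same frame always yields
#' the same scores.
#'
#' @name standard-plane-classifier
NULL

#' Class labels of the mock standard-plane classifier
#' @return Character vector: `"Background"` plus 13 fetal standard views.
#' @export
plane_class_labels <- function() {
  c("Background", "Abdominal", "Brain-Cb", "Brain-Tv", "Femur", "Kidneys",
    "Lips", "LVOT", "Profile", "RVOT", "Spine-Cor", "Spine-Sag", "3VV", "4CH")
}

# Fixed coefficient matrix (14 classes x 6 features) and intercepts,
# generated from a closed form so the scorer ships as code, not data.
plane_coefs <- function() {
  K <- 14L; P <- 6L
  W <- matrix(sin(seq_len(K * P) * 2.39996), K, P)   # golden-angle spread
  b <- 0.1 * cos(seq_len(K) * 1.7)
  list(W = W, b = b)
}

plane_features <- function(x) {
  v <- as.numeric(x) / 255
  m <- mean(v); s <- stats::sd(v)
  skew <- if (s > 0) mean(((v - m) / s)^3) else 0
  gx <- diff(t(x)) / 255; gy <- diff(x) / 255
  grad <- mean(abs(gx)) + mean(abs(gy))
  h <- tabulate(pmin(16L, 1L + floor(v * 16)), 16L) / length(v)
  ent <- -sum(ifelse(h > 0, h * log(h), 0))
  frac <- mean(v > 0.5)
  c(m, s, skew, grad, ent, frac)
}

#' Score one image with the mock plane classifier
#'
#' @param pixels 2D numeric matrix in `[0, 255]`.
#' @return Named numeric vector of class scores in `[0, 1]` summing to 1.
#' @export
plane_scores <- function(pixels) {
  cf <- plane_coefs()
  z <- as.numeric(cf$W %*% plane_features(pixels)) * 4 + cf$b
  e <- exp(z - max(z))
  stats::setNames(e / sum(e), plane_class_labels())
}

#' Classify a frame with temporal score averaging
#'
#' Scores the subscribed layer (with the plug-in's `model` function, or the
#' built-in mock scorer), pushes the raw scores into the plug-in's sliding
#' window of the last `taverage` frames, and writes the window-averaged
#' argmax label and confidence into the frame metadata (keys namespaced by
#' the plug-in's stream name: `<stream>.label`, `<stream>.confidence`,
#' `<stream>.scores` as a JSON string). A coarse overlay layer encoding the
#' predicted class index is appended so downstream sinks can display the
#' detection. The window resets when the plug-in is re-subscribed to a
#' different stream.
#'
#' @param frame A `stream_frame`.
#' @param plugin The `standardplanedetection` plug-in instance (fields
#'   `taverage`, `sub_layer`, `score_window`, `model`, `out_stream`).
#' @param en Engine (unused by the mock model; present for drop-in models
#'   that need clock access).
#' @return `frame`, with metadata and the overlay layer appended.
#' @export
classify_task <- function(frame, plugin, en = NULL) {
  N <- as.integer(plugin$taverage)
  if (is.na(N) || N < 1L) stop("taverage must be >= 1", call. = FALSE)
  scorer <- if (is.function(plugin$model)) plugin$model else plane_scores
  raw <- scorer(get_layer(frame, plugin$sub_layer))
  win <- plugin$score_window
  win[[length(win) + 1L]] <- raw
  if (length(win) > N) win <- win[(length(win) - N + 1L):length(win)]
  plugin$score_window <- win
  avg <- Reduce(`+`, win) / length(win)
  lab <- names(avg)[which.max(avg)]
  ns <- if (is.null(plugin$out_stream)) plugin$token else plugin$out_stream
  set_frame_meta(frame, paste0(ns, ".label"), lab)
  set_frame_meta(frame, paste0(ns, ".confidence"), unname(max(avg)))
  set_frame_meta(frame, paste0(ns, ".scores"),
                 as.character(jsonlite::toJSON(as.list(avg), auto_unbox = TRUE,
                                               digits = NA)))
  add_layer(frame, label_overlay(dim(get_layer(frame, 0L)), lab))
  frame
}

# Overlay layer: a band at the top encodes the predicted class index as a
# normalized intensity; zero elsewhere. Enough for a headless sink to show
# which view was detected without any text rendering.
label_overlay <- function(dims, label) {
  labels <- plane_class_labels()
  idx <- match(label, labels)
  ov <- matrix(0, dims[1L], dims[2L])
  band <- max(1L, dims[1L] %/% 8L)
  ov[seq_len(band), ] <- (idx - 1L) / (length(labels) - 1L)
  ov
}
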