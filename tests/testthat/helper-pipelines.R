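# Shared fixtures: tiny pipelines and frame folders built in code.

# A short source>blur pipeline with an artificial wait; sim-clock by default.
delay_pipeline <- function(wait = 0.1, rate = 20, duration = 10,
                           source_fps = 30, size = 16L) {
  build_pipeline("framesource>pythonalgorithm", list(
    framesource = list(duration = duration, fps = source_fps,
                       width = size, height = size),
    pythonalgorithm = list(delay = wait, framerate = rate, sigma = 2)))
}

# Write n tiny grayscale PNGs into a fresh temp folder; returns the path.
make_png_folder <- function(n, size = 8L) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  for (k in seq_len(n)) {
    px <- matrix((k * 10 %% 256) / 255, size, size)
    png::writePNG(px, file.path(dir, sprintf("frame_%03d.png", k)))
  }
  dir
}

# Independent direct 2D Gaussian convolution with symmetric boundary --
# the brute-force oracle for the separable blur implementation.
reference_blur <- function(x, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  off <- seq(-r, r)
  k1 <- dnorm(off, sd = sigma); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  n <- nrow(x); m <- ncol(x)
  reflect <- function(i, n) {          # symmetric extension with edge repeat
    m <- (i - 1L) %% (2L * n)
    ifelse(m < n, m + 1L, 2L * n - m)
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (a in seq_along(off)) for (b in seq_along(off)) {
      acc <- acc + k2[a, b] * x[reflect(i + off[a], n), reflect(j + off[b], m)]
    }
    out[i, j] <- acc
  }
  out
}
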