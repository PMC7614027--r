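test_that("synthetic source is bit-identical across runs and leaves the RNG alone", {
  g1 <- synthetic_frame_gen(16, 16, "blobs", seed = 7L)
  g2 <- synthetic_frame_gen(16, 16, "blobs", seed = 7L)
  set.seed(42); before <- runif(3)
  set.seed(42)
  frames1 <- lapply(0:4, g1)
  expect_identical(runif(3), before)   # generator does not consume global RNG
  expect_identical(frames1, lapply(0:4, g2))
  g3 <- synthetic_frame_gen(16, 16, "blobs", seed = 8L)
  expect_false(identical(g1(0), g3(0)))
  expect_true(all(g1(0) >= 0 & g1(0) <= 255))
})

test_that("Gaussian blur matches a direct-convolution oracle", {
  # constant images are fixed points of a normalized blur
  const <- matrix(77, 12, 12)
  expect_equal(gaussian_blur(const, 3), const, tolerance = 1e-12)

  # centred unit impulse against brute-force 2D convolution
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  expect_equal(gaussian_blur(imp, 2), reference_blur(imp, 2), tolerance = 1e-12)

  # arbitrary image, small sigma
  set.seed(11)
  x <- matrix(runif(15 * 9, 0, 255), 15, 9)
  expect_equal(gaussian_blur(x, 1.3), reference_blur(x, 1.3), tolerance = 1e-9)

  # linearity and mean preservation under the reflective boundary
  expect_equal(gaussian_blur(3.7 * x, 2), 3.7 * gaussian_blur(x, 2),
               tolerance = 1e-9)
  expect_equal(mean(gaussian_blur(x, 4)), mean(x), tolerance = 1e-6)
})

test_that("blur task appends a layer and leaves inputs untouched", {
  f <- make_frame(matrix(100, 16, 16))
  mark <- tracemem(f$layers[[1L]])
  copies <- capture.output(blur_task(f, -1L, sigma = 2))
  untracemem(f$layers[[1L]])
  expect_identical(copies, character(0))
  expect_equal(n_layers(f), 2L)
  expect_equal(get_layer(f, -1L), matrix(100, 16, 16), tolerance = 1e-9)
  expect_error(blur_task(f, 7L), "out of range")
})

test_that("threshold task produces the expected binary masks", {
  low <- make_frame(matrix(100, 4, 4))
  threshold_task(low, 0L, level = 127)
  expect_equal(get_layer(low, -1L), matrix(0, 4, 4))

  high <- make_frame(matrix(200, 4, 4))
  threshold_task(high, 0L, level = 127)
  expect_equal(get_layer(high, -1L), matrix(1, 4, 4))

  half <- make_frame(rbind(matrix(0, 2, 4), matrix(255, 2, 4)))
  threshold_task(half, 0L, level = 127)
  expect_equal(mean(get_layer(half, -1L)), 0.5)

  # idempotence: thresholding a 0/1 mask at 0.5 returns the mask
  mask <- get_layer(half, -1L)
  f2 <- make_frame(mask)
  threshold_task(f2, 0L, level = 0.5)
  expect_equal(get_layer(f2, -1L), mask)
})

test_that("classifier scores are normalized and the window average matches brute force", {
  px <- synthetic_frame_gen(24, 24, seed = 3L)(0)
  sc <- plane_scores(px)
  expect_equal(sum(sc), 1, tolerance = 1e-9)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_identical(names(sc), plane_class_labels())
  expect_identical(plane_scores(px), sc)   # deterministic

  desc <- builtin_plugins()$standardplanedetection
  pl <- instantiate_plugin(desc, list(taverage = 3L))
  pl$out_stream <- "standardplanedetection"
  gen <- synthetic_frame_gen(24, 24, seed = 5L)
  raws <- list()
  for (k in 0:7) {
    f <- make_frame(gen(k), "Input", k)
    classify_task(f, pl)
    raws[[k + 1L]] <- plane_scores(gen(k))
    lo <- max(1L, k + 1L - 2L)
    brute <- Reduce(`+`, raws[lo:(k + 1L)]) / (k + 2L - lo)
    got <- jsonlite::fromJSON(frame_meta(f, "standardplanedetection.scores"))
    expect_equal(unlist(got), brute, tolerance = 1e-9)
    expect_equal(sum(unlist(got)), 1, tolerance = 1e-9)
    expect_identical(frame_meta(f, "standardplanedetection.label"),
                     names(brute)[which.max(brute)])
  }
  expect_equal(length(pl$score_window), 3L)
  pl0 <- instantiate_plugin(desc, list(taverage = 0L))
  expect_error(classify_task(f, pl0), "taverage")
})

test_that("taverage = 1 reproduces raw scores; alternating scores average to 0.5", {
  desc <- builtin_plugins()$standardplanedetection
  pl1 <- instantiate_plugin(desc, list(taverage = 1L))
  pl1$out_stream <- "spd"
  px <- synthetic_frame_gen(16, 16, seed = 2L)(0)
  f <- make_frame(px)
  classify_task(f, pl1)
  raw <- plane_scores(px)
  expect_equal(frame_meta(f, "spd.confidence"), unname(max(raw)),
               tolerance = 1e-9)

  # drop-in model: top class alternates 0.9/0.1; with N = 2 the averaged
  # top-class score is 0.5 from the second frame on
  pl2 <- instantiate_plugin(desc, list(taverage = 2L))
  pl2$out_stream <- "spd"
  k <- 0L
  pl2$model <- function(px) {
    k <<- k + 1L
    top <- if (k %% 2L == 1L) 0.9 else 0.1
    setNames(c(top, rep((1 - top) / 13, 13)), plane_class_labels())
  }
  confs <- numeric(4)
  for (i in 1:4) {
    fi <- make_frame(px)
    classify_task(fi, pl2)
    sc <- unlist(jsonlite::fromJSON(frame_meta(fi, "spd.scores")))
    confs[i] <- sc[["Background"]]
  }
  expect_equal(confs, c(0.9, 0.5, 0.5, 0.5), tolerance = 1e-12)

  # window resets when the subscription changes stream
  resubscribe(pl2, stream = "cppalgorithm")
  expect_length(pl2$score_window, 0L)
})

test_that("delay task passes frames through unchanged", {
  f <- make_frame(matrix(3, 4, 4))
  out <- delay_task(f, wait = 0)
  expect_identical(out, f)
  expect_error(delay_task(f, wait = -1))
})

test_that("writer saves PNG layers with JSON sidecars that round-trip", {
  dir <- withr::local_tempdir()
  gen <- synthetic_frame_gen(12, 12, seed = 9L)
  for (k in 0:9) {
    f <- make_frame(gen(k), "Input", k, k / 10, 10)
    threshold_task(f, 0L, 127)
    set_frame_meta(f, "spd.label", "Femur")
    write_frame(f, dir, "classA")
  }
  pngs <- list.files(file.path(dir, "classA"), pattern = "\\.png$")
  jsons <- list.files(file.path(dir, "classA"), pattern = "\\.json$")
  expect_length(jsons, 10L)
  expect_length(pngs, 20L)   # two layers per frame

  back <- read_saved_frame(file.path(dir, "classA", sort(jsons)[1L]))
  orig <- gen(0)
  expect_equal(get_layer(back, 0L), orig, tolerance = 1e-9)  # 8-bit exact
  expect_equal(get_layer(back, 1L), (orig > 127) * 1)
  expect_identical(back$meta$spd.label, "Femur")
  expect_identical(back$meta$stream, "Input")
  expect_equal(back$frame_id, 0L)
})

test_that("the writer's label switches mid-session without frame loss", {
  dir <- withr::local_tempdir()
  desc <- builtin_plugins()$imagefilewriter
  pl <- instantiate_plugin(desc, list(folder = dir))
  pl$label <- "classA"
  gen <- synthetic_frame_gen(8, 8, seed = 1L)
  fake_en <- list(clock = list(mode = "simulated"))
  pl$on_activate(pl, fake_en)
  for (k in 0:9) {
    if (k == 5L) pl$label <- "classB"    # run-time 'set imagefilewriter_label'
    f <- make_frame(gen(k), "Input", k, k / 10, 10)
    pl$fn_task(pl, f, fake_en)
  }
  expect_length(list.files(file.path(dir, "classA"), pattern = "json$"), 5L)
  expect_length(list.files(file.path(dir, "classB"), pattern = "json$"), 5L)
})

test_that("sidecars record multi-source provenance", {
  dir <- withr::local_tempdir()
  write_frame(make_frame(matrix(1, 4, 4), "Input", 0L), dir, "multi")
  write_frame(make_frame(matrix(2, 4, 4), "Input1", 0L), dir, "multi")
  jsons <- list.files(file.path(dir, "multi"), pattern = "json$", full.names = TRUE)
  streams <- sort(vapply(jsons, function(p) jsonlite::read_json(p)$stream,
                         character(1), USE.NAMES = FALSE))
  expect_identical(streams, c("Input", "Input1"))
})

test_that("file sources honour frame count, rate and loop mode", {
  dir <- make_png_folder(7)
  cfg <- list(filemanager = list(input = dir, framerate = 10))
  run <- run_pipeline(build_pipeline("filemanager>gui", cfg), duration = 5)
  cnt <- run$counters
  expect_equal(cnt$emitted[cnt$plugin == "filemanager"], 7L)  # then end-of-stream
  expect_equal(cnt$received[cnt$plugin == "gui"], 7L)

  # looped playback restarts ids at 0 and tags the wrap count
  desc <- builtin_plugins()$videomanager
  pl <- instantiate_plugin(desc, list(input = dir, framerate = 10, loop = 1L))
  pl$on_activate(pl, list(quiet = TRUE))
  pl$emit_index <- 8L
  nx <- pl$fn_next(pl, 0.8)
  expect_equal(nx$frame_id, 1L)
  expect_equal(nx$meta$wrap, 1L)
})

test_that("the synthetic spec string drives the video manager", {
  cfg <- list(videomanager = list(
    input = "synthetic:duration=1,fps=20,seed=4,width=8,height=8"))
  run <- run_pipeline(build_pipeline("videomanager>gui", cfg), duration = 2)
  cnt <- run$counters
  expect_equal(cnt$emitted[cnt$plugin == "videomanager"], 20L)
  expect_error(pulsestream:::parse_synthetic_spec("synthetic:bogus=1"),
               "unknown synthetic spec key")
})

test_that("the display sink summarises streams and never raises", {
  cfg <- list(framesource = list(duration = 2, fps = 10, width = 8, height = 8),
              standardplanedetection = list(framerate = 20))
  pls <- build_pipeline("framesource>standardplanedetection>gui", cfg)
  run <- run_pipeline(pls, duration = 2)
  gui <- run$plugins[[3L]]
  s <- sink_summary(gui)
  expect_true("Input" %in% s$stream)
  expect_equal(s$shown[s$stream == "Input"],
               run$counters$processed[run$counters$plugin == "gui"])
  # a frame the sink cannot digest is ignored, not fatal
  expect_silent(gui$fn_task(gui, structure(list(), class = "stream_frame"),
                            list(clock = list(mode = "simulated"))))
})
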