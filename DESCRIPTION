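Package: pulsestream
Title: Plug-in Pipelines for Real-Time Imaging Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight plug-in pipeline engine for live streams of layered
    image frames, modelled on real-time ultrasound research platforms. Each
    plug-in runs concurrently at a user-defined frame rate with latest-frame
    (frame-dropping) semantics, consuming named data streams and appending its
    result as a new layer on the shared frame. Ships source, processing and
    sink plug-ins (synthetic and file-backed frame sources, Gaussian blur,
    binary threshold, a deterministic mock standard-plane classifier with
    temporal score averaging, an artificial-delay task, an image writer and a
    headless display sink), a command-line front end, and a telemetry harness
    that measures per-plugin execution times, effective frame rates and
    delay-to-input under either a deterministic simulated clock or the wall
    clock.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr
Config/testthat/edition: 3
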