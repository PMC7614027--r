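# pulsestream

A plug-in pipeline engine for real-time streams of layered image frames,
written for the kind of live ultrasound research setting where a video
source (machine video output, a recorded clip played back at acquisition
rate, or a synthetic stream) feeds a chain of image-analysis plug-ins — a
blur, a threshold, a standard-plane classifier — and every plug-in must keep
up with the stream no matter how slow its task is.

The engine's contract is *latest-frame scheduling with frame dropping*:

* every plug-in owns one worker; at most one task is in flight per plug-in,
  and frame forwarding through the pipeline is never blocked by any worker;
* a plug-in checks for input periodically at its requested frame rate *f*
  (tick period *p* = 1/*f*, 20 Hz by default); stale frames waiting at the
  input are replaced by newer ones and counted as dropped;
* consequently a task of constant duration *T* settles into processing one
  frame every ⌈*T*/*p*⌉ ticks, an **effective frame rate** of

  *f*<sub>eff</sub> = *f* / ⌈*T* · *f*⌉   (and *f* itself when *T* ≤ *p*),

  trading frame rate for zero temporal drift: the frame a worker receives is
  always the most recent one, never older than *T* + *p*.

Plug-ins communicate over named **streams**: input plug-ins emit on
`Input` (`Input1`, `Input2`, … for additional sources), every other plug-in
emits on a stream named after itself, and each plug-in subscribes to exactly
one stream (default `Input`) and one layer of it (default `-1`, the last).
A plug-in's result is appended to the shared frame as a new **layer** — no
pixel data is ever copied — so any downstream consumer can pair a result
with the exact input frame that produced it.

Two clocks are available. The **simulated clock** advances only through
events, making runs exactly reproducible and a 15-minute session a matter of
seconds; worker completions are scheduled at dispatch time plus the task's
modelled execution time, which represents each worker running concurrently.
The **wall clock** paces the same event loop against real time for live use.

## Built-in plug-ins

| plug-in (CLI token) | kind | what it does |
|---|---|---|
| `framesource` | source | seeded synthetic frame stream (frame-grabber stand-in) |
| `videomanager` | source | multi-page TIFF, image folder, or `synthetic:` spec, played at acquisition rate |
| `filemanager` | source | folder of PNG/TIFF images at a given frame rate |
| `pythonalgorithm` | processing | Gaussian blur; optional artificial wait (`--pythonalgorithm_delay`) |
| `cppalgorithm` | processing | binary threshold of the subscribed layer |
| `standardplanedetection` | processing | deterministic mock standard-plane classifier with temporal score averaging (`--standardplanedetection_taverage`) |
| `imagefilewriter` | sink | PNG per layer + JSON metadata sidecar, run-time switchable label |
| `gui` | sink | headless display: per-stream summaries for the `stats` command |

## Worked example

The classic blur → threshold → classify chain, wired sequentially, with a
100 ms artificial wait in the blur plug-in and everything requested at
20 Hz, on a 60 s synthetic 30 Hz stream:

```r
library(pulsestream)
cfg <- list(
  framesource            = list(duration = 60, fps = 30, seed = 1),
  pythonalgorithm        = list(delay = 0.1, framerate = 20),
  cppalgorithm           = list(stream = "pythonalgorithm", layer = -1),
  standardplanedetection = list(stream = "cppalgorithm", taverage = 20)
)
pl  <- build_pipeline(
  "framesource>pythonalgorithm>cppalgorithm>standardplanedetection>gui", cfg)
run <- run_pipeline(pl, duration = 60)

for (p in c("pythonalgorithm", "cppalgorithm", "standardplanedetection"))
  cat(sprintf("%-24s rate %5.2f Hz   delay %5.0f ms\n", p,
      effective_rate(run, p), 1000 * median(delay_to_input(run, p))))
#> pythonalgorithm          rate  6.66 Hz   delay   133 ms
#> cppalgorithm             rate  6.68 Hz   delay   168 ms
#> standardplanedetection   rate  6.68 Hz   delay   232 ms

predicted_effective_rate(20, 0.125)
#> [1] 6.666667
```

The blur plug-in's task occupies its worker for 125 ms (100 ms wait plus
its 25 ms modelled cost), which is between two and three 50 ms tick
periods, so it processes every third frame: 20/3 ≈ 6.67 Hz. The
downstream plug-ins are fast but can only consume what reaches them, so
the whole chain converges to the same rate, while each stage adds its own
dispatch wait to the delay against the input stream. Dropped-frame and
conservation counters are in `run$counters`; per-task telemetry rows in
`run$records`.

The same pipeline from a shell:

```sh
exec/pulsestream -pipeline "videomanager>pythonalgorithm>cppalgorithm>gui" \
  --videomanager_input ~/data/video.tif \
  --cppalgorithm_stream pythonalgorithm \
  --cppalgorithm_layer -1
```

then `stats` or `quit` at the prompt. `exec/pulsestream bench` runs the full
wait × rate characterisation grid and writes the report CSVs.

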