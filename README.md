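# netanim

Keyframe animation of styled network visualizations, headless.

Biological networks — pathways, signaling cascades, interaction maps — are
usually shown as static node-link diagrams, yet the systems they describe
change with the cell cycle, environment and treatment. Smoothly animating
between two states of the same network is one of the best ways to make such
change visible (it counters *change blindness*, the difficulty of spotting
differences between successively shown images). `netanim` is an R engine
for building such animations from **key frames**: complete snapshots of a
styled scene (nodes, edges, annotations, camera and background) at chosen
timeline positions. It is aimed at computational biologists and tool
builders who want reproducible, scriptable network movies without a GUI.

## The method

* **Capture.** A scene's four property maps (network, node, edge,
  annotation) are snapshotted with *every* registered visual property
  recorded; unset keys fill with fixed defaults, so maps are total.
* **Reconcile.** The union of objects over all key frames — the object
  universe — is computed, and every frame is completed: objects a frame
  lacks are inserted hidden (visibility `FALSE` / annotation opacity 0),
  styled from the nearest-in-time frame that has them, so they can fade in
  and out.
* **Interpolate.** Each visual property tweens by its registered kind —
  one of nine: `Color` (linear RGB, Bezier-eased alpha), `Size`,
  `Transparency`, `Position`, `ObjectPosition`, `Crossfade` (categorical
  fade-out/fade-in with the switch at t = ½), `CustomGraphicsCrossfade`
  (simultaneous image blend), `Visible` (linear opacity ramp), `None`.
  The timeline is measured in seconds and calibrated at 30 frames per
  second, so a timeline of *k* key frames with *n* interpolations per
  segment expands to **(k − 1)·n + 1** frames: 5 key frames at 30 per
  segment give 121.
* **Render & export.** A deterministic software rasterizer (bit-identical
  output across runs) draws every frame; writers produce PNG sequences,
  animated GIFs, or MP4/H.264 movies at 25 (PAL), 29.97 (NTSC), 30 or
  60 fps and any percent resolution expansion (300 = 3×).

## Worked example

Generate the built-in 13-scene demo script (overview → zoom → relabel →
degree-scaled sizes → annotations → three expression-gradient recolorings
with hold frames → custom-graphics fade-in), then inspect and render it:

```r
library(netanim)
fx <- make_script("mixed", dir = "demo", seed = 1)
netanim_cli(c("inspect", "--storyboard", fx$storyboard))
```

```
key frames: 13
universe: 5 nodes, 4 edges, 2 annotations
segment 1: 30 interpolated frames, 2 changed properties
segment 2: 30 interpolated frames, 5 changed properties
segment 3: 30 interpolated frames, 15 changed properties
segment 4: 30 interpolated frames, 30 changed properties
segment 5: 30 interpolated frames, 35 changed properties
segment 6: 30 interpolated frames, 0 changed properties
...
total frames: 361
```

Thirteen key frames, one second apart, at the 30 fps timeline calibration:
(13 − 1)·30 + 1 = 361 frames. Hold segments (identical consecutive scenes)
change 0 properties but still occupy screen time. Render it as a looping
GIF at 2× resolution:

```r
netanim_cli(c("render", "--storyboard", fx$storyboard, "--format", "gif",
              "--fps", "30", "--resolution", "200", "--loop",
              "--out", "demo/movie.gif"))
```

or drive the same pipeline from R:

```r
tl  <- storyboard_timeline(read_storyboard(fx$storyboard))
seq <- timeline_sequence(tl)            # reconcile + interpolate
length(seq$frames)                      # 361
write_mp4(seq, "demo/movie.mp4", export_settings("mp4", fps = 30),
          render_settings(640, 360, resolution_pct = 200))
```

A shell launcher for the CLI installs with the package at
`system.file("cli", "netanim", package = "netanim")`.

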