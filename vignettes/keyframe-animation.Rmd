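---
title: "Keyframe animation of styled network scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyframe animation of styled network scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netanim)
```

## The model

Biological networks are usually drawn as static node-link diagrams, but the
systems they describe are dynamic: expression levels shift, interactions
appear and disappear, attention moves from the whole map to one complex.
Motion is one of the most effective ways to convey such change — a smooth
transition between two states of the same network counters change blindness
in a way that two side-by-side stills cannot.

`netanim` implements the classical key-frame model for this task. A **key
frame** is a complete snapshot of a styled scene at one timeline position:
four property maps (network, nodes, edges, annotations) in which *every*
registered visual property of every object has a value. The engine then
interpolates between consecutive key frames, producing a dense sequence of
fully specified frames that render to a movie.

Three ideas carry the design:

1. **A total property registry.** Every visual property (fill color, width,
   label text, custom-graphics slots 1–9, …) is registered once with a value
   domain and exactly one of nine interpolation kinds. Capture records every
   registered key, filling unset ones with fixed, documented defaults
   (opaque grey `(200,200,200,255)` fill, node size 35, edge width 2,
   visibility `TRUE`, …). Totality is what makes interpolation pairs
   well-defined without per-property special cases.

2. **Reconciliation against a union universe.** Scenes in one storyboard may
   add or remove objects. The union of all object ids over the timeline — the
   *object universe*, standing in for a shared root network — is computed
   first, and every frame is completed so each universe object has defined
   properties. Objects a frame lacks are inserted *hidden* (visibility
   `FALSE` for nodes and edges, opacity 0 for annotations), with the rest of
   their style copied from the nearest-in-time frame that does contain them
   (ties go to the earlier frame). That donor policy is our choice — a hidden
   object still needs coordinates and size so that a later fade-in starts
   from a sensible state rather than from defaults at the origin. An edge
   whose endpoint is hidden is itself forced hidden, since a dangling edge is
   visually meaningless.

3. **Per-kind interpolators.** With all frames over identical object sets,
   each property tweens independently by its registered kind.

## The interpolator taxonomy

| Kind | Rule |
|------|------|
| `Color` | per-channel linear RGB, rounded half-up; alpha eased by a cubic Bezier |
| `Size` | linear |
| `Transparency` | linear on 0–255 |
| `Position` | linear x/y |
| `ObjectPosition` | linear offsets; anchor/justification changes unsupported (held, then snapped, with a warning) |
| `Crossfade` | old value fades out on `[0, 1/2]`, new value fades in on `[1/2, 1]` |
| `CustomGraphicsCrossfade` | simultaneous image blend: outgoing at `1−t` over incoming at `t` |
| `Visible` | linear opacity ramp on visibility changes |
| `None` | not interpolated: held at the start value, snapped at the segment end |

Numerical choices worth knowing:

* **Color space.** "Linear" color interpolation is done per channel in RGB —
  the simplest faithful reading; channels round half-up so endpoints are
  exact integers.
* **Bezier easing.** Alpha fades follow the y-value of a unit cubic Bezier
  at curve-x = t, solved by bisection to 1e−9 (well inside the stated 1e−6
  tolerance). The control points default to ((0.25, 0.1), (0.25, 1.0)) — the
  standard "ease" curve — and are configurable via `bezier_control()`; the
  monotonicity of x is enforced by requiring control x-coordinates in
  [0, 1]. Equal endpoints short-circuit.
* **Crossfade midpoint.** The switch happens at exactly t = 1/2 and the new
  value owns the midpoint; the multiplier ramps `1−2t`, then `2t−1`, so it is
  continuous on each half with limit 0 at the switch. Unchanged values do
  *not* fade — a crossfade is the transition to a *new* value, and applying
  the ramp to identical values would blink every categorical property on
  every segment. Label-family crossfades (label, font face/style/family,
  text) dim only the label; others dim the object body.
* **Custom graphics** blend simultaneously rather than sequentially:
  image-to-image dissolves must not pass through a fully blank midpoint.
* **Kind `None`** holds the start value until the segment end so the
  arriving key frame is always exact.
* **Transparency keys win.** Colors are RGBA, but wherever a separate
  transparency property exists (node/edge/label/border transparency,
  annotation opacity) it overrides the color's alpha channel. Opacity
  multipliers from `Visible` and `Crossfade` then compose multiplicatively —
  the only composition that keeps endpoints exact.

## Timeline arithmetic

The timeline is measured in seconds and calibrated at a fixed 30 frames per
second: a gap of `g` seconds between consecutive key frames expands to
`max(1, round(30·g))` interpolated frames (round half-up, matching the color
rounding convention). Coincident key frames clamp to a single step — an
instantaneous cut. For each segment with count `n`, frames are emitted at
local `t = i/n`, `i = 0 … n−1` (the segment start is its `i = 0` frame) and
the final key frame is appended once, so a timeline of `k` key frames with a
constant `n` yields `(k−1)·n + 1` frames — five key frames at 30 per segment
give 121. This parameterization is the unique convention that reproduces
that count with exact endpoint fidelity at every key frame.

The *export* frame rate (25 PAL, 29.97 NTSC, 30, 60) never changes the frame
count; it only sets playback timing. At 30 fps playback the movie runs in
real time against the timeline.

```{r counts}
tl <- timeline()
sc <- make_toy_network(5, 4, seed = 1)
for (j in 1:5) {
  sc$network$scale_factor <- 1 + (j - 1) / 4
  tl <- add_keyframe(tl, capture_frame(sc, j - 1, frame_id = paste0("k", j)))
}
segment_counts(tl)
length(timeline_sequence(tl)$frames)   # (5-1)*30 + 1
```

## Rendering and export

Frames rasterize through a deterministic software renderer: hard-edged
primitives, pure arithmetic, a 5×7 bitmap font defined in the package
source (so no system font can perturb pixels), no antialiasing. Identical
inputs therefore produce identical bytes, which the test suite asserts
directly. Draw order is background fill, background-canvas annotations,
edges, nodes (body, custom graphics, label), foreground-canvas annotations.
The camera maps model units to pixels through the network center and scale
factor; `Z`/depth properties are stored and interpolated but ignored by the
2D renderer. The base canvas defaults to 1280×720 and the resolution option
is a percent linear expansion (`300` → exactly 3× the dimensions); at least
2× is sensible for published video.

Three writers are provided:

* **PNG frames** — numbered files, no timing metadata.
* **Animated GIF** — an own GIF89a writer with a global color table
  (deterministic 8×8×4 RGB quantization beyond 256 colors) and LZW
  compression; per-frame delay is `round(100/fps)` centiseconds, so 29.97
  and 30 both map to 3 cs (GIF timing has centisecond granularity), and the
  loop flag writes the standard looping extension.
* **MP4/H.264** — an own baseline-profile encoder in which every picture is
  an IDR frame of I_PCM (uncompressed) macroblocks, BT.601 4:2:0, muxed
  into an ISO base-media container; 29.97 uses the NTSC 30000/1001 time
  base. I_PCM trades file size for exactness and zero dependencies — the
  natural analogue, in R, of bundling a small pure-Java codec. Output
  dimensions must be even (4:2:0 chroma plus 2-sample cropping units cannot
  express odd sizes).

The test suite verifies both movie formats by *decoding* them with
independent readers written from the format specifications (an LZW decoder
and an ISO-BMFF/NAL/I_PCM parser in the test helpers), checking frame
counts, timing, dimensions and — for MP4 — the per-pixel luma of decoded
frames against an independent BT.601 conversion of the renders.

## The fixture corpus

`make_toy_network()` and `make_script()` generate all test inputs: seeded
random graphs on a circular layout and seven key-frame scripts
(`color_sweep`, `zoom_pan`, `shape_crossfade`, `visibility_toggle`,
`annotation_fade`, `custom_graphics_swap`, and a 13-scene `mixed` movie
that zooms to a focus node, relabels, scales sizes by degree, highlights
with annotations, walks through three expression-gradient recolorings with
hold frames, and fades in per-node chart glyphs). Together the scripts touch
every interpolator kind except `None`, and output is byte-identical per
seed, with the seed recorded in file names.

What the fixtures emulate — and what they do not: they reproduce the
*kinds* of visual change a network animation exercises (topology churn,
restyling, camera moves, annotations, custom graphics), at desk scale. They
do not reproduce any particular published dataset, real expression values,
or large-network layouts, so passing tests demonstrate the engine's
arithmetic and formats, not figure-for-figure agreement with any specific
movie.

Problem sizes used throughout the suite are deliberately small — toy graphs
of ~5 nodes, canvases of 32–160 px, segments of 2–30 frames — chosen so the
whole suite exercises every path in well under a minute while still hitting
every format edge case (the 121-frame law is asserted at full size since it
is pure arithmetic).

## Known limitations

* Edge bends are not modeled; edges render as straight segments.
* Label placement is anchor+offset only; nothing is adjusted for rendered
  text extents.
* Annotation `Canvas` and nested-network visibility are `None`-kind by
  design (they snap rather than tween).
* The GIF palette quantizes hard beyond 256 colors; smooth large gradients
  can band.
* The MP4 encoder is exact but large (~0.4 bytes/pixel/frame × 3); for
  distribution-size movies, transcode the PNG frames with an external tool.
* Session bundles are a versioned JSON format of this package; no
  compatibility with any GUI host's session files is claimed.
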