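# File formats

All formats are JSON (plus GraphML import). Colors are `"#RRGGBBAA"` hex
strings (`"#RRGGBB"` accepted on read with alpha `FF`); coordinates are in
model units — the camera maps model units to pixels only at render time, so
resolution scaling never alters stored scenes.

## Scene (`*.json`)

One network state: top-level keys `network`, `nodes`, `edges`,
`annotations`. Every object carries an `id` plus visual-property
name/value pairs; unknown property names are rejected (the error names the
offending key with a JSON-pointer-style path, e.g. `/nodes/2/wobble`);
omitted properties take the documented defaults (`netanim::vp_registry()`
lists every key, domain and interpolation kind).

```json
{
  "network": { "width": 640, "height": 360, "scale_factor": 1,
               "background_paint": "#FFFFFFFF" },
  "nodes": [
    { "id": "A", "x": -60, "y": 0, "fill_color": "#1F77B4FF",
      "label": "A", "shape": "ellipse",
      "label_position": { "anchor": "s", "justification": "c",
                          "dx": 0, "dy": 14 } },
    { "id": "B", "x": 60, "y": 0, "custom_graphics_1": "glyph:ring:#D62728",
      "custom_graphics_size_1": 18 }
  ],
  "edges": [
    { "id": "e1", "source": "A", "target": "B", "width": 2,
      "line_type": "solid", "paint": "#787878FF" }
  ],
  "annotations": [
    { "id": "note", "type": "text", "canvas": "foreground",
      "x": 0, "y": -60, "text": "HELLO", "font_size": 14 }
  ]
}
```

Annotation `type` is one of `shape | text | image | arrow`; `canvas` is
`foreground | background`. Image references are PNG paths (resolved
against the storyboard directory) or procedural `glyph:disc|ring|square|
diamond:#RRGGBB` forms.

## Storyboard (`*.json`)

Scenes with timeline positions in seconds (non-decreasing; a missing
`time_s` defaults to one second after the previous entry), plus optional
export defaults that CLI flags override:

```json
{
  "scenes": [
    { "scene": "scene_01.json", "time_s": 0 },
    { "scene": "scene_02.json", "time_s": 1.5 }
  ],
  "defaults": { "format": "gif", "fps": 30, "resolution_pct": 200,
                "base_width": 640, "base_height": 360 }
}
```

Scene paths resolve relative to the storyboard file. All scenes of one
storyboard share one object universe (one network collection); an edge id
appearing with different endpoints in two scenes is an error.

## Session bundle (`*.json`)

`save_session()` embeds every captured key frame — full property maps —
and its timeline time in a single versioned document:

```json
{
  "format": "netanim-session",
  "version": 1,
  "fps_base": 30,
  "frames": [ { "frame_id": "sb_001", "time_s": 0,
                "network": { "...": "..." },
                "nodes": [ { "id": "A", "...": "..." } ],
                "edges": [], "annotations": [] } ]
}
```

The round trip `load_session(save_session(tl))` is lossless. A bundle with
a different `version` is refused with an explicit unsupported-version
error.

## GraphML import

`import_graphml()` reads topology via igraph. Node ids come from the
GraphML `id`/`name` attribute; positions from conventional `x`/`y` node
attributes when present, otherwise nodes are placed deterministically on a
circle of radius 200 model units in file order. Styles come from the
`style_defaults` argument. GraphML is import-only.
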