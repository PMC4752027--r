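{
  "network": {
    "width": 640,
    "height": 360,
    "scale_factor": 1,
    "background_paint": "#FFFFFFFF"
  },
  "nodes": [
    {
      "id": "A",
      "x": -60,
      "y": 0,
      "fill_color": "#1F77B4FF",
      "label": "A",
      "label_position": { "anchor": "s", "justification": "c", "dx": 0, "dy": 14 }
    },
    {
      "id": "B",
      "x": 60,
      "y": 0,
      "fill_color": "#FF7F0EFF",
      "label": "B",
      "custom_graphics_1": "glyph:ring:#D62728",
      "custom_graphics_size_1": 18
    }
  ],
  "edges": [
    { "id": "e1", "source": "A", "target": "B", "width": 2, "paint": "#787878FF" }
  ],
  "annotations": [
    {
      "id": "note",
      "type": "text",
      "canvas": "foreground",
      "x": 0,
      "y": -60,
      "text": "HELLO",
      "font_size": 14
    }
  ]
}
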