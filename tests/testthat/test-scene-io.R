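test_that("hex color encoding is an exact bijection", {
  expect_identical(decode_color("#FF000080"), c(255L, 0L, 0L, 128L))
  expect_identical(decode_color("#ff00aa"), c(255L, 0L, 170L, 255L))
  expect_identical(encode_color(c(255L, 0L, 0L, 128L)), "#FF000080")
  corners <- list(c(0L, 0L, 0L, 0L), c(255L, 255L, 255L, 255L),
                  c(0L, 255L, 0L, 1L), c(1L, 2L, 3L, 254L))
  for (cc in corners) expect_identical(decode_color(encode_color(cc)), cc)
  set.seed(99)
  for (i in 1:200) {
    cc <- as.integer(sample(0:255, 4L, replace = TRUE))
    expect_identical(decode_color(encode_color(cc)), cc)
  }
  expect_error(decode_color("#12345"), class = "netanim_validation_error")
  expect_error(decode_color("red"), class = "netanim_validation_error")
})

test_that("a minimal scene file parses with defaults filled in", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes": [{"id": "A", "x": 3, "fill_color": "#FF000080"}]}', path)
  sc <- read_scene(path)
  expect_length(sc$nodes, 1L)
  expect_identical(sc$nodes$A$x, 3)
  expect_identical(sc$nodes$A$fill_color, c(255L, 0L, 0L, 128L))
  expect_identical(sc$nodes$A$size, 35)  # default
})

test_that("scene validation errors carry JSON-pointer-style paths", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes": [{"id": "A", "wobble": 1}]}', path)
  expect_error(read_scene(path), "/nodes/1/wobble",
               class = "netanim_validation_error")

  path2 <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"nodes": [{"id": "A"}],',
                    '"edges": [{"id": "e9", "source": "A", "target": "Zz"}]}'),
             path2)
  expect_error(read_scene(path2), "e9", class = "netanim_validation_error")

  path3 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes": [{"id": "A", "fill_color": "notacolor"}]}', path3)
  expect_error(read_scene(path3), "/nodes/1/fill_color",
               class = "netanim_validation_error")

  expect_error(read_scene(tempfile()), class = "netanim_io_error")
})

test_that("scene write/read round trips every property map", {
  sc <- make_toy_network(5, 4, seed = 3)
  sc$annotations <- scene_state(
    nodes = list(x = list()),
    annotations = list(a1 = list(type = "text", text = "NOTE", x = 5,
                                 font_color = c(1L, 2L, 3L, 200L))))$annotations
  path <- withr::local_tempfile(fileext = ".json")
  write_scene(sc, path)
  back <- read_scene(path)
  expect_same_maps(back, sc)
})

test_that("every fixture-generated scene file parses without error", {
  dir <- withr::local_tempdir()
  for (kind in c("color_sweep", "zoom_pan", "visibility_toggle", "mixed")) {
    fx <- make_script(kind, dir = dir, seed = 4)
    for (p in fx$scenes) expect_s3_class(read_scene(p), "netanim_scene")
  }
})

test_that("the shipped example scene parses and renders", {
  p <- system.file("extdata", "example_scene.json", package = "netanim")
  sc <- read_scene(p)
  expect_length(sc$nodes, 2L)
  expect_identical(sc$nodes$B$custom_graphics_1, "glyph:ring:#D62728")
  img <- render_frame(capture_frame(sc, 0), render_settings(64, 36, 100))
  expect_identical(dim(unclass(img)), c(36L, 64L, 4L))
})

test_that("storyboards parse with defaults and resolve scene paths", {
  dir <- withr::local_tempdir()
  fx <- make_script("color_sweep", dir = dir, seed = 2)
  sb <- read_storyboard(fx$storyboard)
  expect_identical(nrow(sb$entries), 2L)
  expect_identical(sb$entries$time_s, c(0, 1))
  expect_equal(sb$defaults$fps, 30)
  tl <- storyboard_timeline(sb)
  expect_length(tl$entries, 2L)
  expect_identical(segment_counts(tl), 30L)
})

test_that("storyboard validation rejects empty and non-monotone inputs", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"scenes": []}', p)
  expect_error(read_storyboard(p), class = "netanim_validation_error")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"scenes": [{"scene": "a.json", "time_s": 2},',
                    '{"scene": "b.json", "time_s": 1}]}'), p2)
  expect_error(read_storyboard(p2), "non-decreasing",
               class = "netanim_validation_error")
})

test_that("session save/load round trips a timeline losslessly", {
  dir <- withr::local_tempdir()
  fx <- make_script("mixed", dir = dir, seed = 6)
  tl <- storyboard_timeline(read_storyboard(fx$storyboard))
  path <- withr::local_tempfile(fileext = ".json")
  save_session(tl, path)
  back <- load_session(path)
  expect_identical(timeline_times(back), timeline_times(tl))
  expect_length(back$entries, length(tl$entries))
  for (i in seq_along(tl$entries)) {
    expect_identical(back$entries[[i]]$network, tl$entries[[i]]$network)
    expect_identical(back$entries[[i]]$nodes, tl$entries[[i]]$nodes)
    expect_identical(back$entries[[i]]$edges, tl$entries[[i]]$edges)
    expect_identical(back$entries[[i]]$annotations, tl$entries[[i]]$annotations)
  }
})

test_that("an empty timeline round trips and future versions are refused", {
  path <- withr::local_tempfile(fileext = ".json")
  save_session(timeline(), path)
  expect_length(load_session(path)$entries, 0L)

  p2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "netanim-session", "version": 99, "frames": []}', p2)
  expect_error(load_session(p2), "version 99", class = "netanim_io_error")
  p3 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"frames": []}', p3)
  expect_error(load_session(p3), class = "netanim_io_error")
})

graphml_text <- function(nodes, edges, with_xy = FALSE) {
  keydef <- if (with_xy) paste0(
    '<key id="x" for="node" attr.name="x" attr.type="double"/>',
    '<key id="y" for="node" attr.name="y" attr.type="double"/>') else ""
  nodexml <- vapply(seq_along(nodes), function(i) {
    data <- if (with_xy) sprintf(
      '<data key="x">%d</data><data key="y">%d</data>', i * 10L, i * 5L) else ""
    sprintf('<node id="%s">%s</node>', nodes[[i]], data)
  }, character(1L))
  edgexml <- vapply(edges, function(e)
    sprintf('<edge source="%s" target="%s"/>', e[[1L]], e[[2L]]), character(1L))
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">', keydef,
         '<graph edgedefault="undirected">',
         paste(nodexml, collapse = ""), paste(edgexml, collapse = ""),
         '</graph></graphml>')
}

test_that("GraphML topology imports with positions or a deterministic circle", {
  p <- withr::local_tempfile(fileext = ".graphml")
  writeLines(graphml_text(c("a", "b", "c"), list(c("a", "b"), c("b", "c"))), p)
  sc <- import_graphml(p)
  expect_length(sc$nodes, 3L)
  expect_length(sc$edges, 2L)
  sc2 <- import_graphml(p)
  expect_identical(sc, sc2)          # deterministic circular layout
  expect_equal(sc$nodes$a$x, 200)    # radius 200, angle 0

  pxy <- withr::local_tempfile(fileext = ".graphml")
  writeLines(graphml_text(c("a", "b"), list(c("a", "b")), with_xy = TRUE), pxy)
  scxy <- import_graphml(pxy, style_defaults = list(shape = "rectangle"))
  expect_identical(scxy$nodes$a$x, 10)
  expect_identical(scxy$nodes$b$y, 10)
  expect_identical(scxy$nodes$a$shape, "rectangle")
})

test_that("malformed GraphML fails as a parse error", {
  p <- withr::local_tempfile(fileext = ".graphml")
  writeLines("<graphml><graph><node id=", p)
  expect_error(import_graphml(p), class = "netanim_io_error")
})
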