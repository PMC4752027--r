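test_that("an empty scene renders as a solid background", {
  sc <- scene_state(network = list(background_paint = c(10L, 20L, 30L, 255L)))
  f <- capture_frame(sc, 0)
  img <- render_frame(f, render_settings(40, 30, 100))
  expect_identical(dim(unclass(img)), c(30L, 40L, 4L))
  expect_true(all(img[, , 1L] == 10))
  expect_true(all(img[, , 2L] == 20))
  expect_true(all(img[, , 3L] == 30))
})

test_that("output dimensions scale exactly with the resolution percentage", {
  sc <- make_toy_network(4, 3, seed = 5)
  f <- capture_frame(sc, 0)
  d100 <- dim(unclass(render_frame(f, render_settings(64, 36, 100))))
  d200 <- dim(unclass(render_frame(f, render_settings(64, 36, 200))))
  d300 <- dim(unclass(render_frame(f, render_settings(64, 36, 300))))
  expect_identical(d200[1:2], 2L * d100[1:2])
  expect_identical(d300[1:2], 3L * d100[1:2])
})

test_that("a node at opacity zero renders pixel-identically to its absence", {
  with_b <- capture_frame(tiny_scene(), 0)
  with_b$nodes$B$.opacity <- 0
  with_b$nodes$B$.label_opacity <- 0
  with_b$edges$e1$props$.opacity <- 0
  without_b <- capture_frame(
    scene_state(network = tiny_scene()$network,
                nodes = list(A = tiny_scene()$nodes$A)), 0)
  rs <- render_settings(64, 36, 100)
  expect_identical(unclass(render_frame(with_b, rs)),
                   unclass(render_frame(without_b, rs)))
})

test_that("renders are bit-deterministic across runs and frame order", {
  fx <- reconcile_timeline(uniform_timeline(3)$entries)
  s <- make_frames(fx$frames, 5L)
  rs <- render_settings(64, 36, 100)
  a <- lapply(s$frames, render_frame, settings = rs)
  b <- lapply(rev(seq_along(s$frames)),
              function(i) render_frame(s$frames[[i]], rs))
  for (i in seq_along(a)) {
    expect_identical(unclass(a[[i]]), unclass(b[[length(b) - i + 1L]]))
  }
})

test_that("node fill, border and edge paint land on the canvas", {
  sc <- scene_state(
    network = list(width = 60, height = 40,
                   background_paint = c(255L, 255L, 255L, 255L)),
    nodes = list(A = list(x = -15, y = 0, width = 12, height = 12,
                          fill_color = c(255L, 0L, 0L, 255L), border_width = 0),
                 B = list(x = 15, y = 0, width = 12, height = 12,
                          fill_color = c(0L, 0L, 255L, 255L), border_width = 0)),
    edges = list(e = list(source = "A", target = "B",
                          paint = c(0L, 255L, 0L, 255L), width = 2)))
  img <- unclass(render_frame(capture_frame(sc, 0), render_settings(60, 40, 100)))
  # node centers: A at (15, 20), B at (45, 20); edge midpoint (30, 20)
  expect_identical(img[20, 15, 1:3], c(255, 0, 0))
  expect_identical(img[20, 45, 1:3], c(0, 0, 255))
  expect_identical(img[20, 30, 1:3], c(0, 255, 0))
  expect_identical(img[3, 3, 1:3], c(255, 255, 255))
})

test_that("camera scale factor magnifies distances around the center", {
  sc <- scene_state(
    network = list(width = 100, height = 100, scale_factor = 1),
    nodes = list(A = list(x = 10, y = 0, width = 4, height = 4,
                          fill_color = c(0L, 0L, 0L, 255L), border_width = 0)))
  rs <- render_settings(100, 100, 100)
  img1 <- unclass(render_frame(capture_frame(sc, 0), rs))
  sc$network$scale_factor <- 3
  img3 <- unclass(render_frame(capture_frame(sc, 0), rs))
  # at scale 1 the node sits at x=60; at scale 3 at x=80, and is larger
  expect_identical(img1[50, 60, 1:3], c(0, 0, 0))
  expect_identical(img3[50, 80, 1:3], c(0, 0, 0))
  expect_gt(sum(img3[, , 1L] == 0), sum(img1[, , 1L] == 0))
})

test_that("labels draw with the bundled bitmap font deterministically", {
  sc <- scene_state(
    network = list(width = 80, height = 40),
    nodes = list(A = list(x = 0, y = 0, width = 6, height = 6, label = "AB",
                          label_size = 14,
                          label_position = object_position("s", "c", 0, 10))))
  rs <- render_settings(80, 40, 100)
  img1 <- unclass(render_frame(capture_frame(sc, 0), rs))
  img2 <- unclass(render_frame(capture_frame(sc, 0), rs))
  expect_identical(img1, img2)
  expect_gt(sum(img1[, , 1L] == 0), 10)  # some black label pixels exist
})

test_that("non-positive render dimensions are rejected", {
  expect_error(render_settings(0, 100), class = "netanim_range_error")
  expect_error(render_settings(100, 100, 0), class = "netanim_range_error")
})
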