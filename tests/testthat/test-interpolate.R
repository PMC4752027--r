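test_that("numeric and position interpolation is linear with exact endpoints", {
  expect_identical(lerp_number(0, 10, 0.5), 5)
  expect_identical(lerp_number(7, 7, 0.3), 7)
  expect_identical(lerp_number(2, 5, 1.0), 5)
  expect_identical(lerp_number(2, 5, 0), 2)
  expect_error(lerp_number(0, 1, 1.5), class = "netanim_range_error")
  expect_error(lerp_number(0, Inf, 0.5), class = "netanim_validation_error")

  expect_identical(lerp_position(c(0, 0), c(10, 20), 0.5), c(5, 10))
  expect_identical(lerp_position(c(1, 2), c(9, 9), 1), c(9, 9))
  expect_equal(lerp_position(c(-5, 3), c(5, 3), 0.2), c(-3, 3))
})

test_that("color interpolation is per-channel linear RGB, rounded half-up", {
  black <- c(0L, 0L, 0L, 255L); white <- c(255L, 255L, 255L, 255L)
  expect_identical(lerp_color(black, white, 0.5), c(128L, 128L, 128L, 255L))
  expect_identical(lerp_color(black, white, 0), black)
  expect_identical(lerp_color(black, white, 1), white)
  # hand-computed: 12.5, 25, 37.5 -> 13, 25, 38 under round-half-up
  expect_identical(lerp_color(c(10L, 20L, 30L, 255L), c(20L, 40L, 60L, 255L), 0.25),
                   c(13L, 25L, 38L, 255L))
  expect_error(lerp_color(c(0L, 0L, 0L, 300L), white, 0.5),
               class = "netanim_validation_error")
})

test_that("bezier alpha matches a dense-sampling inversion oracle within one level", {
  ctrl <- bezier_control(c(0.25, 0.1), c(0.25, 1.0))
  expect_identical(bezier_alpha(128, 128, 0.37, ctrl), 128L)
  expect_identical(bezier_alpha(0, 255, 0, ctrl), 0L)
  expect_identical(bezier_alpha(0, 255, 1, ctrl), 255L)
  ts <- seq(0, 1, length.out = 101L)
  got <- vapply(ts, function(t) bezier_alpha(0, 255, t, ctrl), integer(1L))
  want <- vapply(ts, function(t) bezier_oracle_alpha(0, 255, t), numeric(1L))
  expect_lte(max(abs(got - want)), 1)
  # a second control curve, descending values
  ctrl2 <- bezier_control(c(0.4, 0.0), c(0.6, 1.0))
  got2 <- vapply(ts, function(t) bezier_alpha(200, 40, t, ctrl2), integer(1L))
  want2 <- vapply(ts, function(t)
    bezier_oracle_alpha(200, 40, t, c(0.4, 0), c(0.6, 1)), numeric(1L))
  expect_lte(max(abs(got2 - want2)), 1)
})

test_that("bezier controls must keep x in the unit interval", {
  expect_error(bezier_control(c(1.2, 0), c(0.3, 1)),
               class = "netanim_range_error")
})

test_that("object positions interpolate offsets and hold anchor changes", {
  op0 <- object_position("c", "c", 0, 0)
  op1 <- object_position("c", "c", 0, 10)
  mid <- lerp_object_position(op0, op1, 0.5)
  expect_identical(mid$dy, 5)
  expect_identical(lerp_object_position(op0, op0, 0.8), op0)

  opN <- object_position("n", "c", 0, 10)
  expect_warning(held <- lerp_object_position(op0, opN, 0.5), "anchor")
  expect_identical(held, op0)
  expect_warning(snapped <- lerp_object_position(op0, opN, 1), "anchor")
  expect_identical(snapped, opN)
})

test_that("categorical crossfade ramps opacity 1-2t then 2t-1 and switches at 1/2", {
  r <- crossfade_value("ellipse", "rectangle", 0)
  expect_identical(r, list(value = "ellipse", opacity = 1))
  r <- crossfade_value("ellipse", "rectangle", 1)
  expect_identical(r, list(value = "rectangle", opacity = 1))
  r <- crossfade_value("ellipse", "rectangle", 0.5)
  expect_identical(r, list(value = "rectangle", opacity = 0))
  r <- crossfade_value("ellipse", "rectangle", 0.25)
  expect_identical(r, list(value = "ellipse", opacity = 0.5))
  # unchanged values never fade
  r <- crossfade_value("ellipse", "ellipse", 0.5)
  expect_identical(r$opacity, 1)
})

test_that("crossfade multiplier is continuous off the switch with limits 0 at 1/2", {
  eps <- 1e-9
  lo <- crossfade_value("a", "b", 0.5 - eps)$opacity
  hi <- crossfade_value("a", "b", 0.5 + eps)$opacity
  expect_lt(lo, 1e-6)
  expect_lt(hi, 1e-6)
  ts <- seq(0, 0.49, by = 0.01)
  ops <- vapply(ts, function(t) crossfade_value("a", "b", t)$opacity, numeric(1L))
  expect_equal(ops, 1 - 2 * ts)
})

test_that("visibility fades are linear in t", {
  expect_identical(visibility_opacity(TRUE, FALSE, 0.25), 0.75)
  expect_identical(visibility_opacity(FALSE, TRUE, 1.0), 1)
  expect_identical(visibility_opacity(FALSE, FALSE, 0.7), 0)
  expect_identical(visibility_opacity(TRUE, TRUE, 0.2), 1)
  ts <- seq(0, 1, by = 0.1)
  expect_equal(vapply(ts, function(t) visibility_opacity(FALSE, TRUE, t),
                      numeric(1L)), ts)
})

test_that("custom graphics blend simultaneously, empty slots fade", {
  at0 <- crossfade_custom_graphics("g0.png", "g1.png", 0)
  expect_length(at0, 1L)
  expect_identical(at0[[1L]], list(ref = "g0.png", opacity = 1))
  at1 <- crossfade_custom_graphics("g0.png", "g1.png", 1)
  expect_identical(at1[[1L]], list(ref = "g1.png", opacity = 1))
  mid <- crossfade_custom_graphics("g0.png", "g1.png", 0.5)
  expect_length(mid, 2L)
  expect_identical(mid[[1L]]$opacity, 0.5)
  expect_identical(mid[[2L]]$opacity, 0.5)
  fadein <- crossfade_custom_graphics(NA_character_, "g1.png", 0.5)
  expect_length(fadein, 1L)
  expect_identical(fadein[[1L]], list(ref = "g1.png", opacity = 0.5))
})

test_that("interpolate_property dispatches on the registered kind", {
  r <- interpolate_property("width", "edge", 2, 6, 0.5)
  expect_identical(r$value, 4)
  r <- interpolate_property("canvas", "annotation", "background", "foreground", 0.5)
  expect_identical(r$value, "background")   # None holds until the segment end
  r <- interpolate_property("canvas", "annotation", "background", "foreground", 1)
  expect_identical(r$value, "foreground")
  r <- interpolate_property("x", "node", 0, 100, 0.1)
  expect_identical(r$value, 10)
  r <- interpolate_property("visible", "node", TRUE, FALSE, 0.25)
  expect_identical(r$opacity, 0.75)
})

test_that("make_frames obeys the (k-1)*n+1 count law", {
  tl5 <- uniform_timeline(5)
  rec <- reconcile_timeline(tl5$entries)
  seq5 <- make_frames(rec$frames, 30L)
  expect_length(seq5$frames, 121L)

  tl1 <- uniform_timeline(1)
  seq1 <- make_frames(reconcile_timeline(tl1$entries)$frames, 30L)
  expect_length(seq1$frames, 1L)

  tl3 <- uniform_timeline(3)
  seq3 <- make_frames(reconcile_timeline(tl3$entries)$frames, 10L)
  expect_length(seq3$frames, 21L)

  # mixed per-segment counts: total = sum(n_j) + 1
  seq_mixed <- make_frames(rec$frames, c(3L, 7L, 1L, 12L))
  expect_length(seq_mixed$frames, 3L + 7L + 1L + 12L + 1L)
})

test_that("count law holds property-style over random segment counts", {
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(2:6, 1L)
    counts <- sample(1:60, k - 1L, replace = TRUE)
    rec <- reconcile_timeline(uniform_timeline(k)$entries)
    s <- make_frames(rec$frames, counts)
    expect_length(s$frames, sum(counts) + 1L)
  }
})

test_that("segment start frames and the final frame equal their key frames exactly", {
  tl <- uniform_timeline(3)
  tl$entries[[2L]]$nodes$A$fill_color <- c(0L, 200L, 50L, 255L)
  rec <- reconcile_timeline(tl$entries)
  s <- make_frames(rec$frames, 10L)
  starts <- c(1L, 11L)
  for (j in seq_along(starts)) {
    got <- s$frames[[starts[[j]]]]
    expect_identical(got$nodes, rec$frames[[j]]$nodes)
    expect_identical(got$edges, rec$frames[[j]]$edges)
    expect_identical(got$network, rec$frames[[j]]$network)
  }
  last <- s$frames[[length(s$frames)]]
  expect_identical(last$nodes, rec$frames[[3L]]$nodes)
  expect_identical(last$network, rec$frames[[3L]]$network)
})

test_that("size, transparency and position interpolants are monotone", {
  ts <- seq(0, 1, by = 0.05)
  sizes <- vapply(ts, function(t) interpolate_property("width", "node", 10, 60, t)$value,
                  numeric(1L))
  expect_true(all(diff(sizes) >= 0))
  tra <- vapply(ts, function(t)
    interpolate_property("transparency", "node", 40, 250, t)$value, numeric(1L))
  expect_true(all(diff(tra) >= 0))
  pos <- vapply(ts, function(t) interpolate_property("y", "node", -20, 35, t)$value,
                numeric(1L))
  expect_true(all(diff(pos) >= 0))
})

test_that("make_frames validates its inputs", {
  tl <- uniform_timeline(3)
  expect_error(make_frames(tl$entries[c(1, 2)], 0L), class = "netanim_range_error")
  expect_error(make_frames(list()), class = "netanim_range_error")
  expect_error(make_frames(tl$entries, c(5L, 5L, 5L)), class = "netanim_range_error")
  # unreconciled frames (differing object sets) are rejected
  s1 <- capture_frame(tiny_scene(), 0)
  s2 <- capture_frame(scene_state(nodes = list(A = list(x = 1))), 1)
  expect_error(make_frames(list(s1, s2), 5L), class = "netanim_consistency_error")
})

test_that("a visibility toggle produces a linear fade ramp across the segment", {
  fs <- list(capture_frame(tiny_scene(), 0),
             capture_frame(scene_state(nodes = list(A = list(x = -10))), 1))
  rec <- reconcile_timeline(fs)
  s <- make_frames(rec$frames, 10L)
  # node B fades out: opacity multiplier at frame i (t = (i-1)/10) is 1 - t
  ops <- vapply(2:10, function(i) s$frames[[i]]$nodes$B$.opacity, numeric(1L))
  expect_equal(ops, 1 - (1:9) / 10)
})
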