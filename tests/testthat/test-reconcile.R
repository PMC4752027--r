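# three frames sharing a core scene; node C exists only in frames 1 and 3
three_frame_set <- function() {
  s1 <- scene_state(
    nodes = list(A = list(x = 0, y = 0), B = list(x = 50, y = 0),
                 C = list(x = 0, y = 50, fill_color = c(10L, 20L, 30L, 255L))),
    edges = list(ab = list(source = "A", target = "B"),
                 ac = list(source = "A", target = "C")))
  s2 <- scene_state(
    nodes = list(A = list(x = 0, y = 0), B = list(x = 60, y = 10)),
    edges = list(ab = list(source = "A", target = "B")))
  s3 <- scene_state(
    nodes = list(A = list(x = 0, y = 0), B = list(x = 50, y = 0),
                 C = list(x = 5, y = 55, fill_color = c(200L, 0L, 0L, 255L))),
    edges = list(ab = list(source = "A", target = "B"),
                 ac = list(source = "A", target = "C")))
  list(f1 = capture_frame(s1, 0, frame_id = "f1"),
       f2 = capture_frame(s2, 1, frame_id = "f2"),
       f3 = capture_frame(s3, 4, frame_id = "f3"))
}

test_that("the universe is the exact union of frame objects", {
  fs <- three_frame_set()
  u <- union_topology(list(fs$f1, fs$f2, fs$f3))
  expect_setequal(u$node_ids, c("A", "B", "C"))
  expect_setequal(u$edge_ids, c("ab", "ac"))
  expect_identical(u$edge_endpoints$ac, c("A", "C"))

  u1 <- union_topology(list(fs$f2))
  expect_setequal(u1$node_ids, c("A", "B"))
  expect_setequal(u1$edge_ids, "ab")
})

test_that("an edge id with different endpoints across frames is a conflict", {
  s1 <- scene_state(nodes = list(A = list(), B = list(), C = list()),
                    edges = list(e = list(source = "A", target = "B")))
  s2 <- scene_state(nodes = list(A = list(), B = list(), C = list()),
                    edges = list(e = list(source = "A", target = "C")))
  expect_error(union_topology(list(capture_frame(s1, 0), capture_frame(s2, 1))),
               "conflicting endpoints", class = "netanim_consistency_error")
})

test_that("a frame already covering the universe is returned unchanged", {
  fs <- three_frame_set()
  u <- union_topology(list(fs$f1, fs$f3))
  expect_identical(reconcile_frame(fs$f1, u, list(fs$f1, fs$f3)), fs$f1)
})

test_that("objects the frame lacks come back hidden, styled from the nearest frame", {
  fs <- three_frame_set()
  u <- union_topology(list(fs$f1, fs$f2, fs$f3))
  r2 <- reconcile_frame(fs$f2, u, list(fs$f1, fs$f2, fs$f3))
  expect_setequal(names(r2$nodes), c("A", "B", "C"))
  expect_setequal(names(r2$edges), c("ab", "ac"))
  expect_false(r2$nodes$C$visible)
  expect_false(r2$edges$ac$props$visible)
  # f2 is at t=1: C's donor is f1 (|dt| = 1) not f3 (|dt| = 3)
  expect_identical(r2$nodes$C$fill_color, fs$f1$nodes$C$fill_color)
  expect_identical(r2$nodes$C$x, fs$f1$nodes$C$x)
  # originally present objects untouched
  expect_identical(r2$nodes$A, fs$f2$nodes$A)
  expect_identical(r2$nodes$B, fs$f2$nodes$B)
})

test_that("donor ties go to the earlier frame", {
  fs <- three_frame_set()
  f3 <- fs$f3; f3$time_s <- 2  # now f1 (dt=1) and f3 (dt=1) tie for f2@1
  u <- union_topology(list(fs$f1, fs$f2, f3))
  r2 <- reconcile_frame(fs$f2, u, list(fs$f1, fs$f2, f3))
  expect_identical(r2$nodes$C$fill_color, fs$f1$nodes$C$fill_color)
})

test_that("reconciliation is idempotent and equalizes object sets", {
  fs <- three_frame_set()
  rec <- reconcile_timeline(list(fs$f1, fs$f2, fs$f3))
  idsets <- lapply(rec$frames, function(f)
    list(sort(names(f$nodes)), sort(names(f$edges)), sort(names(f$annotations))))
  expect_identical(idsets[[1L]], idsets[[2L]])
  expect_identical(idsets[[2L]], idsets[[3L]])
  for (f in rec$frames) {
    expect_identical(reconcile_frame(f, rec$universe), f)
  }
})

test_that("hidden-object counts equal universe minus original objects", {
  fs <- three_frame_set()
  u <- union_topology(list(fs$f1, fs$f2, fs$f3))
  r2 <- reconcile_frame(fs$f2, u, list(fs$f1, fs$f2, fs$f3))
  hidden_nodes <- sum(!vapply(r2$nodes, function(p) p$visible, logical(1L)))
  expect_identical(hidden_nodes, length(u$node_ids) - length(fs$f2$nodes))
})

test_that("a frame with objects outside the universe is rejected", {
  fs <- three_frame_set()
  u <- union_topology(list(fs$f2))
  expect_error(reconcile_frame(fs$f1, u), class = "netanim_consistency_error")
})

test_that("annotations missing from a frame reconcile to opacity 0", {
  s1 <- scene_state(nodes = list(A = list()),
                    annotations = list(note = list(type = "text", text = "HI",
                                                   opacity = 200)))
  s2 <- scene_state(nodes = list(A = list()))
  f1 <- capture_frame(s1, 0); f2 <- capture_frame(s2, 1)
  rec <- reconcile_timeline(list(f1, f2))
  expect_identical(rec$frames[[2L]]$annotations$note$props$opacity, 0)
  expect_identical(rec$frames[[2L]]$annotations$note$props$text, "HI")
})
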