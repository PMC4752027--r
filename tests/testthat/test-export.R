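small_sequence <- function(k = 2L, n = 5L) {
  rec <- reconcile_timeline(uniform_timeline(k)$entries)
  make_frames(rec$frames, n)
}

test_that("write_frames emits one zero-padded PNG per frame", {
  s <- small_sequence(2, 5)  # 6 frames
  dir <- withr::local_tempdir()
  paths <- write_frames(s, dir, render_settings(64, 36, 100))
  expect_length(paths, 6L)
  expect_identical(basename(paths[[1L]]), "frame_000001.png")
  expect_true(all(file.exists(paths)))
  # determinism: a second run writes byte-identical files
  dir2 <- withr::local_tempdir()
  paths2 <- write_frames(s, dir2, render_settings(64, 36, 100))
  for (i in seq_along(paths)) {
    expect_identical(readBin(paths[[i]], "raw", file.size(paths[[i]])),
                     readBin(paths2[[i]], "raw", file.size(paths2[[i]])))
  }
})

test_that("an empty sequence refuses to export", {
  s <- small_sequence()
  s$frames <- list()
  expect_error(write_frames(s, withr::local_tempdir()),
               class = "netanim_range_error")
  expect_error(write_gif(s, tempfile()), class = "netanim_range_error")
  expect_error(write_mp4(s, tempfile()), class = "netanim_range_error")
})

test_that("export settings accept only the four offered frame rates", {
  expect_identical(export_settings("gif", 25)$fps, 25)
  expect_identical(export_settings("gif", "29.97")$fps, 29.97)
  expect_identical(export_settings("mp4", 60)$fps, 60)
  expect_error(export_settings("gif", 24), class = "netanim_range_error")
  expect_error(export_settings("gif", 23.976), class = "netanim_range_error")
})

test_that("GIF round trip conserves frame count, size, delay and loop flag", {
  s <- small_sequence(3, 4)  # 9 frames
  path <- withr::local_tempfile(fileext = ".gif")
  write_gif(s, path, export_settings("gif", fps = 25, loop = TRUE),
            render_settings(64, 36, 100))
  dec <- gif_decode(path)
  expect_length(dec$frames, length(s$frames))
  expect_identical(dec$width, 64L)
  expect_identical(dec$height, 36L)
  expect_true(all(dec$delays == 4L))   # round(100/25)
  expect_true(dec$loop)

  path30 <- withr::local_tempfile(fileext = ".gif")
  write_gif(s, path30, export_settings("gif", fps = 30, loop = FALSE),
            render_settings(64, 36, 100))
  dec30 <- gif_decode(path30)
  expect_true(all(dec30$delays == 3L))  # round(100/30) = 3 (from 3.33)
  expect_false(dec30$loop)
})

test_that("GIF pixels decode back to the rendered rasters exactly", {
  s <- small_sequence(2, 3)
  rs <- render_settings(48, 32, 100)
  path <- withr::local_tempfile(fileext = ".gif")
  write_gif(s, path, export_settings("gif", 30), rs)
  dec <- gif_decode(path)
  for (i in seq_along(s$frames)) {
    want <- unclass(render_frame(s$frames[[i]], rs))[, , 1:3]
    got <- gif_frame_rgb(dec, i)
    expect_identical(got * 1.0, want)
  }
})

test_that("MP4 structure carries the right sample count, timing and dimensions", {
  s <- small_sequence(2, 5)  # 6 frames
  rs <- render_settings(64, 36, 100)
  path <- withr::local_tempfile(fileext = ".mp4")
  write_mp4(s, path, export_settings("mp4", 30), rs)
  info <- mp4_read(path)
  expect_identical(info$n_samples, 6)
  expect_identical(info$stts_count, 6)
  expect_identical(info$timescale, 30)
  expect_identical(info$delta, 1)
  expect_equal(info$duration / info$timescale, 6 / 30)
  expect_identical(info$width, 64L)
  expect_identical(info$height, 36L)
})

test_that("the NTSC rate is written with the 30000/1001 time base", {
  s <- small_sequence(2, 2)
  path <- withr::local_tempfile(fileext = ".mp4")
  write_mp4(s, path, export_settings("mp4", 29.97), render_settings(32, 32, 100))
  info <- mp4_read(path)
  expect_identical(info$timescale, 30000)
  expect_identical(info$delta, 1001)
})

test_that("decoded I_PCM luma matches an independent BT.601 conversion of the render", {
  s <- small_sequence(2, 2)  # 3 frames
  rs <- render_settings(64, 36, 100)
  path <- withr::local_tempfile(fileext = ".mp4")
  write_mp4(s, path, export_settings("mp4", 30), rs)
  info <- mp4_read(path, decode_frames = c(1L, 3L))
  for (i in c(1L, 3L)) {
    img <- render_frame(s$frames[[i]], rs)
    wantY <- luma_bt601(img)
    gotY <- info$planes[[as.character(i)]]$Y[seq_len(36), seq_len(64)]
    expect_lte(max(abs(gotY - wantY)), 1)
  }
})

test_that("a one-frame sequence still yields a valid one-sample MP4", {
  s <- small_sequence(1, 1)
  expect_length(s$frames, 1L)
  path <- withr::local_tempfile(fileext = ".mp4")
  write_mp4(s, path, export_settings("mp4", 30), render_settings(32, 32, 100))
  info <- mp4_read(path, decode_frames = 1L)
  expect_identical(info$n_samples, 1)
  expect_length(info$planes, 1L)
})

test_that("odd MP4 dimensions fail with an actionable message", {
  s <- small_sequence(2, 2)
  expect_error(write_mp4(s, tempfile(), export_settings("mp4", 30),
                         render_settings(63, 36, 100)),
               "even", class = "netanim_range_error")
})
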