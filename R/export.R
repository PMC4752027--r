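# Export back ends: PNG frame sequences, animated GIF (own GIF89a/LZW
# writer), and MP4/H.264 (own baseline encoder using I_PCM macroblocks,
# every picture an IDR, muxed into an ISO base-media container). The
# offered frame rates are the two broadcast standards, 25 (PAL) and 29.97
# (NTSC), plus 30 and 60; the frame rate only sets playback timing -- the
# number of frames always comes from the timeline's 30 fps calibration.

#' Export settings
#'
#' @param format One of `"frames"` (PNG files), `"gif"`, `"mp4"`.
#' @param fps Frames per second for timed formats: 25, 29.97, 30 or 60.
#' @param loop For GIF only: loop forever instead of stopping at the end.
#' @return A `netanim_export_settings` object.
#' @export
export_settings <- function(format = c("frames", "gif", "mp4"), fps = 30,
                            loop = FALSE) {
  format <- match.arg(format)
  fps <- check_fps(fps)
  structure(list(format = format, fps = fps, loop = isTRUE(loop)),
            class = "netanim_export_settings")
}

check_fps <- function(fps) {
  allowed <- c(25, 29.97, 30, 60)
  if (is.character(fps)) fps <- suppressWarnings(as.numeric(fps))
  if (!(is.numeric(fps) && length(fps) == 1L && !is.na(fps) &&
        any(abs(fps - allowed) < 1e-9))) {
    stop(netanim_error(
      sprintf("fps must be one of 25, 29.97, 30, 60 (got %s)",
              paste(fps, collapse = ",")),
      class = "netanim_range_error"))
  }
  allowed[which.min(abs(fps - allowed))]
}

# Render every frame of a sequence; returns list of netanim_raster arrays.
render_sequence <- function(seq, settings = render_settings(),
                            assets_dir = NULL) {
  if (!is_sequence(seq)) stop(netanim_error("expected a netanim_sequence"))
  lapply(seq$frames, render_frame, settings = settings,
         assets_dir = assets_dir)
}

#' Write a frame sequence as numbered PNG files
#'
#' One PNG per interpolated frame, named `frame_000001.png`,
#' `frame_000002.png`, ... No timing metadata is written (individual frames
#' carry no time encoding); feed them to any movie tool.
#'
#' @param seq A `netanim_sequence` from [make_frames()] /
#'   [timeline_sequence()].
#' @param dir Output directory (created if missing).
#' @param settings A [render_settings()].
#' @param assets_dir Optional directory for image references.
#' @return Character vector of the files written, invisibly.
#' @export
write_frames <- function(seq, dir, settings = render_settings(),
                         assets_dir = NULL) {
  if (!is_sequence(seq) || !length(seq$frames))
    stop(netanim_error("nothing to export: empty frame sequence",
                       class = "netanim_range_error"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir))
    stop(netanim_error(sprintf("cannot create output directory '%s'", dir),
                       class = "netanim_io_error"))
  paths <- character(length(seq$frames))
  for (i in seq_along(seq$frames)) {
    img <- render_frame(seq$frames[[i]], settings, assets_dir)
    paths[[i]] <- file.path(dir, sprintf("frame_%06d.png", i))
    png::writePNG(unclass(img) / 255, paths[[i]])
  }
  invisible(paths)
}

## ---- GIF --------------------------------------------------------------

u16le <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))

# Flatten rasters to palette indices + palette. Over 256 unique colors the
# image is quantized to an 8x8x4 RGB grid (level centers), deterministically.
gif_palettize <- function(rasters) {
  keys <- lapply(rasters, function(img) {
    img <- unclass(img)
    img[, , 1L] * 65536 + img[, , 2L] * 256 + img[, , 3L]
  })
  uniq <- sort(unique(unlist(lapply(keys, unique))))
  if (length(uniq) > 256L) {
    quant <- function(img) {
      r <- 32 * (img[, , 1L] %/% 32) + 16
      g <- 32 * (img[, , 2L] %/% 32) + 16
      b <- 64 * (img[, , 3L] %/% 64) + 32
      r * 65536 + g * 256 + b
    }
    keys <- lapply(rasters, function(img) quant(unclass(img)))
    uniq <- sort(unique(unlist(lapply(keys, unique))))
  }
  idx <- lapply(keys, function(k) {
    m <- match(k, uniq) - 1L
    matrix(m, nrow = nrow(k))
  })
  pal <- cbind(uniq %/% 65536, (uniq %/% 256) %% 256, uniq %% 256)
  list(palette = pal, indices = idx)
}

gif_subblocks <- function(bytes) {
  out <- raw()
  pos <- 1L
  n <- length(bytes)
  chunks <- list()
  while (pos <= n) {
    end <- min(pos + 254L, n)
    chunks[[length(chunks) + 1L]] <- c(as.raw(end - pos + 1L), bytes[pos:end])
    pos <- end + 1L
  }
  c(do.call(c, chunks), as.raw(0L))
}

#' Write a frame sequence as an animated GIF
#'
#' Frames are rendered, mapped to a global color table (quantized to at
#' most 256 colors), LZW-compressed and written as a GIF89a stream. The
#' per-frame delay is `round(100 / fps)` centiseconds -- GIF timing has
#' centisecond granularity, so 29.97 and 30 fps both map to 3 cs.
#'
#' @param seq A `netanim_sequence`.
#' @param path Output file.
#' @param export An [export_settings()] (uses `fps` and `loop`).
#' @param settings A [render_settings()].
#' @param assets_dir Optional directory for image references.
#' @return `path`, invisibly.
#' @export
write_gif <- function(seq, path, export = export_settings("gif"),
                      settings = render_settings(), assets_dir = NULL) {
  if (!is_sequence(seq) || !length(seq$frames))
    stop(netanim_error("nothing to export: empty frame sequence",
                       class = "netanim_range_error"))
  rasters <- render_sequence(seq, settings, assets_dir)
  pal <- gif_palettize(rasters)
  ncol_pal <- nrow(pal$palette)
  bits <- max(2L, ceiling(log2(ncol_pal)))
  gct_n <- 2L^bits
  delay <- as.integer(round_half_up(100 / export$fps))
  W <- dim(rasters[[1L]])[2L]; H <- dim(rasters[[1L]])[1L]

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("GIF89a"), con)
  writeBin(c(u16le(W), u16le(H)), con)
  writeBin(as.raw(c(bitwOr(bitwOr(0x80L, 0x70L), bits - 1L), 0L, 0L)), con)
  gct <- matrix(0L, gct_n, 3L)
  gct[seq_len(ncol_pal), ] <- pal$palette
  writeBin(as.raw(t(gct)), con)
  if (export$loop) {
    writeBin(c(as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
               as.raw(c(3, 1)), u16le(0L), as.raw(0)), con)
  }
  min_code <- max(2L, bits)
  for (i in seq_along(rasters)) {
    writeBin(c(as.raw(c(0x21, 0xF9, 0x04, 0x04)), u16le(delay),
               as.raw(c(0, 0))), con)
    writeBin(c(as.raw(0x2C), u16le(0L), u16le(0L), u16le(W), u16le(H),
               as.raw(0)), con)
    # GIF scans row-major from the top-left; indices are [row, col]
    stream <- as.integer(t(pal$indices[[i]]))
    lz <- .lzw_encode_gif(stream, min_code)
    writeBin(c(as.raw(min_code), gif_subblocks(lz)), con)
  }
  writeBin(as.raw(0x3B), con)
  invisible(path)
}

## ---- MP4 / H.264 ------------------------------------------------------

# MSB-first bit writer for the few dozen header bits of the SPS/PPS.
bitw_new <- function() new.env(parent = emptyenv())
bitw_init <- function(bw) { bw$bits <- integer() ; bw }
bitw_put <- function(bw, v, n) {
  bw$bits <- c(bw$bits, as.integer(bitwAnd(bitwShiftR(as.integer(v),
                                                      (n - 1L):0L), 1L)))
}
bitw_ue <- function(bw, v) {
  vp1 <- v + 1L
  nb <- floor(log2(vp1)) + 1L
  if (nb > 1L) bitw_put(bw, 0L, nb - 1L)
  bitw_put(bw, vp1, nb)
}
bitw_trailing <- function(bw) {
  bitw_put(bw, 1L, 1L)
  while (length(bw$bits) %% 8L != 0L) bitw_put(bw, 0L, 1L)
}
bitw_bytes <- function(bw) {
  m <- matrix(bw$bits, nrow = 8L)
  as.raw(colSums(m * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L)))
}

# Sequence parameter set: baseline profile, progressive, 4:2:0, POC type 2,
# optional cropping for dimensions that are not multiples of 16.
h264_sps <- function(width, height) {
  mbw <- ceiling(width / 16); mbh <- ceiling(height / 16)
  crop_r <- (mbw * 16 - width) / 2
  crop_b <- (mbh * 16 - height) / 2
  bw <- bitw_init(bitw_new())
  bitw_put(bw, 66L, 8L)          # profile_idc: baseline
  bitw_put(bw, 0L, 8L)           # constraint flags + reserved
  bitw_put(bw, 40L, 8L)          # level_idc 4.0
  bitw_ue(bw, 0L)                # seq_parameter_set_id
  bitw_ue(bw, 0L)                # log2_max_frame_num_minus4
  bitw_ue(bw, 2L)                # pic_order_cnt_type
  bitw_ue(bw, 0L)                # max_num_ref_frames
  bitw_put(bw, 0L, 1L)           # gaps_in_frame_num_value_allowed
  bitw_ue(bw, mbw - 1L)          # pic_width_in_mbs_minus1
  bitw_ue(bw, mbh - 1L)          # pic_height_in_map_units_minus1
  bitw_put(bw, 1L, 1L)           # frame_mbs_only_flag
  bitw_put(bw, 0L, 1L)           # direct_8x8_inference_flag
  if (crop_r > 0 || crop_b > 0) {
    bitw_put(bw, 1L, 1L)         # frame_cropping_flag
    bitw_ue(bw, 0L); bitw_ue(bw, as.integer(crop_r))
    bitw_ue(bw, 0L); bitw_ue(bw, as.integer(crop_b))
  } else {
    bitw_put(bw, 0L, 1L)
  }
  bitw_put(bw, 0L, 1L)           # vui_parameters_present_flag
  bitw_trailing(bw)
  c(as.raw(0x67), .escape_rbsp(bitw_bytes(bw)))
}

h264_pps <- function() {
  bw <- bitw_init(bitw_new())
  bitw_ue(bw, 0L)                # pic_parameter_set_id
  bitw_ue(bw, 0L)                # seq_parameter_set_id
  bitw_put(bw, 0L, 1L)           # entropy_coding_mode_flag: CAVLC
  bitw_put(bw, 0L, 1L)           # bottom_field_pic_order_in_frame_present
  bitw_ue(bw, 0L)                # num_slice_groups_minus1
  bitw_ue(bw, 0L)                # num_ref_idx_l0_default_active_minus1
  bitw_ue(bw, 0L)                # num_ref_idx_l1_default_active_minus1
  bitw_put(bw, 0L, 1L)           # weighted_pred_flag
  bitw_put(bw, 0L, 2L)           # weighted_bipred_idc
  bitw_ue(bw, 0L)                # pic_init_qp_minus26: se(0)
  bitw_ue(bw, 0L)                # pic_init_qs_minus26: se(0)
  bitw_ue(bw, 0L)                # chroma_qp_index_offset: se(0)
  bitw_put(bw, 0L, 1L)           # deblocking_filter_control_present_flag
  bitw_put(bw, 0L, 1L)           # constrained_intra_pred_flag
  bitw_put(bw, 0L, 1L)           # redundant_pic_cnt_present_flag
  bitw_trailing(bw)
  c(as.raw(0x68), .escape_rbsp(bitw_bytes(bw)))
}

# BT.601 limited-range RGB -> YCbCr planes; chroma subsampled 2x2 by mean.
# Samples clamp to [1, 255]: PCM sample values of 0 are not permitted.
rgb_to_ycbcr420 <- function(img) {
  img <- unclass(img)
  R <- img[, , 1L]; G <- img[, , 2L]; B <- img[, , 3L]
  Y <- 16 + (65.481 * R + 128.553 * G + 24.966 * B) / 255
  Cb <- 128 + (-37.797 * R - 74.203 * G + 112 * B) / 255
  Cr <- 128 + (112 * R - 93.786 * G - 18.214 * B) / 255
  sub2 <- function(P) {
    h <- nrow(P); w <- ncol(P)
    (P[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
     P[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
     P[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
     P[seq(2, h, 2), seq(2, w, 2), drop = FALSE]) / 4
  }
  clamp <- function(P) {
    P <- round_half_up(P)
    P[P < 1] <- 1; P[P > 255] <- 255
    matrix(as.integer(P), nrow(P))
  }
  list(Y = clamp(Y), Cb = clamp(sub2(Cb)), Cr = clamp(sub2(Cr)))
}

pad_to_multiple <- function(P, mult) {
  h <- nrow(P); w <- ncol(P)
  H <- ceiling(h / mult) * mult; W <- ceiling(w / mult) * mult
  if (H > h) P <- P[c(seq_len(h), rep(h, H - h)), , drop = FALSE]
  if (W > w) P <- P[, c(seq_len(w), rep(w, W - w)), drop = FALSE]
  P
}

mp4_fps_timebase <- function(fps) {
  if (abs(fps - 29.97) < 1e-9) list(timescale = 30000L, delta = 1001L)
  else list(timescale = as.integer(fps), delta = 1L)
}

u32be <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "big")
u16be <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "big")
mp4_box <- function(type, ...) {
  payload <- c(...)
  c(u32be(8L + length(payload)), charToRaw(type), payload)
}
mp4_matrix_identity <- function() {
  c(u32be(0x00010000L), u32be(0L), u32be(0L),
    u32be(0L), u32be(0x00010000L), u32be(0L),
    u32be(0L), u32be(0L), u32be(0x40000000L))
}

mp4_moov <- function(n, width, height, tb, sample_sizes, chunk_offset,
                     sps, pps) {
  dur <- n * tb$delta
  mvhd <- mp4_box("mvhd", u32be(0L), u32be(0L), u32be(0L),
                  u32be(tb$timescale), u32be(dur),
                  u32be(0x00010000L), u16be(0x0100L), u16be(0L),
                  u32be(0L), u32be(0L), mp4_matrix_identity(),
                  do.call(c, rep(list(u32be(0L)), 6L)), u32be(2L))
  tkhd <- mp4_box("tkhd", as.raw(c(0, 0, 0, 3)), u32be(0L), u32be(0L),
                  u32be(1L), u32be(0L), u32be(dur),
                  u32be(0L), u32be(0L), u16be(0L), u16be(0L), u16be(0L),
                  u16be(0L), mp4_matrix_identity(),
                  u32be(width * 65536L), u32be(height * 65536L))
  mdhd <- mp4_box("mdhd", u32be(0L), u32be(0L), u32be(0L),
                  u32be(tb$timescale), u32be(dur), u16be(0x55C4L), u16be(0L))
  hdlr <- mp4_box("hdlr", u32be(0L), u32be(0L), charToRaw("vide"),
                  u32be(0L), u32be(0L), u32be(0L),
                  charToRaw("netanim video"), as.raw(0L))
  avcC <- mp4_box("avcC", as.raw(c(1L, as.integer(sps[2:4]), 0xFF, 0xE1)),
                  u16be(length(sps)), sps, as.raw(1L),
                  u16be(length(pps)), pps)
  avc1 <- mp4_box("avc1", as.raw(rep(0L, 6L)), u16be(1L),
                  u16be(0L), u16be(0L), u32be(0L), u32be(0L), u32be(0L),
                  u16be(width), u16be(height),
                  u32be(0x00480000L), u32be(0x00480000L), u32be(0L),
                  u16be(1L), as.raw(rep(0L, 32L)), u16be(24L), u16be(0xFFFFL),
                  avcC)
  stsd <- mp4_box("stsd", u32be(0L), u32be(1L), avc1)
  stts <- mp4_box("stts", u32be(0L), u32be(1L), u32be(n), u32be(tb$delta))
  stsc <- mp4_box("stsc", u32be(0L), u32be(1L), u32be(1L), u32be(n), u32be(1L))
  stsz <- mp4_box("stsz", u32be(0L), u32be(0L), u32be(n),
                  do.call(c, lapply(sample_sizes, u32be)))
  stco <- mp4_box("stco", u32be(0L), u32be(1L), u32be(chunk_offset))
  stbl <- mp4_box("stbl", stsd, stts, stsc, stsz, stco)
  vmhd <- mp4_box("vmhd", as.raw(c(0, 0, 0, 1)), u16be(0L),
                  u16be(0L), u16be(0L), u16be(0L))
  dref <- mp4_box("dref", u32be(0L), u32be(1L),
                  mp4_box("url ", as.raw(c(0, 0, 0, 1))))
  dinf <- mp4_box("dinf", dref)
  minf <- mp4_box("minf", vmhd, dinf, stbl)
  mdia <- mp4_box("mdia", mdhd, hdlr, minf)
  trak <- mp4_box("trak", tkhd, mdia)
  mp4_box("moov", mvhd, trak)
}

#' Write a frame sequence as an MP4/H.264 movie
#'
#' Frames are rendered, converted to 4:2:0 YCbCr (BT.601) and encoded as an
#' H.264 baseline stream in which every picture is an IDR frame made of
#' I_PCM (uncompressed) macroblocks, then muxed into an ISO MP4 container
#' at the requested frame rate (29.97 is written with the NTSC 30000/1001
#' time base). The encoder trades file size for exactness and zero external
#' dependencies; producing an MP4 is the most expensive of the three output
#' types. Output pixel dimensions must be even (a 4:2:0 chroma
#' requirement).
#'
#' @inheritParams write_gif
#' @return `path`, invisibly.
#' @export
write_mp4 <- function(seq, path, export = export_settings("mp4"),
                      settings = render_settings(), assets_dir = NULL) {
  if (!is_sequence(seq) || !length(seq$frames))
    stop(netanim_error("nothing to export: empty frame sequence",
                       class = "netanim_range_error"))
  dims <- output_dims(settings)
  W <- dims[["width"]]; H <- dims[["height"]]
  if (W %% 2L != 0L || H %% 2L != 0L) {
    stop(netanim_error(sprintf(
      "MP4 output dimensions must be even (got %dx%d): 4:2:0 chroma cannot express odd sizes; adjust base dimensions or resolution",
      W, H), class = "netanim_range_error"))
  }
  sps <- h264_sps(W, H)
  pps <- h264_pps()
  samples <- vector("list", length(seq$frames))
  for (i in seq_along(seq$frames)) {
    img <- render_frame(seq$frames[[i]], settings, assets_dir)
    pl <- rgb_to_ycbcr420(img)
    Y <- pad_to_multiple(pl$Y, 16L)
    Cb <- pad_to_multiple(pl$Cb, 8L)
    Cr <- pad_to_multiple(pl$Cr, 8L)
    nal <- .h264_ipcm_slice(Y, Cb, Cr, (i - 1L) %% 2L)
    samples[[i]] <- c(u32be(length(nal)), nal)
  }
  sizes <- vapply(samples, length, integer(1L))
  tb <- mp4_fps_timebase(export$fps)
  ftyp <- mp4_box("ftyp", charToRaw("isom"), u32be(512L),
                  charToRaw("isom"), charToRaw("iso2"),
                  charToRaw("avc1"), charToRaw("mp41"))
  mdat <- mp4_box("mdat", do.call(c, samples))
  chunk_offset <- length(ftyp) + 8L
  moov <- mp4_moov(length(samples), W, H, tb, sizes, chunk_offset, sps, pps)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(ftyp, con); writeBin(mdat, con); writeBin(moov, con)
  invisible(path)
}
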