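# Shared fixtures plus independent decoders used as oracles: a GIF89a/LZW
# reader, an ISO-BMFF + H.264 I_PCM reader, and a dense-sampling Bezier
# inverter. These are written directly from the file-format definitions and
# share no code with the package's writers.

tiny_scene <- function(fill = c(255L, 0L, 0L, 255L)) {
  scene_state(
    network = list(width = 64, height = 36, background_paint = c(255L, 255L, 255L, 255L)),
    nodes = list(
      A = list(x = -10, y = 0, fill_color = fill, label = "A"),
      B = list(x = 12, y = 4)),
    edges = list(e1 = list(source = "A", target = "B")))
}

# k key frames over the same two-node scene, 1 s apart, with a moving node
uniform_timeline <- function(k, dt = 1) {
  tl <- timeline()
  for (i in seq_len(k)) {
    sc <- tiny_scene()
    sc$nodes$A$x <- -10 + 4 * (i - 1)
    tl <- add_keyframe(tl, capture_frame(sc, (i - 1) * dt,
                                         frame_id = sprintf("f%d", i)))
  }
  tl
}

expect_same_maps <- function(a, b) {
  expect_identical(a$network, b$network)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_identical(a$annotations, b$annotations)
}

## ---- independent Bezier oracle ---------------------------------------

# dense sampling of the unit cubic Bezier, numerical inversion of x
bezier_oracle_ease <- function(t, p1, p2, n = 1e5) {
  u <- seq(0, 1, length.out = n)
  bx <- 3 * (1 - u)^2 * u * p1[[1]] + 3 * (1 - u) * u^2 * p2[[1]] + u^3
  by <- 3 * (1 - u)^2 * u * p1[[2]] + 3 * (1 - u) * u^2 * p2[[2]] + u^3
  stats::approx(bx, by, xout = t, ties = "ordered")$y
}

bezier_oracle_alpha <- function(a0, a1, t, p1 = c(0.25, 0.1), p2 = c(0.25, 1)) {
  if (a0 == a1) return(a0)
  floor(a0 + bezier_oracle_ease(t, p1, p2) * (a1 - a0) + 0.5)
}

## ---- independent GIF decoder -----------------------------------------

gif_u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}

gif_lzw_decode <- function(bytes, min_code_size, npix) {
  clear <- bitwShiftL(1L, min_code_size)
  eoi <- clear + 1L
  bits <- as.integer(rawToBits(bytes))  # already LSB-first per byte
  pos <- 1L
  read_code <- function(width) {
    v <- 0L
    for (b in 0:(width - 1L)) {
      v <- v + bitwShiftL(bits[pos + b], b)
    }
    pos <<- pos + width
    v
  }
  out <- integer(npix)
  nout <- 0L
  reset <- function() {
    dict <<- vector("list", 4096L)
    for (i in seq_len(clear)) dict[[i]] <<- i - 1L
    width <<- min_code_size + 1L
    next_code <<- eoi + 1L
    prev <<- NULL
  }
  dict <- NULL; width <- NULL; next_code <- NULL; prev <- NULL
  reset()
  repeat {
    code <- read_code(width)
    if (code == clear) { reset(); next }
    if (code == eoi) break
    if (code < next_code && !is.null(dict[[code + 1L]])) {
      entry <- dict[[code + 1L]]
    } else if (code == next_code && !is.null(prev)) {
      entry <- c(prev, prev[[1L]])
    } else stop("corrupt LZW stream")
    out[(nout + 1L):(nout + length(entry))] <- entry
    nout <- nout + length(entry)
    if (!is.null(prev) && next_code < 4096L) {
      dict[[next_code + 1L]] <- c(prev, entry[[1L]])
      next_code <- next_code + 1L
      if (next_code == bitwShiftL(1L, width) && width < 12L)
        width <- width + 1L
    }
    prev <- entry
    if (nout >= npix) break
  }
  out[seq_len(nout)]
}

# Returns list(width, height, loop, frames = list of integer index
# matrices [h x w]), delays (cs), palette (n x 3).
gif_decode <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  stopifnot(rawToChar(bytes[1:6]) == "GIF89a")
  w <- gif_u16(bytes, 7L); h <- gif_u16(bytes, 9L)
  packed <- as.integer(bytes[11L])
  stopifnot(bitwAnd(packed, 0x80L) != 0L)  # global color table present
  gct_bits <- bitwAnd(packed, 0x07L) + 1L
  gct_n <- bitwShiftL(1L, gct_bits)
  pos <- 14L
  palette <- matrix(as.integer(bytes[pos:(pos + 3L * gct_n - 1L)]),
                    ncol = 3L, byrow = TRUE)
  pos <- pos + 3L * gct_n
  frames <- list(); delays <- integer(); loop <- FALSE
  repeat {
    marker <- as.integer(bytes[pos])
    if (marker == 0x3B) break
    if (marker == 0x21) {
      label <- as.integer(bytes[pos + 1L])
      if (label == 0xF9) {
        delays <- c(delays, gif_u16(bytes, pos + 4L))
        pos <- pos + 8L
      } else {
        pos <- pos + 2L
        if (label == 0xFF &&
            rawToChar(bytes[(pos + 1L):(pos + 11L)]) == "NETSCAPE2.0")
          loop <- TRUE
        repeat {  # skip sub-blocks
          n <- as.integer(bytes[pos])
          pos <- pos + 1L + n
          if (n == 0L) break
        }
      }
    } else if (marker == 0x2C) {
      fw <- gif_u16(bytes, pos + 5L); fh <- gif_u16(bytes, pos + 7L)
      stopifnot(as.integer(bytes[pos + 9L]) == 0L)  # no local color table
      pos <- pos + 10L
      min_code <- as.integer(bytes[pos]); pos <- pos + 1L
      data <- raw()
      repeat {
        n <- as.integer(bytes[pos])
        if (n == 0L) { pos <- pos + 1L; break }
        data <- c(data, bytes[(pos + 1L):(pos + n)])
        pos <- pos + 1L + n
      }
      idx <- gif_lzw_decode(data, min_code, fw * fh)
      frames[[length(frames) + 1L]] <- matrix(idx, nrow = fh, byrow = TRUE)
    } else stop("unexpected GIF block marker: ", marker)
  }
  list(width = w, height = h, loop = loop, frames = frames,
       delays = delays, palette = palette)
}

# RGB array (h x w x 3, 0-255) of one decoded GIF frame
gif_frame_rgb <- function(dec, i) {
  idx <- dec$frames[[i]]
  arr <- array(0L, c(nrow(idx), ncol(idx), 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(dec$palette[idx + 1L, ch], nrow(idx))
  arr
}

## ---- independent MP4 / H.264 I_PCM reader ----------------------------

be32 <- function(bytes, pos) {
  sum(as.integer(bytes[pos:(pos + 3L)]) * c(16777216, 65536, 256, 1))
}

# find a (possibly nested) box payload by path, e.g. c("moov","mvhd").
# Some containers carry fixed fields before their child boxes: stsd has an
# 8-byte version/entry-count header, an avc1 sample entry 78 bytes of
# sample-entry fields.
mp4_find <- function(bytes, path, start = 1L, end = length(bytes)) {
  skip_into <- c(stsd = 8L, avc1 = 78L)
  pos <- start
  while (pos + 7L <= end) {
    sz <- be32(bytes, pos)
    if (sz < 8L) stop("corrupt box size")
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    if (type == path[[1L]]) {
      inner <- pos + 8L + if (type %in% names(skip_into)) skip_into[[type]] else 0L
      if (length(path) == 1L) return(list(start = pos + 8L, end = pos + sz - 1L))
      return(mp4_find(bytes, path[-1L], inner, pos + sz - 1L))
    }
    pos <- pos + sz
  }
  NULL
}

msb_reader <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bits <- as.integer(rawToBits(bytes))
  # rawToBits is LSB-first per byte; reorder to MSB-first
  env$bits <- as.vector(matrix(env$bits, nrow = 8L)[8:1, ])
  env$pos <- 1L
  env
}
rd_bits <- function(r, n) {
  v <- 0L
  for (i in seq_len(n)) {
    v <- v * 2L + r$bits[r$pos]
    r$pos <- r$pos + 1L
  }
  v
}
rd_ue <- function(r) {
  nz <- 0L
  while (r$bits[r$pos] == 0L) { nz <- nz + 1L; r$pos <- r$pos + 1L }
  rd_bits(r, nz + 1L) - 1L
}

unescape_ebsp <- function(bytes) {
  n <- length(bytes)
  if (n < 3L) return(bytes)
  drop <- logical(n)
  zeros <- 0L
  for (i in seq_len(n)) {
    b <- as.integer(bytes[i])
    if (zeros >= 2L && b == 3L) {
      drop[i] <- TRUE
      zeros <- 0L
    } else {
      zeros <- if (b == 0L) zeros + 1L else 0L
    }
  }
  bytes[!drop]
}

# Parse SPS for dimensions (baseline, POC type 2, as this package emits)
h264_parse_sps <- function(sps) {
  r <- msb_reader(unescape_ebsp(sps[-1L]))  # skip NAL header byte
  rd_bits(r, 24L)                 # profile, constraints, level
  rd_ue(r)                        # sps id
  rd_ue(r)                        # log2_max_frame_num_minus4
  poc_type <- rd_ue(r)
  stopifnot(poc_type == 2L)
  rd_ue(r)                        # max_num_ref_frames
  rd_bits(r, 1L)                  # gaps allowed
  mbw <- rd_ue(r) + 1L
  mbh <- rd_ue(r) + 1L
  rd_bits(r, 1L)                  # frame_mbs_only
  rd_bits(r, 1L)                  # direct_8x8
  crop <- rd_bits(r, 1L)
  cr <- c(0L, 0L, 0L, 0L)
  if (crop == 1L) cr <- c(rd_ue(r), rd_ue(r), rd_ue(r), rd_ue(r))
  list(width = mbw * 16L - 2L * (cr[[1L]] + cr[[2L]]),
       height = mbh * 16L - 2L * (cr[[3L]] + cr[[4L]]),
       mbw = mbw, mbh = mbh)
}

# Decode one I_PCM IDR slice NAL into Y, Cb, Cr planes
h264_decode_ipcm <- function(nal, mbw, mbh) {
  stopifnot(bitwAnd(as.integer(nal[1L]), 0x1FL) == 5L)  # IDR slice
  payload <- unescape_ebsp(nal[-1L])
  r <- msb_reader(payload)
  stopifnot(rd_ue(r) == 0L)       # first_mb_in_slice
  stopifnot(rd_ue(r) == 7L)       # slice_type I
  rd_ue(r)                        # pps id
  rd_bits(r, 4L)                  # frame_num
  rd_ue(r)                        # idr_pic_id
  rd_bits(r, 2L)                  # dec_ref_pic_marking
  stopifnot(rd_bits(r, 1L) == 1L) # slice_qp_delta se(0)
  Y <- matrix(0L, mbh * 16L, mbw * 16L)
  Cb <- matrix(0L, mbh * 8L, mbw * 8L)
  Cr <- matrix(0L, mbh * 8L, mbw * 8L)
  for (my in seq_len(mbh) - 1L) {
    for (mx in seq_len(mbw) - 1L) {
      stopifnot(rd_ue(r) == 25L)  # I_PCM
      if ((r$pos - 1L) %% 8L != 0L) r$pos <- r$pos + (8L - (r$pos - 1L) %% 8L)
      byte_at <- function(k) {
        b <- r$bits[(r$pos + 8L * (k - 1L)):(r$pos + 8L * k - 1L)]
        sum(b * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L))
      }
      nread <- 0L
      take <- function(n) {
        v <- vapply(seq_len(n), function(k) byte_at(nread + k), integer(1L))
        nread <<- nread + n
        v
      }
      Y[my * 16L + 1:16, mx * 16L + 1:16] <- matrix(take(256L), 16L, byrow = TRUE)
      Cb[my * 8L + 1:8, mx * 8L + 1:8] <- matrix(take(64L), 8L, byrow = TRUE)
      Cr[my * 8L + 1:8, mx * 8L + 1:8] <- matrix(take(64L), 8L, byrow = TRUE)
      r$pos <- r$pos + 8L * nread
    }
  }
  list(Y = Y, Cb = Cb, Cr = Cr)
}

# Full structural parse: sample count, timing, dimensions, and decoded
# planes for the requested frame indices.
mp4_read <- function(path, decode_frames = integer()) {
  bytes <- readBin(path, "raw", file.size(path))
  stsz <- mp4_find(bytes, c("moov", "trak", "mdia", "minf", "stbl", "stsz"))
  n <- be32(bytes, stsz$start + 8L)
  sizes <- vapply(seq_len(n), function(i)
    be32(bytes, stsz$start + 12L + 4L * (i - 1L)), numeric(1L))
  stts <- mp4_find(bytes, c("moov", "trak", "mdia", "minf", "stbl", "stts"))
  stts_n <- be32(bytes, stts$start + 4L)
  stts_count <- be32(bytes, stts$start + 8L)
  delta <- be32(bytes, stts$start + 12L)
  mdhd <- mp4_find(bytes, c("moov", "trak", "mdia", "mdhd"))
  timescale <- be32(bytes, mdhd$start + 12L)
  duration <- be32(bytes, mdhd$start + 16L)
  stco <- mp4_find(bytes, c("moov", "trak", "mdia", "minf", "stbl", "stco"))
  offset <- be32(bytes, stco$start + 8L)
  avcC <- mp4_find(bytes, c("moov", "trak", "mdia", "minf", "stbl", "stsd",
                            "avc1", "avcC"))
  sps_len <- as.integer(bytes[avcC$start + 6L]) * 256L +
             as.integer(bytes[avcC$start + 7L])
  sps <- bytes[(avcC$start + 8L):(avcC$start + 7L + sps_len)]
  dims <- h264_parse_sps(sps)
  planes <- list()
  pos <- offset + 1L
  for (i in seq_len(n)) {
    if (i %in% decode_frames) {
      nal_len <- be32(bytes, pos)
      nal <- bytes[(pos + 4L):(pos + 3L + nal_len)]
      planes[[as.character(i)]] <- h264_decode_ipcm(nal, dims$mbw, dims$mbh)
    }
    pos <- pos + sizes[[i]]
  }
  list(n_samples = n, sizes = sizes, timescale = timescale, delta = delta,
       duration = duration, stts_entries = stts_n, stts_count = stts_count,
       width = dims$width, height = dims$height, planes = planes)
}

# Independent BT.601 limited-range luma from an RGB(A) raster
luma_bt601 <- function(img) {
  img <- unclass(img)
  16 + (65.481 * img[, , 1L] + 128.553 * img[, , 2L] +
        24.966 * img[, , 3L]) / 255
}
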