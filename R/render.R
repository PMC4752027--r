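# Deterministic software rasterizer. Frames are drawn into an RGBA array
# (height x width x 4, levels 0-255) with hard-edged (non-antialiased)
# primitives and pure arithmetic only, so identical inputs always produce
# identical pixels. Draw order: background fill, background-canvas
# annotations, edges, nodes (body, custom graphics, label), then
# foreground-canvas annotations.

#' Render settings
#'
#' @param base_width,base_height Base canvas size in pixels at a resolution
#'   of 100 (defaults 1280 x 720).
#' @param resolution_pct Linear expansion percentage: output dimensions are
#'   `round(base * resolution_pct / 100)`, so 300 gives a 3x render. At
#'   least a 2x expansion is sensible for published video.
#' @return A `netanim_render_settings` object.
#' @export
render_settings <- function(base_width = 1280L, base_height = 720L,
                            resolution_pct = 100L) {
  if (!(is.numeric(base_width) && base_width >= 1 &&
        is.numeric(base_height) && base_height >= 1))
    stop(netanim_error("base dimensions must be positive",
                       class = "netanim_range_error"))
  if (!(is.numeric(resolution_pct) && length(resolution_pct) == 1L &&
        resolution_pct >= 1))
    stop(netanim_error("resolution_pct must be >= 1",
                       class = "netanim_range_error"))
  structure(list(base_width = as.integer(round(base_width)),
                 base_height = as.integer(round(base_height)),
                 resolution_pct = as.numeric(resolution_pct)),
            class = "netanim_render_settings")
}

output_dims <- function(settings) {
  r <- settings$resolution_pct / 100
  c(width = as.integer(round(settings$base_width * r)),
    height = as.integer(round(settings$base_height * r)))
}

## ---- canvas -----------------------------------------------------------

new_canvas <- function(width, height, rgba) {
  img <- array(0, dim = c(height, width, 4L))
  img[, , 1L] <- rgba[[1L]]; img[, , 2L] <- rgba[[2L]]
  img[, , 3L] <- rgba[[3L]]; img[, , 4L] <- rgba[[4L]]
  cv <- new.env(parent = emptyenv())
  cv$img <- img
  cv$w <- as.integer(width); cv$h <- as.integer(height)
  cv
}

# Alpha-composite a colored mask over the canvas inside bounding box
# rows/cols (1-based index vectors). `cover` is a [length(rows) x
# length(cols)] coverage matrix in [0, 1].
blend_mask <- function(cv, rows, cols, cover, rgba, alpha_mult = 1) {
  a_src <- (rgba[[4L]] / 255) * alpha_mult
  if (a_src <= 0 || !length(rows) || !length(cols)) return(invisible(NULL))
  asrc <- cover * a_src
  if (all(asrc == 0)) return(invisible(NULL))
  sub <- cv$img[rows, cols, , drop = FALSE]
  adst <- sub[, , 4L] / 255
  aout <- asrc + adst * (1 - asrc)
  safe <- ifelse(aout > 0, aout, 1)
  for (ch in 1:3) {
    sub[, , ch] <- (rgba[[ch]] * asrc + sub[, , ch] * adst * (1 - asrc)) / safe
  }
  sub[, , 4L] <- aout * 255
  cv$img[rows, cols, ] <- sub
  invisible(NULL)
}

# Composite an RGBA image (values 0-255, dims hs x ws x 4) whose top-left
# lands at (x0, y0) in pixel coordinates (can be fractional; rounded).
blend_image <- function(cv, img, x0, y0, alpha_mult = 1) {
  hs <- dim(img)[1L]; ws <- dim(img)[2L]
  c0 <- as.integer(round_half_up(x0)) + 1L
  r0 <- as.integer(round_half_up(y0)) + 1L
  cols <- c0:(c0 + ws - 1L); rows <- r0:(r0 + hs - 1L)
  keepc <- cols >= 1L & cols <= cv$w
  keepr <- rows >= 1L & rows <= cv$h
  if (!any(keepc) || !any(keepr)) return(invisible(NULL))
  img <- img[keepr, keepc, , drop = FALSE]
  rows <- rows[keepr]; cols <- cols[keepc]
  asrc <- (img[, , 4L] / 255) * alpha_mult
  sub <- cv$img[rows, cols, , drop = FALSE]
  adst <- sub[, , 4L] / 255
  aout <- asrc + adst * (1 - asrc)
  safe <- ifelse(aout > 0, aout, 1)
  for (ch in 1:3) {
    sub[, , ch] <- (img[, , ch] * asrc + sub[, , ch] * adst * (1 - asrc)) / safe
  }
  sub[, , 4L] <- aout * 255
  cv$img[rows, cols, ] <- sub
  invisible(NULL)
}

# Clipped bounding box -> list(rows, cols, X, Y) with pixel-center
# coordinate matrices, or NULL when fully off-canvas.
bbox_grid <- function(cv, xmin, xmax, ymin, ymax) {
  c0 <- max(1L, as.integer(floor(xmin)) + 1L)
  c1 <- min(cv$w, as.integer(ceiling(xmax)))
  r0 <- max(1L, as.integer(floor(ymin)) + 1L)
  r1 <- min(cv$h, as.integer(ceiling(ymax)))
  if (c0 > c1 || r0 > r1) return(NULL)
  cols <- c0:c1; rows <- r0:r1
  X <- matrix(rep(cols - 0.5, each = length(rows)), nrow = length(rows))
  Y <- matrix(rep(rows - 0.5, times = length(cols)), nrow = length(rows))
  list(rows = rows, cols = cols, X = X, Y = Y)
}

## ---- shape masks ------------------------------------------------------

# coverage mask (0/1) of a node shape centered (cx, cy), half-extents rx, ry
shape_mask <- function(shape, X, Y, cx, cy, rx, ry) {
  dx <- X - cx; dy <- Y - cy
  switch(shape,
    ellipse = as.numeric((dx / rx)^2 + (dy / ry)^2 <= 1),
    rectangle = as.numeric(abs(dx) <= rx & abs(dy) <= ry),
    round_rectangle = {
      cr <- 0.3 * min(rx, ry)
      inx <- abs(dx) <= rx - cr; iny <- abs(dy) <= ry - cr
      core <- (inx & abs(dy) <= ry) | (iny & abs(dx) <= rx)
      corner <- (pmax(abs(dx) - (rx - cr), 0))^2 +
                (pmax(abs(dy) - (ry - cr), 0))^2 <= cr^2
      as.numeric(core | corner)
    },
    diamond = as.numeric(abs(dx) / rx + abs(dy) / ry <= 1),
    triangle = as.numeric(abs(dy) <= ry &
                          abs(dx) / rx <= (dy + ry) / (2 * ry)),
    hexagon = as.numeric(abs(dy) <= ry &
                         abs(dx) / rx + 0.5 * abs(dy) / ry <= 1),
    # unknown shape names draw as rectangles
    as.numeric(abs(dx) <= rx & abs(dy) <= ry))
}

draw_shape <- function(cv, shape, cx, cy, rx, ry, fill_rgba, fill_alpha_mult,
                       border_rgba = NULL, border_w = 0, border_alpha_mult = 1) {
  if (rx <= 0 || ry <= 0) return(invisible(NULL))
  g <- bbox_grid(cv, cx - rx - border_w, cx + rx + border_w,
                 cy - ry - border_w, cy + ry + border_w)
  if (is.null(g)) return(invisible(NULL))
  outer_m <- shape_mask(shape, g$X, g$Y, cx, cy, rx, ry)
  blend_mask(cv, g$rows, g$cols, outer_m, fill_rgba, fill_alpha_mult)
  if (!is.null(border_rgba) && border_w > 0) {
    rx_i <- max(rx - border_w, 0); ry_i <- max(ry - border_w, 0)
    inner_m <- if (rx_i > 0 && ry_i > 0)
      shape_mask(shape, g$X, g$Y, cx, cy, rx_i, ry_i) else 0
    blend_mask(cv, g$rows, g$cols, pmax(outer_m - inner_m, 0),
               border_rgba, border_alpha_mult)
  }
  invisible(NULL)
}

# straight line segment with width and dash pattern; pattern lengths in px
line_cover <- function(X, Y, x0, y0, x1, y1, halfw, dash = NULL) {
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx * vx + vy * vy
  if (len2 == 0) {
    d2 <- (X - x0)^2 + (Y - y0)^2
    return(as.numeric(d2 <= halfw^2))
  }
  s <- ((X - x0) * vx + (Y - y0) * vy) / len2
  sc <- pmin(pmax(s, 0), 1)
  dx <- X - (x0 + sc * vx); dy <- Y - (y0 + sc * vy)
  m <- as.numeric(dx * dx + dy * dy <= halfw^2)
  if (!is.null(dash)) {
    along <- sc * sqrt(len2)
    period <- dash[[1L]] + dash[[2L]]
    m <- m * as.numeric((along %% period) < dash[[1L]])
  }
  m
}

draw_line <- function(cv, x0, y0, x1, y1, width, rgba, alpha_mult = 1,
                      line_type = "solid") {
  halfw <- max(width, 0) / 2
  if (halfw <= 0) return(invisible(NULL))
  g <- bbox_grid(cv, min(x0, x1) - halfw, max(x0, x1) + halfw,
                 min(y0, y1) - halfw, max(y0, y1) + halfw)
  if (is.null(g)) return(invisible(NULL))
  dash <- switch(line_type,
                 dashed = c(6 * halfw, 4 * halfw),
                 dotted = c(2 * halfw, 3 * halfw),
                 NULL)
  m <- line_cover(g$X, g$Y, x0, y0, x1, y1, halfw, dash)
  blend_mask(cv, g$rows, g$cols, m, rgba, alpha_mult)
  invisible(NULL)
}

draw_triangle <- function(cv, pts, rgba, alpha_mult = 1) {
  g <- bbox_grid(cv, min(pts[, 1L]), max(pts[, 1L]),
                 min(pts[, 2L]), max(pts[, 2L]))
  if (is.null(g)) return(invisible(NULL))
  m <- matrix(1, nrow(g$X), ncol(g$X))
  for (i in 1:3) {
    j <- if (i == 3L) 1L else i + 1L
    ex <- pts[j, 1L] - pts[i, 1L]; ey <- pts[j, 2L] - pts[i, 2L]
    cross <- ex * (g$Y - pts[i, 2L]) - ey * (g$X - pts[i, 1L])
    # orientation-independent: flip if third vertex is on the negative side
    k <- setdiff(1:3, c(i, j))
    ref <- ex * (pts[k, 2L] - pts[i, 2L]) - ey * (pts[k, 1L] - pts[i, 1L])
    m <- m * as.numeric(if (ref >= 0) cross >= 0 else cross <= 0)
  }
  blend_mask(cv, g$rows, g$cols, m, rgba, alpha_mult)
  invisible(NULL)
}

draw_text <- function(cv, text, ax, ay, font_px, rgba, alpha_mult = 1,
                      bold = FALSE, justification = "c") {
  if (is.na(text) || !nzchar(text) || alpha_mult <= 0) return(invisible(NULL))
  bm <- text_bitmap(text, bold = bold)
  if (!ncol(bm)) return(invisible(NULL))
  s <- max(1L, as.integer(round_half_up(font_px / 7)))
  if (s > 1L) bm <- bm[rep(seq_len(nrow(bm)), each = s),
                       rep(seq_len(ncol(bm)), each = s), drop = FALSE]
  w <- ncol(bm); h <- nrow(bm)
  x0 <- switch(justification, l = ax, r = ax - w, ax - w / 2)
  y0 <- ay - h / 2
  c0 <- as.integer(round_half_up(x0)); r0 <- as.integer(round_half_up(y0))
  cols <- (c0 + 1L):(c0 + w); rows <- (r0 + 1L):(r0 + h)
  keepc <- cols >= 1L & cols <= cv$w; keepr <- rows >= 1L & rows <= cv$h
  if (!any(keepc) || !any(keepr)) return(invisible(NULL))
  blend_mask(cv, rows[keepr], cols[keepc],
             bm[keepr, keepc, drop = FALSE], rgba, alpha_mult)
  invisible(NULL)
}

## ---- image references -------------------------------------------------

# Resolve a custom-graphics / image-annotation reference to an RGBA array
# (0-255). Supported forms:
#   "glyph:disc:#RRGGBB[AA]", "glyph:ring:...", "glyph:square:...",
#   "glyph:diamond:..."   -- procedural 33x33 glyphs
#   a path to a PNG file  -- read with png::readPNG
# Anything else maps to a deterministic colored disc derived from the
# string's bytes, so unknown refs still render reproducibly.
resolve_image_ref <- function(ref, assets_dir = NULL) {
  if (is.na(ref) || !nzchar(ref)) return(NULL)
  if (grepl("^glyph:", ref)) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1L]]
    kind <- if (length(parts) >= 2L) parts[[2L]] else "disc"
    col <- if (length(parts) >= 3L) decode_color(parts[[3L]]) else c(80L, 80L, 200L, 255L)
    return(procedural_glyph(kind, col))
  }
  path <- ref
  if (!is.null(assets_dir) && !file.exists(path))
    path <- file.path(assets_dir, ref)
  if (grepl("\\.png$", ref, ignore.case = TRUE) && file.exists(path)) {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
    if (dim(raw)[3L] == 3L) {
      raw <- array(c(raw, array(1, dim(raw)[1:2])), c(dim(raw)[1:2], 4L))
    }
    return(raw * 255)
  }
  seedcol <- utf8ToInt(ref)
  rgb <- c(sum(seedcol * 31) %% 256, sum(seedcol * 57) %% 256,
           sum(seedcol * 97) %% 256)
  procedural_glyph("disc", as.integer(c(rgb, 255L)))
}

procedural_glyph <- function(kind, rgba) {
  n <- 33L
  cc <- (n + 1) / 2
  X <- matrix(rep(seq_len(n), each = n), n); Y <- t(X)
  r <- (n - 1) / 2
  m <- switch(kind,
    ring = as.numeric((X - cc)^2 + (Y - cc)^2 <= r^2 &
                      (X - cc)^2 + (Y - cc)^2 >= (0.6 * r)^2),
    square = as.numeric(abs(X - cc) <= 0.85 * r & abs(Y - cc) <= 0.85 * r),
    diamond = as.numeric(abs(X - cc) + abs(Y - cc) <= r),
    as.numeric((X - cc)^2 + (Y - cc)^2 <= r^2))
  img <- array(0, c(n, n, 4L))
  img[, , 1L] <- rgba[[1L]]; img[, , 2L] <- rgba[[2L]]; img[, , 3L] <- rgba[[3L]]
  img[, , 4L] <- m * rgba[[4L]]
  img
}

# nearest-neighbour resize to (wpx, hpx)
resize_image <- function(img, wpx, hpx) {
  hpx <- max(1L, as.integer(round_half_up(hpx)))
  wpx <- max(1L, as.integer(round_half_up(wpx)))
  h <- dim(img)[1L]; w <- dim(img)[2L]
  ri <- pmin(h, pmax(1L, ceiling(seq_len(hpx) / hpx * h)))
  ci <- pmin(w, pmax(1L, ceiling(seq_len(wpx) / wpx * w)))
  img[ri, ci, , drop = FALSE]
}

adjust_image <- function(img, brightness = 0, contrast = 0) {
  if (brightness == 0 && contrast == 0) return(img)
  rgbpart <- img[, , 1:3, drop = FALSE]
  rgbpart <- (rgbpart - 128) * (1 + contrast / 100) + 128 + brightness
  img[, , 1:3] <- pmin(pmax(rgbpart, 0), 255)
  img
}

## ---- frame rendering --------------------------------------------------

anchor_point <- function(anchor, cx, cy, rx, ry) {
  dx <- switch(anchor, e = rx, w = -rx, ne = rx, se = rx, nw = -rx, sw = -rx, 0)
  dy <- switch(anchor, n = -ry, s = ry, ne = -ry, nw = -ry, se = ry, sw = ry, 0)
  c(cx + dx, cy + dy)
}

body_opacity <- function(props) {
  if (!is.null(props$.opacity)) return(props$.opacity)
  if (!is.null(props$visible)) return(if (isTRUE(props$visible)) 1 else 0)
  1
}

label_opacity <- function(props) {
  if (!is.null(props$.label_opacity)) return(props$.label_opacity)
  body_opacity(props)
}

# replace a color's alpha channel with a separate transparency property
# (the transparency key wins where both exist)
with_alpha <- function(rgba, transparency) {
  c(rgba[1:3], as.integer(round_half_up(min(max(transparency, 0), 255))))
}

custom_graphics_layers <- function(value) {
  if (is.null(value)) return(list())
  if (is.list(value)) return(value)          # interpolated: list of layers
  if (length(value) == 1L && is.na(value)) return(list())
  list(list(ref = value, opacity = 1))       # key frame: plain ref
}

#' Render one frame to an RGBA raster
#'
#' Deterministically rasterizes a fully-specified frame (a key frame or one
#' frame of an interpolated sequence). The camera maps model coordinates to
#' pixels via the network `center_x`/`center_y` and `scale_factor`; the
#' network `depth` and z locations are stored and interpolated but ignored
#' by this 2D renderer.
#'
#' @param frame A `netanim_keyframe` or one element of a
#'   `netanim_sequence`'s `frames`.
#' @param settings A [render_settings()].
#' @param assets_dir Optional directory against which relative image
#'   references are resolved.
#' @return Numeric array `height x width x 4` with levels 0-255, class
#'   `netanim_raster`.
#' @export
render_frame <- function(frame, settings = render_settings(),
                         assets_dir = NULL) {
  dims <- output_dims(settings)
  if (dims[["width"]] < 1L || dims[["height"]] < 1L)
    stop(netanim_error("render dimensions must be positive",
                       class = "netanim_range_error"))
  net <- frame$network
  r <- settings$resolution_pct / 100
  k <- net$scale_factor * r
  W <- dims[["width"]]; H <- dims[["height"]]
  px <- function(x) (x - net$center_x) * k + W / 2
  py <- function(y) (y - net$center_y) * k + H / 2

  cv <- new_canvas(W, H, c(net$background_paint[1:3], 255))
  if (net$background_paint[[4L]] < 255) {
    # semi-transparent backgrounds composite over opaque white
    cv$img[, , 1:3] <- 255
    cv$img[, , 4L] <- 255
    g <- list(rows = seq_len(H), cols = seq_len(W))
    blend_mask(cv, g$rows, g$cols, matrix(1, H, W), net$background_paint)
  }

  draw_annotation <- function(id, ann) {
    p <- ann$props
    m <- body_opacity(p) * (p$opacity / 255)
    if (m <= 0) return(invisible(NULL))
    ka <- k * p$zoom
    cx <- px(p$x); cy <- py(p$y)
    if (ann$type == "shape") {
      draw_shape(cv, if (p$shape %in% c("ellipse", "oval")) "ellipse" else p$shape,
                 cx, cy, p$width * ka / 2, p$height * ka / 2,
                 p$color, m, p$border_color, p$border_width * ka, m)
    } else if (ann$type == "text") {
      draw_text(cv, p$text, cx, cy, p$font_size * ka, p$font_color, m,
                bold = identical(p$font_style, "bold"))
    } else if (ann$type == "image") {
      img <- resolve_image_ref(p$image_url, assets_dir)
      if (!is.null(img)) {
        img <- adjust_image(resize_image(img, p$width * ka, p$height * ka),
                            p$image_brightness, p$image_contrast)
        blend_image(cv, img, cx - p$width * ka / 2, cy - p$height * ka / 2,
                    m * (p$image_opacity / 255))
      }
    } else if (ann$type == "arrow") {
      x1 <- px(p$x + p$width); y1 <- py(p$y + p$height)
      draw_line(cv, cx, cy, x1, y1, p$arrow_width * ka, p$arrow_color, m)
      if (!identical(p$arrow_target_type, "none")) {
        v <- c(x1 - cx, y1 - cy); vl <- sqrt(sum(v^2))
        if (vl > 0) {
          u <- v / vl; n <- c(-u[[2L]], u[[1L]])
          sz <- p$arrow_target_size * ka
          tip <- c(x1, y1)
          base <- tip - u * sz
          draw_triangle(cv, rbind(tip, base + n * sz / 2, base - n * sz / 2),
                        p$arrow_target_color, m)
        }
      }
    }
    invisible(NULL)
  }

  anns <- frame$annotations
  for (id in names(anns)) {
    if (identical(anns[[id]]$props$canvas, "background")) draw_annotation(id, anns[[id]])
  }

  for (id in names(frame$edges)) {
    e <- frame$edges[[id]]
    p <- e$props
    m <- body_opacity(p)
    if (m <= 0) next
    n0 <- frame$nodes[[e$source]]; n1 <- frame$nodes[[e$target]]
    if (is.null(n0) || is.null(n1)) next
    x0 <- px(n0$x); y0 <- py(n0$y); x1 <- px(n1$x); y1 <- py(n1$y)
    draw_line(cv, x0, y0, x1, y1, p$width * k,
              with_alpha(p$paint, p$transparency), m, p$line_type)
    if (!is.na(p$label) && nzchar(p$label)) {
      draw_text(cv, p$label, (x0 + x1) / 2, (y0 + y1) / 2, p$label_size * k,
                with_alpha(p$label_color, p$label_transparency),
                label_opacity(p), bold = identical(p$font_face, "bold"))
    }
  }

  for (id in names(frame$nodes)) {
    p <- frame$nodes[[id]]
    m <- body_opacity(p)
    lm <- label_opacity(p)
    if (m <= 0 && lm <= 0) next
    cx <- px(p$x); cy <- py(p$y)
    rx <- p$width * k / 2; ry <- p$height * k / 2
    if (m > 0) {
      draw_shape(cv, p$shape, cx, cy, rx, ry,
                 with_alpha(p$fill_color, p$transparency), m,
                 with_alpha(p$border_paint, p$border_transparency),
                 p$border_width * k, m)
      for (slot in 1:9) {
        layers <- custom_graphics_layers(p[[sprintf("custom_graphics_%d", slot)]])
        if (!length(layers)) next
        sz <- p[[sprintf("custom_graphics_size_%d", slot)]] * k
        if (sz <= 0) next
        op <- p[[sprintf("custom_graphics_position_%d", slot)]]
        ap <- anchor_point(op$anchor, cx, cy, rx, ry)
        gx <- ap[[1L]] + op$dx * k; gy <- ap[[2L]] + op$dy * k
        for (layer in layers) {
          img <- resolve_image_ref(layer$ref, assets_dir)
          if (is.null(img)) next
          img <- resize_image(img, sz, sz)
          blend_image(cv, img, gx - sz / 2, gy - sz / 2, m * layer$opacity)
        }
      }
    }
    if (lm > 0 && !is.na(p$label) && nzchar(p$label)) {
      op <- p$label_position
      ap <- anchor_point(op$anchor, cx, cy, rx, ry)
      draw_text(cv, p$label, ap[[1L]] + op$dx * k, ap[[2L]] + op$dy * k,
                p$label_size * k,
                with_alpha(p$label_color, p$label_transparency), lm,
                bold = identical(p$font_face, "bold"),
                justification = op$justification)
    }
  }

  for (id in names(anns)) {
    if (!identical(anns[[id]]$props$canvas, "background")) draw_annotation(id, anns[[id]])
  }

  structure(round_half_up(cv$img), class = "netanim_raster",
            dims = dims)
}
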