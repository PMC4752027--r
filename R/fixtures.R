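# Seeded synthetic corpus: toy styled networks and key-frame scripts that
# between them exercise every interpolator kind, with no external data.
# All randomness flows from one documented seed per fixture, so the same
# (spec, seed) always produces byte-identical files.

fixture_palette <- function() {
  c("#1F77B4FF", "#FF7F0EFF", "#2CA02CFF", "#D62728FF", "#9467BDFF",
    "#8C564BFF", "#E377C2FF", "#7F7F7FFF", "#BCBD22FF", "#17BECFFF")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a deterministic toy network scene
#'
#' A seeded random graph (uniform over simple graphs with the requested
#' edge count) laid out on a circle of radius 200 model units, with fill
#' colors drawn from a fixed palette. The same arguments always produce an
#' identical scene.
#'
#' @param n_nodes,n_edges Node and edge counts; `n_edges` at most
#'   `n_nodes * (n_nodes - 1) / 2`.
#' @param seed Integer seed.
#' @return A `netanim_scene`.
#' @export
make_toy_network <- function(n_nodes = 5L, n_edges = 4L, seed = 1L) {
  if (n_nodes < 1L)
    stop(netanim_error("need at least one node", class = "netanim_range_error"))
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop(netanim_error(sprintf(
      "%d edges is more than a simple graph on %d nodes can hold",
      n_edges, n_nodes), class = "netanim_range_error"))
  }
  with_seed(seed, {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    ids <- sprintf("N%d", seq_len(n_nodes))
    pal <- fixture_palette()
    cols <- sample(pal, n_nodes, replace = TRUE)
    nodes <- list()
    for (i in seq_len(n_nodes)) {
      ang <- 2 * pi * (i - 1L) / n_nodes
      nodes[[ids[[i]]]] <- list(
        x = round(200 * cos(ang), 3L), y = round(200 * sin(ang), 3L),
        fill_color = decode_color(cols[[i]]),
        label = ids[[i]],
        label_position = object_position("s", "c", 0, 14))
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- list()
    for (i in seq_len(nrow(el))) {
      edges[[sprintf("E%d", i)]] <- list(source = ids[[el[i, 1L]]],
                                         target = ids[[el[i, 2L]]])
    }
    scene_state(
      network = list(width = 640, height = 360, center_x = 0, center_y = 0),
      nodes = nodes, edges = edges)
  })
}

script_kinds <- function() {
  c("color_sweep", "zoom_pan", "shape_crossfade", "visibility_toggle",
    "annotation_fade", "custom_graphics_swap", "mixed")
}

mutate_scene <- function(scene, network = NULL, nodes = NULL, edges = NULL,
                         annotations = NULL, drop_nodes = NULL) {
  if (!is.null(network)) scene$network[names(network)] <- network
  for (id in names(nodes))
    scene$nodes[[id]][names(nodes[[id]])] <- nodes[[id]]
  for (id in names(edges))
    scene$edges[[id]]$props[names(edges[[id]])] <- edges[[id]]
  for (id in names(annotations)) {
    a <- annotations[[id]]
    type <- if (is.null(a$type)) "shape" else a$type
    props <- totalize_props(a[setdiff(names(a), "type")], "annotation", id)
    scene$annotations[[id]] <- list(type = type, props = props)
  }
  if (!is.null(drop_nodes)) {
    keep_e <- vapply(scene$edges, function(e)
      !(e$source %in% drop_nodes || e$target %in% drop_nodes), logical(1L))
    scene$edges <- scene$edges[keep_e]
    scene$nodes <- scene$nodes[setdiff(names(scene$nodes), drop_nodes)]
  }
  scene
}

# linear blue -> yellow gradient, u in [0, 1]
gradient_color <- function(u) {
  as.integer(round_half_up(c(40 + u * (235 - 40), 40 + u * (220 - 40),
                             200 - u * 170, 255)))
}

fixture_script_scenes <- function(script_kind, n_nodes, n_edges, seed) {
  base <- make_toy_network(n_nodes, n_edges, seed)
  ids <- names(base$nodes)
  pal <- fixture_palette()
  scenes <- switch(script_kind,
    color_sweep = {
      shifted <- with_seed(seed + 1L, sample(pal, length(ids), replace = TRUE))
      s2 <- base
      for (i in seq_along(ids))
        s2$nodes[[ids[[i]]]]$fill_color <- decode_color(shifted[[i]])
      list(base, s2)
    },
    zoom_pan = {
      focus <- base$nodes[[ids[[1L]]]]
      s2 <- mutate_scene(base, network = list(
        center_x = focus$x, center_y = focus$y, scale_factor = 2.5))
      list(base, s2)
    },
    shape_crossfade = {
      s2 <- base
      shapes <- c("rectangle", "diamond", "hexagon", "triangle")
      for (i in seq_along(ids))
        s2$nodes[[ids[[i]]]]$shape <- shapes[[(i - 1L) %% length(shapes) + 1L]]
      list(base, s2)
    },
    visibility_toggle = {
      s2 <- mutate_scene(base, drop_nodes = ids[[length(ids)]])
      list(base, s2)
    },
    annotation_fade = {
      s2 <- mutate_scene(base, annotations = list(
        box1 = list(type = "shape", x = -120, y = -120, width = 120,
                    height = 60, color = decode_color("#FFE08080"),
                    canvas = "background"),
        note1 = list(type = "text", x = -120, y = -150, text = "FOCUS",
                     font_size = 16, canvas = "foreground")))
      list(base, s2)
    },
    custom_graphics_swap = {
      s1 <- base
      for (id in ids[1:2]) {
        s1$nodes[[id]]$custom_graphics_1 <- "glyph:disc:#D62728"
        s1$nodes[[id]]$custom_graphics_size_1 <- 18
      }
      s2 <- s1
      for (id in ids[1:2]) {
        s2$nodes[[id]]$custom_graphics_1 <- "glyph:ring:#1F77B4"
        s2$nodes[[id]]$custom_graphics_size_1 <- 26
      }
      list(s1, s2)
    },
    mixed = {
      degs <- vapply(ids, function(id) {
        sum(vapply(base$edges, function(e)
          e$source == id || e$target == id, logical(1L)))
      }, numeric(1L))
      s1 <- base
      focus <- base$nodes[[ids[[1L]]]]
      s2 <- mutate_scene(s1, network = list(center_x = focus$x,
                                            center_y = focus$y,
                                            scale_factor = 2))
      s3 <- s2
      for (i in seq_along(ids)) {
        s3$nodes[[ids[[i]]]]$label <- sprintf("G%d", i)
        s3$nodes[[ids[[i]]]]$shape <- "ellipse"
      }
      s4 <- s3
      for (i in seq_along(ids)) {
        s4$nodes[[ids[[i]]]]$width <- 35 + 12 * degs[[i]]
        s4$nodes[[ids[[i]]]]$height <- 35 + 12 * degs[[i]]
        s4$nodes[[ids[[i]]]]$label_size <- 12 + 3 * degs[[i]]
      }
      s5 <- mutate_scene(s4, annotations = list(
        hilite = list(type = "shape", x = focus$x, y = focus$y, width = 90,
                      height = 90, shape = "ellipse",
                      color = decode_color("#FFD70060"),
                      canvas = "background")))
      recolor <- function(s, shift, note) {
        u <- (seq_along(ids) - 1L + shift) %% length(ids) / max(1L, length(ids) - 1L)
        out <- s
        for (i in seq_along(ids))
          out$nodes[[ids[[i]]]]$fill_color <- gradient_color(min(u[[i]], 1))
        mutate_scene(out, annotations = list(
          datanote = list(type = "text", x = focus$x, y = focus$y - 80,
                          text = note, font_size = 14,
                          canvas = "foreground")))
      }
      s6 <- recolor(s5, 0L, "EXPR A")
      s7 <- s6
      s8 <- recolor(s6, 2L, "EXPR B")
      s9 <- s8
      s10 <- recolor(s8, 4L, "EXPR C")
      s11 <- s10
      s12 <- s11
      for (i in seq_along(ids)) {
        id <- ids[[i]]
        s12$nodes[[id]]$custom_graphics_1 <-
          sprintf("glyph:square:%s", substr(pal[[(i - 1L) %% 10L + 1L]], 1L, 7L))
        s12$nodes[[id]]$custom_graphics_size_1 <- 20
        s12$nodes[[id]]$label_position <- object_position("s", "c", 0, 26)
      }
      s13 <- s12
      list(s1, s2, s3, s4, s5, s6, s7, s8, s9, s10, s11, s12, s13)
    },
    stop(netanim_error(sprintf(
      "unknown script kind '%s' (valid: %s)", script_kind,
      paste(script_kinds(), collapse = ", ")),
      class = "netanim_usage_error")))
  scenes
}

#' Generate a key-frame script: scene files plus a storyboard
#'
#' Writes 2-13 scene files whose pairwise differences exercise the
#' interpolator kinds implied by `script_kind`, and a storyboard placing
#' them one second apart. `mixed` emits a 13-scene movie script (overview,
#' zoom to a focus node, label/shape change, degree-scaled sizes,
#' highlight annotations, three expression-gradient recolorings with hold
#' frames, and a final custom-graphics chart fade-in).
#'
#' @param script_kind One of `color_sweep`, `zoom_pan`, `shape_crossfade`,
#'   `visibility_toggle`, `annotation_fade`, `custom_graphics_swap`,
#'   `mixed`.
#' @param dir Output directory (created if needed).
#' @param n_nodes,n_edges,seed Passed to [make_toy_network()]; the seed is
#'   recorded in the output file names.
#' @return List with `storyboard` (path) and `scenes` (paths), invisibly.
#' @export
make_script <- function(script_kind = "mixed", dir = ".", n_nodes = 5L,
                        n_edges = 4L, seed = 1L) {
  script_kind <- as.character(script_kind)
  if (!script_kind %in% script_kinds()) {
    stop(netanim_error(sprintf(
      "unknown script kind '%s' (valid: %s)", script_kind,
      paste(script_kinds(), collapse = ", ")),
      class = "netanim_usage_error"))
  }
  scenes <- fixture_script_scenes(script_kind, n_nodes, n_edges, seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(scenes))
  for (i in seq_along(scenes)) {
    paths[[i]] <- file.path(dir, sprintf("scene_%s_s%d_%02d.json",
                                         script_kind, seed, i))
    write_scene(scenes[[i]], paths[[i]])
  }
  sb_path <- file.path(dir, sprintf("storyboard_%s_s%d.json", script_kind, seed))
  jsonlite::write_json(
    list(scenes = lapply(seq_along(paths), function(i)
           list(scene = basename(paths[[i]]), time_s = i - 1)),
         defaults = list(fps = 30, resolution_pct = 100, format = "frames",
                         base_width = 640, base_height = 360)),
    sb_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(storyboard = sb_path, scenes = paths))
}
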