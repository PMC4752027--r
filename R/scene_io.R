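# File formats. Scenes, storyboards and session bundles are JSON so they
# diff cleanly under version control; colors serialize as "#RRGGBBAA" hex
# (6-digit accepted on read with alpha FF), coordinates stay in model units
# (the camera maps model units to pixels only at render time). Topology can
# also be imported from GraphML.

#' Decode a hex color string
#'
#' @param s `"#RRGGBB"` or `"#RRGGBBAA"`.
#' @return Integer RGBA 4-tuple.
#' @export
decode_color <- function(s) {
  if (!(is.character(s) && length(s) == 1L &&
        grepl("^#[0-9a-fA-F]{6}([0-9a-fA-F]{2})?$", s)))
    stop(netanim_error(sprintf(
      "invalid color string '%s' (expected #RRGGBB or #RRGGBBAA)",
      paste(s, collapse = ","))))
  hx <- substring(s, c(2L, 4L, 6L, 8L), c(3L, 5L, 7L, 9L))
  if (!nzchar(hx[[4L]])) hx[[4L]] <- "FF"
  as.integer(strtoi(hx, 16L))
}

#' Encode an RGBA color as 8-digit hex
#'
#' @param rgba Integer RGBA 4-tuple, channels 0-255.
#' @return `"#RRGGBBAA"` string; exact inverse of [decode_color()].
#' @export
encode_color <- function(rgba) {
  msg <- check_domain_value(rgba, "color")
  if (!is.null(msg)) stop(netanim_error(msg))
  sprintf("#%02X%02X%02X%02X", rgba[[1L]], rgba[[2L]], rgba[[3L]], rgba[[4L]])
}

# domain-directed conversions between JSON values and property values
json_to_prop <- function(value, domain, ptr) {
  err <- function(msg) stop(netanim_error(sprintf("%s at %s", msg, ptr)))
  switch(domain,
    color = {
      if (!is.character(value) || length(value) != 1L)
        err("expected a hex color string")
      tryCatch(decode_color(value), error = function(e) err(conditionMessage(e)))
    },
    number = {
      if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
        err("expected a finite number")
      as.numeric(value)
    },
    object_position = {
      if (!is.list(value)) err("expected an object position object")
      tryCatch(object_position(
        anchor = if (is.null(value$anchor)) "c" else value$anchor,
        justification = if (is.null(value$justification)) "c" else value$justification,
        dx = if (is.null(value$dx)) 0 else value$dx,
        dy = if (is.null(value$dy)) 0 else value$dy),
        error = function(e) err(conditionMessage(e)))
    },
    text = {
      if (is.null(value)) NA_character_
      else if (is.character(value) && length(value) == 1L) value
      else err("expected a string")
    },
    enum = {
      if (!is.character(value) || length(value) != 1L) err("expected a string")
      value
    },
    boolean = {
      if (!is.logical(value) || length(value) != 1L || is.na(value))
        err("expected true or false")
      value
    },
    image_ref = {
      if (is.null(value)) NA_character_
      else if (is.character(value) && length(value) == 1L) value
      else err("expected an image reference string")
    },
    err(sprintf("unknown domain '%s'", domain)))
}

prop_to_json <- function(value, domain) {
  switch(domain,
    color = encode_color(value),
    object_position = list(anchor = value$anchor,
                           justification = value$justification,
                           dx = value$dx, dy = value$dy),
    text = , image_ref = if (is.na(value)) NULL else value,
    value)
}

props_from_json <- function(obj, category, ptr, skip = character()) {
  domains <- .netanim$domain_map[[category]]
  keys <- setdiff(names(obj), c("id", skip))
  unknown <- setdiff(keys, names(domains))
  if (length(unknown)) {
    stop(netanim_error(sprintf(
      "unknown %s property '%s' at %s/%s", category, unknown[[1L]], ptr,
      unknown[[1L]])))
  }
  out <- list()
  for (k in keys) out[[k]] <- json_to_prop(obj[[k]], domains[[k]], paste0(ptr, "/", k))
  out
}

props_to_json <- function(props, category) {
  domains <- .netanim$domain_map[[category]]
  out <- list()
  for (k in names(props)) {
    v <- prop_to_json(props[[k]], domains[[k]])
    if (!is.null(v)) out[[k]] <- v
  }
  out
}

#' Read a scene file
#'
#' A scene file is a JSON document with top-level keys `network` (a property
#' object), `nodes`, `edges` and `annotations` (arrays of objects carrying
#' `id` plus visual properties; edges also carry `source`/`target`,
#' annotations `type`). Unknown property names are rejected with the
#' offending key named; missing properties fill with the documented
#' defaults.
#'
#' @param path Path to a scene JSON file.
#' @return A `netanim_scene`.
#' @export
read_scene <- function(path) {
  if (!file.exists(path))
    stop(netanim_error(sprintf("scene file not found: '%s'", path),
                       class = "netanim_io_error"))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
    stop(netanim_error(sprintf("cannot parse '%s' as JSON: %s", path,
                               conditionMessage(e)),
                       class = "netanim_io_error"))
  })
  unknown_top <- setdiff(names(doc), c("network", "nodes", "edges", "annotations"))
  if (length(unknown_top)) {
    stop(netanim_error(sprintf("unknown top-level key at /%s", unknown_top[[1L]])))
  }
  network <- if (is.null(doc$network)) list()
             else props_from_json(doc$network, "network", "/network")

  named_objects <- function(entries, what, fn) {
    out <- list()
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      ptr <- sprintf("/%s/%d", what, i)
      if (is.null(e$id) || !nzchar(e$id))
        stop(netanim_error(sprintf("missing id at %s", ptr)))
      if (!is.null(out[[e$id]]))
        stop(netanim_error(sprintf("duplicate id '%s' at %s", e$id, ptr)))
      out[[e$id]] <- fn(e, ptr)
    }
    out
  }
  nodes <- named_objects(doc$nodes, "nodes", function(e, ptr)
    props_from_json(e, "node", ptr))
  edges <- named_objects(doc$edges, "edges", function(e, ptr) {
    if (is.null(e$source) || is.null(e$target))
      stop(netanim_error(sprintf("edge missing source/target at %s", ptr)))
    c(list(source = e$source, target = e$target),
      props_from_json(e, "edge", ptr, skip = c("source", "target")))
  })
  annotations <- named_objects(doc$annotations, "annotations", function(e, ptr) {
    c(list(type = if (is.null(e$type)) "shape" else e$type),
      props_from_json(e, "annotation", ptr, skip = "type"))
  })
  scene_state(network = network, nodes = nodes, edges = edges,
              annotations = annotations)
}

#' Write a scene file
#'
#' @param scene A `netanim_scene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  if (!is_scene(scene)) stop(netanim_error("write_scene() expects a netanim_scene"))
  doc <- list(
    network = props_to_json(scene$network, "network"),
    nodes = lapply(names(scene$nodes), function(id)
      c(list(id = id), props_to_json(scene$nodes[[id]], "node"))),
    edges = lapply(names(scene$edges), function(id) {
      e <- scene$edges[[id]]
      c(list(id = id, source = e$source, target = e$target),
        props_to_json(e$props, "edge"))
    }),
    annotations = lapply(names(scene$annotations), function(id) {
      a <- scene$annotations[[id]]
      c(list(id = id, type = a$type), props_to_json(a$props, "annotation"))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a storyboard
#'
#' A storyboard lists scene files with their timeline positions in seconds
#' (non-decreasing), plus optional export defaults (`fps`,
#' `resolution_pct`, `format`, `base_width`, `base_height`, `loop`).
#'
#' @param path Path to a storyboard JSON file.
#' @return A `netanim_storyboard`: list with `entries` (data frame `scene`,
#'   `time_s`), `defaults` and `dir` (directory of `path`, against which
#'   scene paths resolve).
#' @export
read_storyboard <- function(path) {
  if (!file.exists(path))
    stop(netanim_error(sprintf("storyboard file not found: '%s'", path),
                       class = "netanim_io_error"))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
    stop(netanim_error(sprintf("cannot parse '%s' as JSON: %s", path,
                               conditionMessage(e)),
                       class = "netanim_io_error"))
  })
  if (!length(doc$scenes))
    stop(netanim_error("storyboard must list at least one scene at /scenes"))
  scenes <- vapply(doc$scenes, function(e) as.character(e$scene), character(1L))
  times <- vapply(doc$scenes, function(e)
    if (is.null(e$time_s)) NA_real_ else as.numeric(e$time_s), numeric(1L))
  # unset times default to 1 s after the previous entry
  for (i in seq_along(times)) {
    if (is.na(times[[i]])) times[[i]] <- if (i == 1L) 0 else times[[i - 1L]] + 1
  }
  if (any(diff(times) < 0))
    stop(netanim_error("storyboard times must be non-decreasing at /scenes"))
  if (any(times < 0))
    stop(netanim_error("storyboard times must be >= 0 at /scenes",
                       class = "netanim_range_error"))
  structure(list(entries = data.frame(scene = scenes, time_s = times,
                                      stringsAsFactors = FALSE),
                 defaults = if (is.null(doc$defaults)) list() else doc$defaults,
                 dir = dirname(path)),
            class = "netanim_storyboard")
}

is_storyboard <- function(x) inherits(x, "netanim_storyboard")

#' Build a timeline from a storyboard
#'
#' Reads every scene file and captures it as a key frame at its storyboard
#' time.
#'
#' @param sb A `netanim_storyboard` from [read_storyboard()].
#' @return A `netanim_timeline`.
#' @export
storyboard_timeline <- function(sb) {
  if (!is_storyboard(sb)) stop(netanim_error("expected a netanim_storyboard"))
  tl <- timeline()
  for (i in seq_len(nrow(sb$entries))) {
    p <- sb$entries$scene[[i]]
    if (!file.exists(p)) p <- file.path(sb$dir, sb$entries$scene[[i]])
    scene <- read_scene(p)
    frame <- capture_frame(scene, sb$entries$time_s[[i]],
                           frame_id = sprintf("sb_%03d", i))
    tl <- add_keyframe(tl, frame)
  }
  tl
}

## ---- session bundles --------------------------------------------------

SESSION_VERSION <- 1L

frame_to_json <- function(f) {
  list(frame_id = f$frame_id, time_s = f$time_s,
       network = props_to_json(f$network, "network"),
       nodes = lapply(names(f$nodes), function(id)
         c(list(id = id), props_to_json(f$nodes[[id]], "node"))),
       edges = lapply(names(f$edges), function(id) {
         e <- f$edges[[id]]
         c(list(id = id, source = e$source, target = e$target),
           props_to_json(e$props, "edge"))
       }),
       annotations = lapply(names(f$annotations), function(id) {
         a <- f$annotations[[id]]
         c(list(id = id, type = a$type), props_to_json(a$props, "annotation"))
       }))
}

frame_from_json <- function(obj, ptr) {
  named_objects <- function(entries, what, fn) {
    out <- list()
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      out[[e$id]] <- fn(e, sprintf("%s/%s/%d", ptr, what, i))
    }
    out
  }
  nodes <- named_objects(obj$nodes, "nodes", function(e, p)
    totalize_props(props_from_json(e, "node", p), "node", e$id))
  edges <- named_objects(obj$edges, "edges", function(e, p)
    list(source = e$source, target = e$target,
         props = totalize_props(
           props_from_json(e, "edge", p, skip = c("source", "target")),
           "edge", e$id)))
  annotations <- named_objects(obj$annotations, "annotations", function(e, p)
    list(type = e$type,
         props = totalize_props(props_from_json(e, "annotation", p, skip = "type"),
                                "annotation", e$id)))
  structure(list(frame_id = obj$frame_id, time_s = as.numeric(obj$time_s),
                 network = totalize_props(
                   props_from_json(obj$network, "network", paste0(ptr, "/network")),
                   "network"),
                 nodes = nodes, edges = edges, annotations = annotations,
                 thumbnail = NULL),
            class = "netanim_keyframe")
}

#' Save a timeline as a session bundle
#'
#' All captured key frames -- full property maps -- and their timeline
#' positions are embedded in a single versioned JSON file, so a session
#' survives and can be reopened losslessly.
#'
#' @param tl A `netanim_timeline`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_session <- function(tl, path) {
  if (!is_timeline(tl)) stop(netanim_error("save_session() expects a timeline"))
  doc <- list(format = "netanim-session", version = SESSION_VERSION,
              fps_base = tl$fps_base,
              frames = lapply(tl$entries, frame_to_json))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a session bundle
#'
#' @param path Path to a bundle written by [save_session()].
#' @return The reconstructed `netanim_timeline`.
#' @export
load_session <- function(path) {
  if (!file.exists(path))
    stop(netanim_error(sprintf("session file not found: '%s'", path),
                       class = "netanim_io_error"))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
    stop(netanim_error(sprintf("cannot parse session '%s': %s", path,
                               conditionMessage(e)),
                       class = "netanim_io_error"))
  })
  if (is.null(doc$version))
    stop(netanim_error("corrupt session bundle: missing version field",
                       class = "netanim_io_error"))
  if (doc$version != SESSION_VERSION) {
    stop(netanim_error(sprintf(
      "unsupported session version %s (this build reads version %d); no migration path is available",
      doc$version, SESSION_VERSION), class = "netanim_io_error"))
  }
  tl <- timeline()
  for (i in seq_along(doc$frames)) {
    tl <- add_keyframe(tl, frame_from_json(doc$frames[[i]],
                                           sprintf("/frames/%d", i)))
  }
  tl
}

## ---- GraphML ----------------------------------------------------------

#' Import network topology from GraphML
#'
#' Nodes and edges come from the GraphML file; node coordinates come from
#' conventional `x`/`y` vertex attributes when present, otherwise nodes are
#' placed deterministically on a circle of radius 200 model units (in file
#' order, starting at angle 0). Styles come from `style_defaults`.
#'
#' @param path Path to a GraphML file.
#' @param style_defaults Named list of node properties applied to every
#'   node.
#' @return A `netanim_scene`.
#' @export
import_graphml <- function(path, style_defaults = list()) {
  if (!file.exists(path))
    stop(netanim_error(sprintf("GraphML file not found: '%s'", path),
                       class = "netanim_io_error"))
  g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                error = function(e) {
    stop(netanim_error(sprintf("cannot parse GraphML '%s': %s", path,
                               conditionMessage(e)),
                       class = "netanim_io_error"))
  })
  n <- igraph::vcount(g)
  attrs <- igraph::vertex_attr_names(g)
  ids <- if ("id" %in% attrs) igraph::vertex_attr(g, "id")
         else if ("name" %in% attrs) igraph::vertex_attr(g, "name")
         else sprintf("n%d", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop(netanim_error(sprintf("duplicate node id '%s' in '%s'",
                               ids[duplicated(ids)][[1L]], path)))
  }
  has_xy <- all(c("x", "y") %in% attrs)
  xs <- if (has_xy) as.numeric(igraph::vertex_attr(g, "x"))
        else 200 * cos(2 * pi * (seq_len(n) - 1L) / max(n, 1L))
  ys <- if (has_xy) as.numeric(igraph::vertex_attr(g, "y"))
        else 200 * sin(2 * pi * (seq_len(n) - 1L) / max(n, 1L))
  nodes <- list()
  for (i in seq_len(n)) {
    nodes[[ids[[i]]]] <- utils::modifyList(
      c(list(x = xs[[i]], y = ys[[i]], label = ids[[i]]), style_defaults),
      list())
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- list()
  for (i in seq_len(nrow(el))) {
    edges[[sprintf("e%d", i)]] <- list(source = ids[[el[i, 1L]]],
                                       target = ids[[el[i, 2L]]])
  }
  scene_state(nodes = nodes, edges = edges)
}
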