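# Scene model: a SceneState is one fully styled network view; a KeyFrame is
# its snapshot at a timeline position. Property maps are total per object --
# construction fills unset keys with the documented defaults, so every object
# always carries a value for every registered key of its category.

totalize_props <- function(props, category, id = NULL) {
  defaults <- vp_defaults(category)
  if (length(props)) {
    unknown <- setdiff(names(props), names(defaults))
    if (length(unknown)) {
      stop(netanim_error(sprintf(
        "unknown %s property '%s'%s", category, unknown[[1L]],
        if (is.null(id)) "" else sprintf(" on object '%s'", id))))
    }
    defaults[names(props)] <- props
  }
  defaults
}

validate_props <- function(props, category, id) {
  reg <- vp_registry(category)
  for (k in reg$name) {
    msg <- check_domain_value(props[[k]], reg$domain[reg$name == k])
    if (!is.null(msg)) {
      stop(netanim_error(sprintf(
        "invalid value for %s property '%s' on '%s': %s", category, k, id, msg)))
    }
  }
  invisible(TRUE)
}

#' Construct a styled network scene
#'
#' A scene holds network-level visual properties (background paint, camera
#' center and scale factor, canvas width/height), plus styled nodes, edges
#' and annotations. Coordinates follow the screen convention: x grows
#' rightward, y grows downward, and node `x`/`y` denote the node center.
#' Any property not supplied is filled with its documented default, so the
#' property map of every object is total.
#'
#' @param network Named list of network properties (see
#'   `vp_registry("network")`).
#' @param nodes Named list: node id -> named list of node properties.
#' @param edges Named list: edge id -> list with `source`, `target` (node
#'   ids) and optional named properties under `props` or inline.
#' @param annotations Named list: annotation id -> list with `type` (one of
#'   `"shape"`, `"text"`, `"image"`, `"arrow"`) and named properties.
#' @return A `netanim_scene` object.
#' @examples
#' sc <- scene_state(
#'   nodes = list(A = list(x = 0, y = 0, fill_color = c(255L, 0L, 0L, 255L)),
#'                B = list(x = 60, y = 0)),
#'   edges = list(e1 = list(source = "A", target = "B")))
#' @export
scene_state <- function(network = list(), nodes = list(), edges = list(),
                        annotations = list()) {
  net <- totalize_props(network, "network")
  validate_props(net, "network", "<network>")

  check_ids <- function(x, what) {
    if (length(x)) {
      ids <- names(x)
      if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
        stop(netanim_error(sprintf("every %s must have a non-empty id", what)))
      if (anyDuplicated(ids))
        stop(netanim_error(sprintf(
          "duplicate %s id '%s'", what, ids[duplicated(ids)][[1L]])))
    }
    invisible(TRUE)
  }
  check_ids(nodes, "node")
  check_ids(edges, "edge")
  check_ids(annotations, "annotation")

  nodes <- lapply(stats::setNames(names(nodes), names(nodes)), function(id) {
    p <- totalize_props(nodes[[id]], "node", id)
    validate_props(p, "node", id)
    p
  })

  edges <- lapply(stats::setNames(names(edges), names(edges)), function(id) {
    e <- edges[[id]]
    if (is.null(e$source) || is.null(e$target))
      stop(netanim_error(sprintf("edge '%s' must declare source and target", id)))
    if (!(e$source %in% names(nodes)))
      stop(netanim_error(sprintf(
        "edge '%s' references unknown source node '%s'", id, e$source)))
    if (!(e$target %in% names(nodes)))
      stop(netanim_error(sprintf(
        "edge '%s' references unknown target node '%s'", id, e$target)))
    props <- if (!is.null(e$props)) e$props else
      e[setdiff(names(e), c("source", "target", "props"))]
    p <- totalize_props(props, "edge", id)
    validate_props(p, "edge", id)
    list(source = e$source, target = e$target, props = p)
  })

  annotations <- lapply(stats::setNames(names(annotations), names(annotations)),
                        function(id) {
    a <- annotations[[id]]
    type <- if (is.null(a$type)) "shape" else a$type
    if (!(type %in% c("shape", "text", "image", "arrow")))
      stop(netanim_error(sprintf(
        "annotation '%s' has unknown type '%s' (use shape|text|image|arrow)",
        id, type)))
    props <- if (!is.null(a$props)) a$props else a[setdiff(names(a), c("type", "props"))]
    p <- totalize_props(props, "annotation", id)
    validate_props(p, "annotation", id)
    if (!(p$canvas %in% c("foreground", "background")))
      stop(netanim_error(sprintf(
        "annotation '%s' canvas must be 'foreground' or 'background'", id)))
    list(type = type, props = p)
  })

  structure(list(network = net, nodes = nodes, edges = edges,
                 annotations = annotations),
            class = "netanim_scene")
}

#' @export
print.netanim_scene <- function(x, ...) {
  cat(sprintf("<netanim scene: %d nodes, %d edges, %d annotations>\n",
              length(x$nodes), length(x$edges), length(x$annotations)))
  invisible(x)
}

is_scene <- function(x) inherits(x, "netanim_scene")

#' Capture a scene as a key frame
#'
#' Snapshots the four property maps (network, nodes, edges, annotations) of a
#' scene at a timeline position. The stored maps are independent copies:
#' mutating the scene afterwards never alters a captured frame.
#'
#' @param scene A `netanim_scene`.
#' @param time_s Timeline position in seconds (finite, >= 0), or `NA` to let
#'   the timeline assign a default position on insertion.
#' @param frame_id Optional frame identifier; defaults to `"frame_<time>"`.
#' @param thumbnail Optional raster array stored verbatim.
#' @return A `netanim_keyframe`.
#' @export
capture_frame <- function(scene, time_s = NA_real_, frame_id = NULL,
                          thumbnail = NULL) {
  if (!is_scene(scene))
    stop(netanim_error("capture_frame() expects a netanim_scene"))
  if (!is.na(time_s)) {
    if (!(is.numeric(time_s) && length(time_s) == 1L && is.finite(time_s) &&
          time_s >= 0))
      stop(netanim_error("time_s must be a finite non-negative number",
                         class = "netanim_range_error"))
    time_s <- as.numeric(time_s)
  }
  if (is.null(frame_id)) {
    frame_id <- if (is.na(time_s)) sprintf("frame_%08x", sample.int(.Machine$integer.max, 1L))
                else sprintf("frame_t%g", time_s)
  }
  structure(list(frame_id = frame_id, time_s = time_s,
                 network = scene$network, nodes = scene$nodes,
                 edges = scene$edges, annotations = scene$annotations,
                 thumbnail = thumbnail),
            class = "netanim_keyframe")
}

is_keyframe <- function(x) inherits(x, "netanim_keyframe")

#' @export
print.netanim_keyframe <- function(x, ...) {
  cat(sprintf("<netanim key frame '%s' @ %s s: %d nodes, %d edges, %d annotations>\n",
              x$frame_id, format(x$time_s), length(x$nodes), length(x$edges),
              length(x$annotations)))
  invisible(x)
}

#' Rebuild a scene from a key frame
#'
#' Maps the stored visual properties back onto a scene. Objects present in
#' the frame get exactly their stored style; objects the current scene lacks
#' are added back, styled from the stored information; objects of the
#' universe that the frame lacks are kept but hidden (visibility `FALSE` for
#' nodes and edges, opacity 0 for annotations).
#'
#' @param frame A `netanim_keyframe` (ideally reconciled, see
#'   [reconcile_frame()]).
#' @param scene The current scene the frame is applied to.
#' @param universe An object universe from [union_topology()]; defaults to
#'   the union of `frame` and `scene` objects.
#' @return A new `netanim_scene`.
#' @export
apply_frame <- function(frame, scene, universe = NULL) {
  if (!is_keyframe(frame)) stop(netanim_error("apply_frame() expects a key frame"))
  if (!is_scene(scene)) stop(netanim_error("apply_frame() expects a netanim_scene"))
  if (is.null(universe)) {
    universe <- union_topology(list(frame, capture_frame(scene, 0)))
  }
  bad <- c(setdiff(names(frame$nodes), universe$node_ids),
           setdiff(names(frame$edges), universe$edge_ids),
           setdiff(names(frame$annotations), universe$annotation_ids))
  if (length(bad)) {
    stop(netanim_error(sprintf(
      "frame references object '%s' not in the universe", bad[[1L]]),
      class = "netanim_consistency_error"))
  }

  nodes <- scene$nodes
  for (id in names(frame$nodes)) nodes[[id]] <- frame$nodes[[id]]
  for (id in setdiff(names(nodes), names(frame$nodes)))
    nodes[[id]]$visible <- FALSE

  edges <- scene$edges
  for (id in names(frame$edges)) edges[[id]] <- frame$edges[[id]]
  for (id in setdiff(names(edges), names(frame$edges)))
    edges[[id]]$props$visible <- FALSE

  annotations <- scene$annotations
  for (id in names(frame$annotations)) annotations[[id]] <- frame$annotations[[id]]
  for (id in setdiff(names(annotations), names(frame$annotations)))
    annotations[[id]]$props$opacity <- 0

  structure(list(network = frame$network, nodes = nodes, edges = edges,
                 annotations = annotations),
            class = "netanim_scene")
}

# Pull the flat props list of an object entry in a frame/scene map.
object_props <- function(entry, category) {
  if (category %in% c("edge", "annotation")) entry$props else entry
}

prop_values_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  isTRUE(all.equal(unclass(a), unclass(b), check.attributes = FALSE))
}

#' Properties that differ between two key frames
#'
#' Enumerates every (object, property) pair whose value differs between two
#' frames, including keys of objects present in only one frame. Drives the
#' per-segment summary of what needs interpolating.
#'
#' @param a,b `netanim_keyframe` objects.
#' @return A data frame with columns `category`, `id`, `name`.
#' @export
frame_diff <- function(a, b) {
  if (!is_keyframe(a) || !is_keyframe(b))
    stop(netanim_error("frame_diff() expects two key frames"))
  out <- list()
  push <- function(category, id, name) {
    out[[length(out) + 1L]] <<- data.frame(
      category = category, id = id, name = name, stringsAsFactors = FALSE)
  }
  categories <- c(network = "network", nodes = "node", edges = "edge",
                  annotations = "annotation")
  for (fld in names(categories)) {
    cat_name <- categories[[fld]]
    if (fld == "network") {
      pa <- list(`<network>` = a$network)
      pb <- list(`<network>` = b$network)
    } else {
      pa <- a[[fld]]
      pb <- b[[fld]]
    }
    for (id in union(names(pa), names(pb))) {
      ea <- pa[[id]]; eb <- pb[[id]]
      prop_a <- if (is.null(ea)) NULL else if (fld == "network") ea else object_props(ea, cat_name)
      prop_b <- if (is.null(eb)) NULL else if (fld == "network") eb else object_props(eb, cat_name)
      keys <- union(names(prop_a), names(prop_b))
      for (k in keys) {
        if (!prop_values_equal(prop_a[[k]], prop_b[[k]])) push(cat_name, id, k)
      }
    }
  }
  if (!length(out))
    return(data.frame(category = character(), id = character(),
                      name = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
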