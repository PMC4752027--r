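# Reconciliation: key frames in one storyboard may add or remove objects.
# The union of all objects over the timeline forms the object universe (the
# headless analogue of a shared root network); every frame is then completed
# so that each universe object has defined properties, with objects the
# frame lacks hidden. After reconciliation all frames carry identical
# object-id sets, which is what makes per-property interpolation total.

#' Union object universe over key frames
#'
#' Collects the exact union of node, edge and annotation ids over a list of
#' key frames, together with edge endpoints and annotation types. Frames in
#' one storyboard are assumed to belong to one network collection; an edge
#' id appearing with different endpoints in two frames is a conflict.
#'
#' @param frames List of `netanim_keyframe` objects (at least one).
#' @return A `netanim_universe` with fields `node_ids`, `edge_ids`,
#'   `annotation_ids`, `edge_endpoints` (id -> c(source, target)) and
#'   `annotation_types`.
#' @export
union_topology <- function(frames) {
  if (!length(frames)) {
    stop(netanim_error("union_topology() needs at least one frame",
                       class = "netanim_range_error"))
  }
  if (!all(vapply(frames, is_keyframe, logical(1L))))
    stop(netanim_error("union_topology() expects a list of key frames"))

  node_ids <- character(); edge_ids <- character(); ann_ids <- character()
  endpoints <- list(); ann_types <- list()
  for (f in frames) {
    node_ids <- union(node_ids, names(f$nodes))
    ann_ids <- union(ann_ids, names(f$annotations))
    for (id in names(f$edges)) {
      ep <- c(f$edges[[id]]$source, f$edges[[id]]$target)
      if (id %in% edge_ids) {
        if (!identical(endpoints[[id]], ep)) {
          stop(netanim_error(sprintf(
            "edge '%s' has conflicting endpoints across frames: (%s,%s) vs (%s,%s)",
            id, endpoints[[id]][1L], endpoints[[id]][2L], ep[1L], ep[2L]),
            class = "netanim_consistency_error"))
        }
      } else {
        edge_ids <- c(edge_ids, id)
        endpoints[[id]] <- ep
      }
    }
    for (id in names(f$annotations)) {
      if (is.null(ann_types[[id]])) ann_types[[id]] <- f$annotations[[id]]$type
    }
  }
  missing_ep <- setdiff(unique(unlist(endpoints)), node_ids)
  if (length(missing_ep)) {
    stop(netanim_error(sprintf(
      "edge endpoint node '%s' appears in no frame", missing_ep[[1L]]),
      class = "netanim_consistency_error"))
  }
  structure(list(node_ids = node_ids, edge_ids = edge_ids,
                 annotation_ids = ann_ids, edge_endpoints = endpoints,
                 annotation_types = ann_types),
            class = "netanim_universe")
}

is_universe <- function(x) inherits(x, "netanim_universe")

#' @export
print.netanim_universe <- function(x, ...) {
  cat(sprintf("<netanim universe: %d nodes, %d edges, %d annotations>\n",
              length(x$node_ids), length(x$edge_ids), length(x$annotation_ids)))
  invisible(x)
}

# Find the style donor for an object missing from `frame`: the nearest
# other frame (by |time difference|) that contains it; ties go to the
# earlier frame. Falls back to category defaults when no frame has it.
donor_props <- function(field, id, frame, donors) {
  have <- Filter(function(f) !is.null(f[[field]][[id]]), donors)
  if (!length(have)) return(NULL)
  t0 <- if (is.na(frame$time_s)) 0 else frame$time_s
  times <- vapply(have, function(f) if (is.na(f$time_s)) 0 else f$time_s,
                  numeric(1L))
  d <- abs(times - t0)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[which.min(times[best])]
  have[[best]][[field]][[id]]
}

#' Complete a key frame against the object universe
#'
#' Returns a frame holding an entry for every universe object. Objects the
#' input frame already had are passed through untouched. Objects it lacked
#' are inserted hidden -- `visible = FALSE` for nodes and edges, `opacity =
#' 0` for annotations -- with the remaining style copied from the nearest
#' (in time) donor frame that contains the object, so a later fade-in starts
#' from sensible coordinates and size. An edge whose endpoint node is hidden
#' in the frame is also forced hidden.
#'
#' @param frame A `netanim_keyframe` whose objects are contained in
#'   `universe`.
#' @param universe From [union_topology()].
#' @param donors Optional list of key frames searched for hidden-object
#'   style (typically the full timeline). Defaults to `list(frame)`.
#' @return A completed `netanim_keyframe`.
#' @export
reconcile_frame <- function(frame, universe, donors = list(frame)) {
  if (!is_keyframe(frame)) stop(netanim_error("reconcile_frame() expects a key frame"))
  if (!is_universe(universe)) stop(netanim_error("reconcile_frame() expects a universe"))
  bad <- c(setdiff(names(frame$nodes), universe$node_ids),
           setdiff(names(frame$edges), universe$edge_ids),
           setdiff(names(frame$annotations), universe$annotation_ids))
  if (length(bad)) {
    stop(netanim_error(sprintf(
      "frame '%s' contains object '%s' outside the universe",
      frame$frame_id, bad[[1L]]),
      class = "netanim_consistency_error"))
  }

  out <- frame
  for (id in setdiff(universe$node_ids, names(frame$nodes))) {
    p <- donor_props("nodes", id, frame, donors)
    if (is.null(p)) p <- vp_defaults("node")
    p$visible <- FALSE
    out$nodes[[id]] <- p
  }
  for (id in setdiff(universe$edge_ids, names(frame$edges))) {
    e <- donor_props("edges", id, frame, donors)
    if (is.null(e)) {
      e <- list(source = universe$edge_endpoints[[id]][1L],
                target = universe$edge_endpoints[[id]][2L],
                props = vp_defaults("edge"))
    }
    e$props$visible <- FALSE
    out$edges[[id]] <- e
  }
  for (id in setdiff(universe$annotation_ids, names(frame$annotations))) {
    a <- donor_props("annotations", id, frame, donors)
    if (is.null(a)) {
      a <- list(type = universe$annotation_types[[id]],
                props = vp_defaults("annotation"))
    }
    a$props$opacity <- 0
    out$annotations[[id]] <- a
  }
  # dangling edges: an edge is only visible when both endpoints are
  for (id in names(out$edges)) {
    e <- out$edges[[id]]
    if (isTRUE(e$props$visible)) {
      if (!isTRUE(out$nodes[[e$source]]$visible) ||
          !isTRUE(out$nodes[[e$target]]$visible)) {
        out$edges[[id]]$props$visible <- FALSE
      }
    }
  }
  out
}

#' Reconcile every frame of a timeline against the shared universe
#'
#' @param frames List of key frames.
#' @return List with `frames` (all reconciled, identical object-id sets) and
#'   `universe`.
#' @export
reconcile_timeline <- function(frames) {
  universe <- union_topology(frames)
  list(frames = lapply(frames, reconcile_frame, universe = universe,
                       donors = frames),
       universe = universe)
}
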