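# Tweening kernel. Each visual property is interpolated between the two key
# frames bounding a segment by the interpolator its registry kind selects:
# numbers and positions linearly, colors per RGB channel with a Bezier-eased
# alpha, categorical values by crossfade (fade out, switch at t = 1/2, fade
# in), visibility by a linear opacity ramp, and custom graphics by a
# simultaneous image blend.

round_half_up <- function(x) floor(x + 0.5)

#' Linear interpolation of a numeric value
#'
#' @param v0,v1 Finite numbers (segment start / end values).
#' @param t Interpolation parameter in `[0, 1]`.
#' @return `v0 + t * (v1 - v0)`, exact at the endpoints.
#' @export
lerp_number <- function(v0, v1, t) {
  if (!(is.numeric(t) && length(t) == 1L && is.finite(t) && t >= 0 && t <= 1))
    stop(netanim_error("t must lie in [0, 1]", class = "netanim_range_error"))
  if (!(is.finite(v0) && is.finite(v1)))
    stop(netanim_error("lerp_number() needs finite endpoints"))
  if (t == 0) return(v0)
  if (t == 1) return(v1)
  v0 + t * (v1 - v0)
}

#' Linear interpolation of an (x, y) position
#'
#' @param p0,p1 Numeric length-2 vectors.
#' @inheritParams lerp_number
#' @return Component-wise interpolated position.
#' @export
lerp_position <- function(p0, p1, t) {
  c(lerp_number(p0[[1L]], p1[[1L]], t), lerp_number(p0[[2L]], p1[[2L]], t))
}

#' Cubic Bezier easing curve
#'
#' Control points of a unit cubic Bezier with fixed endpoints (0,0) and
#' (1,1); the x component must be monotone so the curve defines a function
#' ease(x). Used to ease alpha fades so fade-in/fade-out looks natural.
#'
#' @param p1,p2 Numeric (x, y) control points with x in `[0, 1]`.
#' @return A `netanim_bezier` object.
#' @export
bezier_control <- function(p1 = c(0.25, 0.1), p2 = c(0.25, 1.0)) {
  if (!(is.numeric(p1) && length(p1) == 2L && is.numeric(p2) && length(p2) == 2L))
    stop(netanim_error("bezier control points must be numeric (x, y) pairs"))
  if (p1[[1L]] < 0 || p1[[1L]] > 1 || p2[[1L]] < 0 || p2[[1L]] > 1) {
    stop(netanim_error(
      "bezier control x coordinates must lie in [0, 1] (x must stay monotone)",
      class = "netanim_range_error"))
  }
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2)),
            class = "netanim_bezier")
}

# Evaluate one coordinate of the unit cubic Bezier at parameter u.
bezier_coord <- function(u, c1, c2) {
  3 * (1 - u)^2 * u * c1 + 3 * (1 - u) * u^2 * c2 + u^3
}

# ease(x): y-coordinate at the curve parameter whose x-coordinate equals x.
# x(u) is monotone for control x in [0,1]; solved by bisection to 1e-9.
bezier_ease <- function(x, ctrl) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (bezier_coord(mid, ctrl$p1[[1L]], ctrl$p2[[1L]]) < x) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  u <- (lo + hi) / 2
  bezier_coord(u, ctrl$p1[[2L]], ctrl$p2[[2L]])
}

#' Bezier-eased alpha interpolation
#'
#' Alpha channels of colors fade along a cubic Bezier easing curve rather
#' than linearly. Equal endpoints short-circuit.
#'
#' @param a0,a1 Integer alpha levels 0-255.
#' @param t Interpolation parameter in `[0, 1]`.
#' @param ctrl A [bezier_control()]; the default is the standard "ease"
#'   curve ((0.25, 0.1), (0.25, 1.0)).
#' @return Integer alpha level, rounded half-up.
#' @export
bezier_alpha <- function(a0, a1, t, ctrl = bezier_control()) {
  if (!(is.numeric(t) && length(t) == 1L && is.finite(t) && t >= 0 && t <= 1))
    stop(netanim_error("t must lie in [0, 1]", class = "netanim_range_error"))
  if (a0 < 0 || a0 > 255 || a1 < 0 || a1 > 255)
    stop(netanim_error("alpha levels must lie in [0, 255]"))
  if (a0 == a1) return(as.integer(a0))
  if (t == 0) return(as.integer(a0))
  if (t == 1) return(as.integer(a1))
  as.integer(round_half_up(a0 + bezier_ease(t, ctrl) * (a1 - a0)))
}

#' Linear RGBA color interpolation
#'
#' RGB channels interpolate linearly (rounded half-up to integers); the
#' alpha channel is eased through [bezier_alpha()].
#'
#' @param c0,c1 Integer RGBA 4-tuples with channels 0-255.
#' @inheritParams bezier_alpha
#' @return Integer RGBA 4-tuple.
#' @export
lerp_color <- function(c0, c1, t, ctrl = bezier_control()) {
  for (cc in list(c0, c1)) {
    msg <- check_domain_value(cc, "color")
    if (!is.null(msg)) stop(netanim_error(msg))
  }
  if (!(is.numeric(t) && length(t) == 1L && is.finite(t) && t >= 0 && t <= 1))
    stop(netanim_error("t must lie in [0, 1]", class = "netanim_range_error"))
  if (t == 0) return(as.integer(c0))
  if (t == 1) return(as.integer(c1))
  rgb <- as.integer(round_half_up(c0[1:3] + t * (c1[1:3] - c0[1:3])))
  a <- bezier_alpha(c0[[4L]], c1[[4L]], t, ctrl)
  c(rgb, a)
}

#' Interpolate an anchored offset
#'
#' Numeric offsets interpolate linearly; the anchor and justification pass
#' through unchanged. A change in anchor or justification is unsupported:
#' the value is held at its start until the end of the segment, then
#' snapped, and a warning is emitted.
#'
#' @param op0,op1 [object_position()] values.
#' @inheritParams lerp_number
#' @return An object position.
#' @export
lerp_object_position <- function(op0, op1, t) {
  if (!is_object_position(op0) || !is_object_position(op1))
    stop(netanim_error("lerp_object_position() expects object positions"))
  if (!identical(op0$anchor, op1$anchor) ||
      !identical(op0$justification, op1$justification)) {
    warning("object-position anchor/justification changes are not interpolated; holding start value until segment end",
            call. = FALSE)
    return(if (t < 1) op0 else op1)
  }
  object_position(op0$anchor, op0$justification,
                  lerp_number(op0$dx, op1$dx, t),
                  lerp_number(op0$dy, op1$dy, t))
}

#' Categorical crossfade
#'
#' Properties that cannot be blended numerically (shape, label text, font
#' face, line type, ...) transition by fading the object out with the old
#' value, switching at t = 1/2, and fading back in with the new value. The
#' returned opacity multiplier is applied to the rendered opacity of the
#' property's visual element. Equal values do not fade.
#'
#' @param v0,v1 Values of a shared domain.
#' @inheritParams lerp_number
#' @return List with `value` and `opacity` (multiplier in `[0, 1]`).
#' @export
crossfade_value <- function(v0, v1, t) {
  if (!(is.numeric(t) && length(t) == 1L && is.finite(t) && t >= 0 && t <= 1))
    stop(netanim_error("t must lie in [0, 1]", class = "netanim_range_error"))
  if (prop_values_equal(v0, v1)) return(list(value = v0, opacity = 1))
  if (t < 0.5) list(value = v0, opacity = 1 - 2 * t)
  else list(value = v1, opacity = 2 * t - 1)
}

#' Visibility fade
#'
#' When an object's visibility differs between the two key frames it fades
#' linearly: appearing objects ramp 0 -> 1, disappearing objects 1 -> 0.
#'
#' @param vis0,vis1 Logical visibility at segment start / end.
#' @inheritParams lerp_number
#' @return Opacity multiplier in `[0, 1]`.
#' @export
visibility_opacity <- function(vis0, vis1, t) {
  if (!(is.numeric(t) && length(t) == 1L && is.finite(t) && t >= 0 && t <= 1))
    stop(netanim_error("t must lie in [0, 1]", class = "netanim_range_error"))
  if (isTRUE(vis0) && isTRUE(vis1)) 1
  else if (!isTRUE(vis0) && !isTRUE(vis1)) 0
  else if (isTRUE(vis0)) 1 - t
  else t
}

#' Custom-graphics crossfade
#'
#' Two per-node custom graphics in the same slot blend simultaneously: the
#' outgoing image is drawn at opacity `1 - t` over the incoming one at
#' opacity `t` (an image-to-image dissolve, unlike the sequential
#' categorical crossfade). An empty slot on either side yields a plain
#' fade-out or fade-in.
#'
#' @param g0,g1 Image references (strings) or `NA` for an empty slot.
#' @inheritParams lerp_number
#' @return List of layers, each `list(ref =, opacity =)`; empty when both
#'   slots are empty.
#' @export
crossfade_custom_graphics <- function(g0, g1, t) {
  if (!(is.numeric(t) && length(t) == 1L && is.finite(t) && t >= 0 && t <= 1))
    stop(netanim_error("t must lie in [0, 1]", class = "netanim_range_error"))
  same <- (is.na(g0) && is.na(g1)) || (!is.na(g0) && !is.na(g1) && g0 == g1)
  layers <- list()
  if (same) {
    if (!is.na(g0)) layers[[1L]] <- list(ref = g0, opacity = 1)
    return(layers)
  }
  if (!is.na(g0) && t < 1) layers[[length(layers) + 1L]] <- list(ref = g0, opacity = 1 - t)
  if (!is.na(g1) && t > 0) layers[[length(layers) + 1L]] <- list(ref = g1, opacity = t)
  layers
}

# Dispatch one property through its registered interpolator. Returns
# list(value =, opacity =) where opacity is an element multiplier (NULL for
# kinds without one). `kind` and `domain` come from the registry.
interpolate_property <- function(name, category, v0, v1, t,
                                 ctrl = bezier_control()) {
  kind <- interpolator_for(name, category)
  switch(kind,
    Color = list(value = lerp_color(v0, v1, t, ctrl), opacity = NULL),
    Size = list(value = lerp_number(v0, v1, t), opacity = NULL),
    Transparency = list(value = round_half_up(lerp_number(v0, v1, t)),
                        opacity = NULL),
    Position = list(value = lerp_number(v0, v1, t), opacity = NULL),
    ObjectPosition = list(value = suppressWarnings(lerp_object_position(v0, v1, t)),
                          opacity = NULL),
    Crossfade = crossfade_value(v0, v1, t),
    CustomGraphicsCrossfade = list(value = crossfade_custom_graphics(v0, v1, t),
                                   opacity = NULL),
    Visible = list(value = if (t < 1) v0 else v1,
                   opacity = visibility_opacity(v0, v1, t)),
    None = list(value = if (t < 1) v0 else v1, opacity = NULL),
    stop(netanim_error(sprintf("unhandled interpolation kind '%s'", kind))))
}

# Visual element a crossfaded key belongs to: a fading label should not dim
# the node body and vice versa.
crossfade_element <- function(name) {
  if (name %in% c("label", "font_face", "font_style", "font_family", "text"))
    "label" else "body"
}

# Interpolate all properties of one object between two frames. Adds the
# composed element opacity multipliers as `.opacity` / `.label_opacity`.
interpolate_props <- function(p0, p1, category, t, ctrl) {
  out <- p0
  body_mult <- 1
  label_mult <- 1
  kinds <- .netanim$kind_map[[category]]
  for (k in names(p0)) {
    kind <- kinds[[k]]
    # unchanged values pass through; visibility still drives the opacity
    # multiplier (an object hidden on both sides must render at opacity 0)
    if (kind != "Visible" && prop_values_equal(p0[[k]], p1[[k]])) next
    r <- interpolate_property(k, category, p0[[k]], p1[[k]], t, ctrl)
    out[[k]] <- r$value
    if (!is.null(r$opacity)) {
      if (kind == "Visible") {
        body_mult <- body_mult * r$opacity
      } else if (crossfade_element(k) == "label") {
        label_mult <- label_mult * r$opacity
      } else {
        body_mult <- body_mult * r$opacity
      }
    }
  }
  out$.opacity <- body_mult
  out$.label_opacity <- body_mult * label_mult
  out
}

assert_reconciled <- function(frames) {
  ids <- function(f) list(n = sort(names(f$nodes)), e = sort(names(f$edges)),
                          a = sort(names(f$annotations)))
  ref <- ids(frames[[1L]])
  for (f in frames[-1L]) {
    if (!identical(ids(f), ref)) {
      stop(netanim_error(
        "key frames have differing object sets; reconcile them first (see reconcile_timeline())",
        class = "netanim_consistency_error"))
    }
  }
  invisible(TRUE)
}

interpolate_pair <- function(f0, f1, t, ctrl) {
  if (t == 0) {
    out <- f0
  } else {
    out <- f0
    out$network <- interpolate_props(f0$network, f1$network, "network", t, ctrl)
    out$nodes <- lapply(stats::setNames(names(f0$nodes), names(f0$nodes)),
                        function(id) interpolate_props(f0$nodes[[id]],
                                                       f1$nodes[[id]], "node", t, ctrl))
    out$edges <- lapply(stats::setNames(names(f0$edges), names(f0$edges)), function(id) {
      e <- f0$edges[[id]]
      e$props <- interpolate_props(f0$edges[[id]]$props, f1$edges[[id]]$props,
                                   "edge", t, ctrl)
      e
    })
    out$annotations <- lapply(stats::setNames(names(f0$annotations),
                                              names(f0$annotations)), function(id) {
      a <- f0$annotations[[id]]
      a$props <- interpolate_props(f0$annotations[[id]]$props,
                                   f1$annotations[[id]]$props, "annotation", t, ctrl)
      a
    })
  }
  out$thumbnail <- NULL
  out
}

#' Expand key frames into the full interpolated sequence
#'
#' For each segment `j` between consecutive key frames, with `counts[j]`
#' interpolations, frames are emitted at local `t = i / counts[j]` for
#' `i = 0 .. counts[j] - 1` (the segment's start key frame is its `i = 0`
#' frame), and the final key frame is appended once. The sequence length is
#' therefore `sum(counts) + 1`; with a constant `n` per segment and `k` key
#' frames that is `(k - 1) * n + 1` -- e.g. 5 key frames at 30 interpolations
#' each yield 121 frames.
#'
#' @param frames List of reconciled key frames (identical object sets; see
#'   [reconcile_timeline()]).
#' @param counts Integer vector of per-segment interpolation counts, length
#'   `length(frames) - 1`, all >= 1. A single number is recycled.
#' @param ctrl Bezier easing control for alpha fades.
#' @return A `netanim_sequence`: list with `frames` (each as a key frame,
#'   plus per-object `.opacity` / `.label_opacity` multipliers) and
#'   `provenance` (data frame of segment index and local t per frame).
#' @export
make_frames <- function(frames, counts = 30L, ctrl = bezier_control()) {
  if (!length(frames))
    stop(netanim_error("make_frames() needs at least one key frame",
                       class = "netanim_range_error"))
  k <- length(frames)
  if (k > 1L) {
    if (length(counts) == 1L) counts <- rep(counts, k - 1L)
    if (length(counts) != k - 1L) {
      stop(netanim_error(sprintf(
        "counts must have one entry per segment (%d), got %d",
        k - 1L, length(counts)), class = "netanim_range_error"))
    }
    counts <- as.integer(counts)
    if (any(is.na(counts)) || any(counts < 1L))
      stop(netanim_error("per-segment interpolation counts must be >= 1",
                         class = "netanim_range_error"))
    assert_reconciled(frames)
  } else {
    counts <- integer()
  }

  out <- list()
  prov <- list()
  if (k == 1L) {
    out[[1L]] <- interpolate_pair(frames[[1L]], frames[[1L]], 0, ctrl)
    prov[[1L]] <- data.frame(segment = 1L, t = 0)
  } else {
    for (j in seq_len(k - 1L)) {
      n <- counts[[j]]
      for (i in seq_len(n) - 1L) {
        out[[length(out) + 1L]] <-
          interpolate_pair(frames[[j]], frames[[j + 1L]], i / n, ctrl)
        prov[[length(prov) + 1L]] <- data.frame(segment = j, t = i / n)
      }
    }
    out[[length(out) + 1L]] <- interpolate_pair(frames[[k]], frames[[k]], 0, ctrl)
    prov[[length(prov) + 1L]] <- data.frame(segment = k - 1L, t = 1)
  }
  structure(list(frames = out, provenance = do.call(rbind, prov)),
            class = "netanim_sequence")
}

is_sequence <- function(x) inherits(x, "netanim_sequence")

#' @export
print.netanim_sequence <- function(x, ...) {
  cat(sprintf("<netanim frame sequence: %d frames>\n", length(x$frames)))
  invisible(x)
}

#' @export
length.netanim_sequence <- function(x) length(x$frames)
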