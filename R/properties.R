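# Visual-property registry: every styleable attribute of a network, node,
# edge or annotation, its value domain, and the interpolation kind assigned
# to it. The registry is total: capture records every key for every object,
# so interpolation pairs are always well defined.

#' The nine interpolation kinds
#'
#' Every visual property is tweened by exactly one of nine interpolator
#' categories: `Color` (per-channel linear RGB, Bezier-eased alpha), `Size`
#' (linear), `Transparency` (linear 0-255), `ObjectPosition` (linear offsets,
#' anchor/justification held fixed), `Position` (linear x/y), `Crossfade`
#' (categorical fade-out/fade-in), `CustomGraphicsCrossfade` (simultaneous
#' image blend), `Visible` (opacity ramp) and `None` (held, then snapped).
#'
#' @return Character vector of the nine kind names.
#' @export
interpolation_kinds <- function() {
  c("Color", "Size", "Transparency", "ObjectPosition", "Position",
    "Crossfade", "CustomGraphicsCrossfade", "Visible", "None")
}

# Internal constructor for one registry row.
vp_row <- function(name, category, domain, kind, slot = NA_integer_) {
  data.frame(name = name, category = category, domain = domain,
             kind = kind, slot = slot, stringsAsFactors = FALSE)
}

build_registry <- function() {
  rows <- list()
  add <- function(names, category, domain, kind) {
    for (nm in names) rows[[length(rows) + 1L]] <<- vp_row(nm, category, domain, kind)
  }
  add_slots <- function(stem, category, domain, kind) {
    for (i in 1:9) {
      rows[[length(rows) + 1L]] <<-
        vp_row(sprintf("%s_%d", stem, i), category, domain, kind, slot = i)
    }
  }

  ## network
  add("background_paint", "network", "color", "Color")
  add(c("center_x", "center_y", "center_z"), "network", "number", "Position")
  add(c("depth", "height", "scale_factor", "size", "width"),
      "network", "number", "Size")

  ## node
  add(c("border_paint", "fill_color", "label_color"), "node", "color", "Color")
  add(c("border_transparency", "label_transparency", "transparency"),
      "node", "number", "Transparency")
  add(c("border_width", "height", "width", "size", "label_size"),
      "node", "number", "Size")
  add_slots("custom_graphics_size", "node", "number", "Size")
  add(c("x", "y", "z"), "node", "number", "Position")
  add(c("shape", "font_face"), "node", "enum", "Crossfade")
  add("label", "node", "text", "Crossfade")
  add("label_position", "node", "object_position", "ObjectPosition")
  add_slots("custom_graphics_position", "node", "object_position", "ObjectPosition")
  add_slots("custom_graphics", "node", "image_ref", "CustomGraphicsCrossfade")
  add("nested_network_visible", "node", "boolean", "None")
  add("visible", "node", "boolean", "Visible")

  ## edge
  add(c("label_color", "paint"), "edge", "color", "Color")
  add("label", "edge", "text", "Crossfade")
  add(c("font_face", "line_type"), "edge", "enum", "Crossfade")
  add(c("label_transparency", "transparency"), "edge", "number", "Transparency")
  add(c("width", "label_size"), "edge", "number", "Size")
  add("visible", "edge", "boolean", "Visible")

  ## annotation
  add(c("x", "y"), "annotation", "number", "Position")
  add(c("zoom", "width", "height", "border_width", "font_size",
        "image_contrast", "image_brightness", "arrow_source_size",
        "arrow_width", "arrow_target_size"), "annotation", "number", "Size")
  add(c("color", "font_color", "border_color", "arrow_source_color",
        "arrow_target_color", "arrow_color"), "annotation", "color", "Color")
  add(c("opacity", "image_opacity"), "annotation", "number", "Transparency")
  add(c("shape", "font_style", "font_family", "arrow_source_anchor",
        "arrow_target_anchor", "arrow_source_type", "arrow_target_type"),
      "annotation", "enum", "Crossfade")
  add(c("text", "image_url"), "annotation", "text", "Crossfade")
  add("canvas", "annotation", "enum", "None")

  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  reg
}

.netanim <- new.env(parent = emptyenv())
.netanim$registry <- build_registry()
# per-category name -> kind / domain fast lookups (hot path of make_frames)
.netanim$kind_map <- lapply(
  stats::setNames(nm = c("network", "node", "edge", "annotation")),
  function(cc) {
    reg <- .netanim$registry[.netanim$registry$category == cc, ]
    stats::setNames(reg$kind, reg$name)
  })
.netanim$domain_map <- lapply(
  stats::setNames(nm = c("network", "node", "edge", "annotation")),
  function(cc) {
    reg <- .netanim$registry[.netanim$registry$category == cc, ]
    stats::setNames(reg$domain, reg$name)
  })

#' Visual-property registry
#'
#' The complete table of registered visual properties. Each key is identified
#' by `(category, name)`; `domain` is its value domain (`color`, `number`,
#' `object_position`, `text`, `enum`, `boolean`, `image_ref`) and `kind` the
#' interpolation category applied between key frames. Custom-graphics keys
#' carry a `slot` index 1-9.
#'
#' @param category Optional filter: one of `"network"`, `"node"`, `"edge"`,
#'   `"annotation"`.
#' @return A data frame with columns `name`, `category`, `domain`, `kind`,
#'   `slot`.
#' @export
vp_registry <- function(category = NULL) {
  reg <- .netanim$registry
  if (!is.null(category)) {
    category <- match.arg(category, c("network", "node", "edge", "annotation"))
    reg <- reg[reg$category == category, , drop = FALSE]
    rownames(reg) <- NULL
  }
  reg
}

#' Look up the interpolation kind for a visual property
#'
#' @param name Property name, e.g. `"fill_color"`.
#' @param category Object category: `"network"`, `"node"`, `"edge"` or
#'   `"annotation"`.
#' @return A single kind name (see [interpolation_kinds()]).
#' @examples
#' interpolator_for("fill_color", "node")   # "Color"
#' interpolator_for("shape", "node")        # "Crossfade"
#' @export
interpolator_for <- function(name, category) {
  hit <- unname(.netanim$kind_map[[category]][name])
  if (length(hit) != 1L || is.na(hit)) {
    stop(netanim_error(
      sprintf("no registered visual property '%s' in category '%s'",
              name, category),
      class = "netanim_lookup_error"))
  }
  hit
}

#' Property domain for a registered key
#' @inheritParams interpolator_for
#' @return Domain string, e.g. `"color"`.
#' @export
vp_domain <- function(name, category) {
  hit <- unname(.netanim$domain_map[[category]][name])
  if (length(hit) != 1L || is.na(hit)) {
    stop(netanim_error(
      sprintf("no registered visual property '%s' in category '%s'",
              name, category),
      class = "netanim_lookup_error"))
  }
  hit
}

# Documented defaults: capture fills unset keys with these so property maps
# are total per object.
vp_defaults <- function(category) {
  op0 <- object_position()
  switch(category,
    network = list(
      background_paint = c(255L, 255L, 255L, 255L),
      center_x = 0, center_y = 0, center_z = 0,
      depth = 0, height = 720, width = 1280,
      scale_factor = 1, size = 0),
    node = c(
      list(
        border_paint = c(0L, 0L, 0L, 255L),
        fill_color = c(200L, 200L, 200L, 255L),
        label_color = c(0L, 0L, 0L, 255L),
        border_transparency = 255, label_transparency = 255,
        transparency = 255,
        border_width = 1, height = 35, width = 35, size = 35,
        label_size = 12,
        x = 0, y = 0, z = 0,
        shape = "ellipse", label = "", font_face = "plain",
        label_position = op0,
        nested_network_visible = FALSE, visible = TRUE),
      stats::setNames(rep(list(0), 9), sprintf("custom_graphics_size_%d", 1:9)),
      stats::setNames(rep(list(op0), 9), sprintf("custom_graphics_position_%d", 1:9)),
      stats::setNames(rep(list(NA_character_), 9), sprintf("custom_graphics_%d", 1:9))),
    edge = list(
      label_color = c(0L, 0L, 0L, 255L),
      paint = c(120L, 120L, 120L, 255L),
      label = "", font_face = "plain", line_type = "solid",
      label_transparency = 255, transparency = 255,
      width = 2, label_size = 10, visible = TRUE),
    annotation = list(
      x = 0, y = 0, zoom = 1, width = 100, height = 50,
      border_width = 1, font_size = 12,
      image_contrast = 0, image_brightness = 0,
      arrow_source_size = 6, arrow_width = 2, arrow_target_size = 6,
      color = c(200L, 200L, 200L, 255L),
      font_color = c(0L, 0L, 0L, 255L),
      border_color = c(0L, 0L, 0L, 255L),
      arrow_source_color = c(0L, 0L, 0L, 255L),
      arrow_target_color = c(0L, 0L, 0L, 255L),
      arrow_color = c(0L, 0L, 0L, 255L),
      opacity = 255, image_opacity = 255,
      shape = "rectangle", text = "", font_style = "plain",
      font_family = "plain", image_url = NA_character_,
      arrow_source_anchor = "c", arrow_target_anchor = "c",
      arrow_source_type = "none", arrow_target_type = "triangle",
      canvas = "foreground"),
    stop("unknown category: ", category))
}

#' Anchored offset for labels and custom graphics
#'
#' An object position is an anchor point on the owner's bounding box plus a
#' numeric offset in model units. Offsets interpolate linearly; changes in
#' anchor or justification are not supported by the interpolator (the value
#' is held, then snapped at the end of the segment, with a warning).
#'
#' @param anchor One of the compass anchors `"c"`, `"n"`, `"s"`, `"e"`,
#'   `"w"`, `"ne"`, `"nw"`, `"se"`, `"sw"`.
#' @param justification Text justification `"l"`, `"c"` or `"r"`.
#' @param dx,dy Offset from the anchor, model units.
#' @return A list of class `netanim_object_position`.
#' @export
object_position <- function(anchor = "c", justification = "c", dx = 0, dy = 0) {
  anchors <- c("c", "n", "s", "e", "w", "ne", "nw", "se", "sw")
  if (!(is.character(anchor) && length(anchor) == 1L && anchor %in% anchors))
    stop(netanim_error("object position anchor must be one of: c n s e w ne nw se sw"))
  if (!(is.character(justification) && length(justification) == 1L &&
        justification %in% c("l", "c", "r")))
    stop(netanim_error("object position justification must be one of: l c r"))
  structure(list(anchor = anchor, justification = justification,
                 dx = as.numeric(dx), dy = as.numeric(dy)),
            class = "netanim_object_position")
}

is_object_position <- function(x) inherits(x, "netanim_object_position")

# Condition constructor shared across the package. Error classes:
#   netanim_validation_error  invalid scene/frame/property data
#   netanim_lookup_error      unregistered key / unknown id
#   netanim_consistency_error cross-frame inconsistency (reconciliation)
#   netanim_range_error       numeric argument out of range
#   netanim_io_error          file I/O
#   netanim_usage_error       CLI usage
netanim_error <- function(message, class = "netanim_validation_error",
                          call = sys.call(-1)) {
  structure(class = c(class, "netanim_error", "error", "condition"),
            list(message = message, call = call))
}

# Validate a single value against a property domain. Returns NULL or an
# error message string (caller attaches object/key context).
check_domain_value <- function(value, domain) {
  switch(domain,
    color = {
      if (!(is.numeric(value) && length(value) == 4L && !anyNA(value) &&
            all(value == floor(value)) && all(value >= 0) && all(value <= 255)))
        return("colors must be integer RGBA 4-tuples with channels in [0, 255]")
      NULL
    },
    number = {
      if (!(is.numeric(value) && length(value) == 1L && is.finite(value)))
        return("numeric properties must be finite scalars")
      NULL
    },
    object_position = {
      if (!is_object_position(value))
        return("expected an object position (see object_position())")
      if (!(is.finite(value$dx) && is.finite(value$dy)))
        return("object position offsets must be finite")
      NULL
    },
    text = {
      if (!(length(value) == 1L &&
            (is.character(value) || is.na(value))))
        return("text properties must be single strings (or NA)")
      NULL
    },
    enum = {
      if (!(is.character(value) && length(value) == 1L && !is.na(value)))
        return("enum properties must be single non-NA strings")
      NULL
    },
    boolean = {
      if (!(is.logical(value) && length(value) == 1L && !is.na(value)))
        return("boolean properties must be single TRUE/FALSE values")
      NULL
    },
    image_ref = {
      if (!(length(value) == 1L && (is.character(value) || is.na(value))))
        return("image references must be single strings (or NA for an empty slot)")
      NULL
    },
    sprintf("unknown domain '%s'", domain))
}
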