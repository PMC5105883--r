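# Cytoscape-side data model: network topology, visual style, element views.

.node_vp_keys <- c(
  "NODE_LABEL", "NODE_BORDER_PAINT", "NODE_FILL_COLOR", "NODE_BORDER_WIDTH",
  "NODE_WIDTH", "NODE_HEIGHT", "NODE_SHAPE", "NODE_LABEL_FONT_FACE",
  "NODE_LABEL_FONT_SIZE", "NODE_LABEL_FONT_COLOR", "NODE_X_POSITION",
  "NODE_Y_POSITION", "NODE_TOOLTIP", "NODE_BORDER_LINE_TYPE", "NODE_VISIBLE",
  "NODE_TRANSPARENCY"
)
.edge_vp_keys <- c(
  "EDGE_LABEL", "EDGE_UNSELECTED_PAINT", "EDGE_WIDTH", "EDGE_LABEL_FONT_FACE",
  "EDGE_LABEL_FONT_SIZE", "EDGE_LABEL_FONT_COLOR", "EDGE_LINE_TYPE",
  "EDGE_VISIBLE", "EDGE_TARGET_ARROW_SHAPE", "EDGE_SOURCE_ARROW_SHAPE",
  "EDGE_TOOLTIP"
)
.network_vp_keys <- c("NETWORK_BACKGROUND_PAINT", "NETWORK_TITLE")

.node_shapes <- c("ellipse", "circle", "triangle", "diamond", "hexagon",
                  "octagon", "parallelogram", "rectangle", "square",
                  "round-rectangle")
.arrow_shapes <- c("vee", "lvee", "rvee", "dot", "normal", "diamond", "none",
                   "tee")
.line_types <- c("solid", "dashed", "dotted")

# visual-property value classes, used for JSON (de)serialization and
# validation
.vp_color_keys <- c("NODE_BORDER_PAINT", "NODE_FILL_COLOR",
                    "NODE_LABEL_FONT_COLOR", "EDGE_UNSELECTED_PAINT",
                    "EDGE_LABEL_FONT_COLOR", "NETWORK_BACKGROUND_PAINT")
.vp_numeric_keys <- c("NODE_BORDER_WIDTH", "NODE_WIDTH", "NODE_HEIGHT",
                      "NODE_LABEL_FONT_SIZE", "NODE_X_POSITION",
                      "NODE_Y_POSITION", "NODE_TRANSPARENCY", "EDGE_WIDTH",
                      "EDGE_LABEL_FONT_SIZE")
.vp_logical_keys <- c("NODE_VISIBLE", "EDGE_VISIBLE")

#' Visual property keys
#'
#' The closed set of visual-property keys the converter maps between DOT
#' attributes and Cytoscape views, grouped by the class of element they
#' apply to.
#'
#' @param class `"node"`, `"edge"`, `"network"`, or `"all"`.
#' @return A character vector of key names.
#' @export
visual_property_keys <- function(class = c("all", "node", "edge", "network")) {
  class <- match.arg(class)
  switch(class,
    all = c(.node_vp_keys, .edge_vp_keys, .network_vp_keys),
    node = .node_vp_keys,
    edge = .edge_vp_keys,
    network = .network_vp_keys
  )
}

# -- colors ------------------------------------------------------------------

#' RGBA color quadruple
#'
#' @param r,g,b,a Channel values, integers in `[0, 255]`; alpha defaults to
#'   opaque.
#' @return An object of class `rgba`.
#' @export
rgba <- function(r, g, b, a = 255L) {
  v <- as.integer(c(r = r, g = g, b = b, a = a))
  if (any(is.na(v)) || any(v < 0L) || any(v > 255L)) {
    stop("rgba channels must be integers in [0, 255]")
  }
  structure(stats::setNames(v, c("r", "g", "b", "a")), class = "rgba")
}

is_rgba <- function(x) inherits(x, "rgba")

#' @export
print.rgba <- function(x, ...) {
  cat(sprintf("<rgba %s>\n", format_color(x)))
  invisible(x)
}

#' @export
format.rgba <- function(x, ...) format_color(x)

# -- visual style ------------------------------------------------------------

.check_style_value <- function(key, value) {
  if (key %in% .vp_color_keys && !is_rgba(value)) {
    stop(sprintf("%s must be an rgba color", key))
  }
  if (key %in% .vp_numeric_keys && !is.numeric(value)) {
    stop(sprintf("%s must be numeric", key))
  }
  if (key %in% .vp_logical_keys && !is.logical(value)) {
    stop(sprintf("%s must be logical", key))
  }
  if (key == "NODE_SHAPE" && !value %in% .node_shapes) {
    stop(sprintf("unknown node shape '%s'", value))
  }
  if (key %in% c("EDGE_TARGET_ARROW_SHAPE", "EDGE_SOURCE_ARROW_SHAPE") &&
      !value %in% .arrow_shapes) {
    stop(sprintf("unknown arrow shape '%s'", value))
  }
  if (key %in% c("NODE_BORDER_LINE_TYPE", "EDGE_LINE_TYPE") &&
      !value %in% .line_types) {
    stop(sprintf("unknown line type '%s'", value))
  }
  invisible(TRUE)
}

new_visual_style <- function(defaults) {
  required <- setdiff(visual_property_keys(),
                      c("NODE_X_POSITION", "NODE_Y_POSITION"))
  missing <- setdiff(required, names(defaults))
  if (length(missing)) {
    stop("visual style is missing defaults for: ",
         paste(missing, collapse = ", "))
  }
  for (key in names(defaults)) .check_style_value(key, defaults[[key]])
  structure(list(defaults = defaults), class = "cy_visual_style")
}

#' Visual style seeded with Graphviz implicit attribute values
#'
#' Builds a fully-populated visual style whose defaults are Graphviz's
#' documented implicit attribute values, mapped through the import rules:
#' shape `ellipse`, node size 0.5 in x 0.75 in (36 pt x 54 pt), `penwidth` 1,
#' font `Times-Roman` at 14 pt in black, light-grey fill (used when a node is
#' `filled`), solid lines, and a white background. Nodes are opaque only when
#' the `filled` style keyword is present, so the transparency default is 0.
#'
#' @return A `cy_visual_style`.
#' @seealso [cytoscape_default_style()], [import_document()]
#' @export
dot_implicit_style <- function() {
  black <- rgba(0, 0, 0)
  new_visual_style(list(
    NODE_LABEL = "\\N",
    NODE_BORDER_PAINT = black,
    NODE_FILL_COLOR = rgba(211, 211, 211),
    NODE_BORDER_WIDTH = 1,
    NODE_WIDTH = 54,
    NODE_HEIGHT = 36,
    NODE_SHAPE = "ellipse",
    NODE_LABEL_FONT_FACE = "Times-Roman",
    NODE_LABEL_FONT_SIZE = 14,
    NODE_LABEL_FONT_COLOR = black,
    NODE_TOOLTIP = "",
    NODE_BORDER_LINE_TYPE = "solid",
    NODE_VISIBLE = TRUE,
    NODE_TRANSPARENCY = 0,
    EDGE_LABEL = "",
    EDGE_UNSELECTED_PAINT = black,
    EDGE_WIDTH = 1,
    EDGE_LABEL_FONT_FACE = "Times-Roman",
    EDGE_LABEL_FONT_SIZE = 14,
    EDGE_LABEL_FONT_COLOR = black,
    EDGE_LINE_TYPE = "solid",
    EDGE_VISIBLE = TRUE,
    EDGE_TARGET_ARROW_SHAPE = "normal",
    EDGE_SOURCE_ARROW_SHAPE = "none",
    EDGE_TOOLTIP = "",
    NETWORK_BACKGROUND_PAINT = rgba(255, 255, 255),
    NETWORK_TITLE = ""
  ))
}

#' Visual style matching the stock Cytoscape defaults
#'
#' The default style a freshly imported network starts from: rounded
#' rectangles of 35 pt x 75 pt with no border ink, light-blue fill, sans
#' fonts, 2 pt dark-grey edges without arrows, and a white background. These
#' are the values a stock Cytoscape session assigns before any DOT defaults
#' override them; [import_document()] uses this style as its seed so that
#' re-exporting an imported network reproduces the conventional header and
#' default statements.
#'
#' @return A `cy_visual_style`.
#' @seealso [dot_implicit_style()]
#' @export
cytoscape_default_style <- function() {
  black <- rgba(0, 0, 0)
  new_visual_style(list(
    NODE_LABEL = "",
    NODE_BORDER_PAINT = rgba(204, 204, 204),
    NODE_FILL_COLOR = rgba(137, 208, 245),
    NODE_BORDER_WIDTH = 0,
    NODE_WIDTH = 75,
    NODE_HEIGHT = 35,
    NODE_SHAPE = "round-rectangle",
    NODE_LABEL_FONT_FACE = "SansSerif.plain",
    NODE_LABEL_FONT_SIZE = 12,
    NODE_LABEL_FONT_COLOR = black,
    NODE_TOOLTIP = "",
    NODE_BORDER_LINE_TYPE = "solid",
    NODE_VISIBLE = TRUE,
    NODE_TRANSPARENCY = 255,
    EDGE_LABEL = "",
    EDGE_UNSELECTED_PAINT = rgba(64, 64, 64),
    EDGE_WIDTH = 2,
    EDGE_LABEL_FONT_FACE = "Dialog.plain",
    EDGE_LABEL_FONT_SIZE = 10,
    EDGE_LABEL_FONT_COLOR = black,
    EDGE_LINE_TYPE = "solid",
    EDGE_VISIBLE = TRUE,
    EDGE_TARGET_ARROW_SHAPE = "none",
    EDGE_SOURCE_ARROW_SHAPE = "none",
    EDGE_TOOLTIP = "",
    NETWORK_BACKGROUND_PAINT = rgba(255, 255, 255),
    NETWORK_TITLE = ""
  ))
}

#' @export
print.cy_visual_style <- function(x, ...) {
  cat(sprintf("<cy_visual_style: %d defaults>\n", length(x$defaults)))
  invisible(x)
}

# -- network -----------------------------------------------------------------

#' Create an empty network
#'
#' A network holds topology only: a name, a directedness flag, node records
#' (SUID and shared name), edge records (SUID, source, target) and a per-edge
#' data table with a nullable `weight` column. Visual information lives in a
#' [cytoscape_default_style()]-like style and in per-element views.
#'
#' @param name Network name.
#' @param directed Whether edges are directed.
#' @return A `cy_network`.
#' @export
cy_network <- function(name = "", directed = FALSE) {
  structure(list(
    name = name,
    directed = isTRUE(directed),
    nodes = data.frame(suid = integer(0), shared_name = character(0),
                       stringsAsFactors = FALSE),
    edges = data.frame(suid = integer(0), source_suid = integer(0),
                       target_suid = integer(0)),
    edge_table = data.frame(suid = integer(0), weight = numeric(0))
  ), class = "cy_network")
}

#' Next free SUID for a network
#'
#' SUIDs (Cytoscape's unique element identifiers) are positive integers
#' assigned sequentially from 1 within an import session. The next free SUID
#' is one more than the largest SUID in use, so successive allocations are
#' strictly increasing and never repeat.
#'
#' @param network A `cy_network`.
#' @return A positive integer not yet used in the network.
#' @export
fresh_suid <- function(network) {
  used <- c(network$nodes$suid, network$edges$suid, 0L)
  max(used) + 1L
}

#' Add a node to a network
#'
#' @param network A `cy_network`.
#' @param shared_name Node name, preserved verbatim from the DOT id on
#'   import.
#' @return The network with one more node; its SUID is `fresh_suid()` of the
#'   input network.
#' @export
add_node <- function(network, shared_name) {
  suid <- fresh_suid(network)
  network$nodes[nrow(network$nodes) + 1L, ] <-
    list(suid = suid, shared_name = shared_name)
  network
}

#' Add an edge to a network
#'
#' @param network A `cy_network`.
#' @param source_suid,target_suid SUIDs of existing nodes.
#' @param weight Optional numeric weight stored in the edge table
#'   (`NA` for none).
#' @return The network with one more edge.
#' @export
add_edge <- function(network, source_suid, target_suid, weight = NA_real_) {
  if (!all(c(source_suid, target_suid) %in% network$nodes$suid)) {
    stop("edge endpoints must reference existing node SUIDs")
  }
  suid <- fresh_suid(network)
  network$edges[nrow(network$edges) + 1L, ] <-
    list(suid = suid, source_suid = source_suid, target_suid = target_suid)
  network$edge_table[nrow(network$edge_table) + 1L, ] <-
    list(suid = suid, weight = as.numeric(weight))
  network
}

#' @export
print.cy_network <- function(x, ...) {
  cat(sprintf("<cy_network '%s': %d nodes, %d edges, %s>\n",
              x$name, nrow(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

# -- views -------------------------------------------------------------------

new_views <- function() {
  structure(list(nodes = list(), edges = list(), network = list()),
            class = "cy_views")
}

set_override <- function(views, class, suid, key, value) {
  if (class == "network") {
    views$network[[key]] <- value
    return(views)
  }
  slot <- paste0(class, "s")
  id <- as.character(suid)
  if (is.null(views[[slot]][[id]])) views[[slot]][[id]] <- list()
  views[[slot]][[id]][[key]] <- value
  views
}

get_overrides <- function(views, class, suid = NULL) {
  if (class == "network") return(views$network)
  ov <- views[[paste0(class, "s")]][[as.character(suid)]]
  if (is.null(ov)) list() else ov
}

#' Effective visual value for an element
#'
#' Looks up the per-element override if present, falling back to the style
#' default: style defaults plus overrides fully determine every element's
#' effective visual value.
#'
#' @param style A `cy_visual_style`.
#' @param views A views container as produced by [import_document()].
#' @param class `"node"`, `"edge"`, or `"network"`.
#' @param suid Element SUID (ignored for `"network"`).
#' @param key A visual property key.
#' @return The effective value, or `NULL` for a positional key with no
#'   override.
#' @export
effective_value <- function(style, views, class, suid, key) {
  ov <- get_overrides(views, class, suid)
  if (!is.null(ov[[key]])) return(ov[[key]])
  style$defaults[[key]]
}

# value equality used when deciding whether an override deviates from a
# style default
.vp_equal <- function(a, b) {
  if (is_rgba(a) && is_rgba(b)) return(all(unclass(a) == unclass(b)))
  if (is.numeric(a) && is.numeric(b)) return(isTRUE(abs(a - b) < 1e-9))
  identical(a, b)
}

# -- export options ----------------------------------------------------------

#' Export options: the Set Parameters choices
#'
#' The three user choices offered when writing a network to DOT: the edge
#' routing style (which sets the `splines` graph attribute), the node label
#' location (`labelloc` in the node defaults, or `xlabel` per node for
#' `"external"`), and whether/where to write a network label.
#'
#' @param edge_style `"straight"` (`splines = "false"`), `"curved"`
#'   (`splines = "curved"`), or `"routed"` (`splines = "true"`).
#' @param node_label_loc `"center"`, `"top"`, `"bottom"` (label placement via
#'   `labelloc`), or `"external"` (labels written as `xlabel`).
#' @param network_label_loc `"none"`, `"top"`, or `"bottom"`.
#' @return A `cy_export_options` object.
#' @seealso [export_network()], [splines_value()]
#' @export
export_options <- function(edge_style = c("straight", "curved", "routed"),
                           node_label_loc = c("center", "top", "bottom",
                                              "external"),
                           network_label_loc = c("none", "top", "bottom")) {
  structure(list(
    edge_style = match.arg(edge_style),
    node_label_loc = match.arg(node_label_loc),
    network_label_loc = match.arg(network_label_loc)
  ), class = "cy_export_options")
}
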