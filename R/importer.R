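# DOT -> Cytoscape import: attribute mapping per the node/edge/style tables,
# unit conversion, color parsing, and the ignored-attribute log.

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_cols <- c("element", "attribute", "value", "reason")

.empty_log <- function() {
  stats::setNames(
    data.frame(character(0), character(0), character(0), character(0),
               stringsAsFactors = FALSE),
    .log_cols
  )
}

.log_row <- function(attribute, value, reason) {
  list(attribute = attribute, value = value, reason = reason)
}

.bind_log <- function(rows, element) {
  if (!length(rows)) return(.empty_log())
  out <- data.frame(
    element = element,
    attribute = vapply(rows, `[[`, "", "attribute"),
    value = vapply(rows, `[[`, "", "value"),
    reason = vapply(rows, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )
  out
}

#' Convert inches to points
#'
#' DOT specifies node height and width in inches while Cytoscape stores node
#' sizes in points; both directions of the converter apply the exact factor
#' 1 in = 72 pt.
#'
#' @param x Length in inches, non-negative.
#' @return `x * 72`, in points.
#' @seealso [points_to_inches()]
#' @export
inches_to_points <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("negative lengths are not valid node sizes")
  x * 72
}

#' Convert points to inches
#'
#' @param x Length in points.
#' @return `x / 72`, in inches.
#' @export
points_to_inches <- function(x) {
  stopifnot(is.numeric(x))
  x / 72
}

#' Parse a DOT color value
#'
#' Accepts `#RRGGBB`, `#RRGGBBAA`, and X11 color names (the default Graphviz
#' color scheme, matched case-insensitively). Color lists (`a:b`, used by
#' Graphviz for parallel or segmented edges), HSV triples, and
#' brewer-colorscheme references return `NULL`, which the importer turns
#' into a log entry rather than an error.
#'
#' @param value A DOT color string.
#' @return An [rgba()] quadruple, or `NULL` when the value has no equivalent.
#' @export
parse_color <- function(value) {
  v <- trimws(value)
  if (grepl("^#[0-9A-Fa-f]{6}$", v)) {
    ch <- strtoi(substring(v, c(2L, 4L, 6L), c(3L, 5L, 7L)), 16L)
    return(rgba(ch[1], ch[2], ch[3]))
  }
  if (grepl("^#[0-9A-Fa-f]{8}$", v)) {
    ch <- strtoi(substring(v, c(2L, 4L, 6L, 8L), c(3L, 5L, 7L, 9L)), 16L)
    return(rgba(ch[1], ch[2], ch[3], ch[4]))
  }
  if (grepl(":", v, fixed = TRUE)) return(NULL)    # color list
  if (grepl("^/", v)) return(NULL)                 # colorscheme reference
  if (grepl("^[0-9.]+[, ]+[0-9.]+[, ]+[0-9.]+$", v)) return(NULL)  # HSV
  key <- tolower(v)
  if (key %in% grDevices::colors()) {
    m <- grDevices::col2rgb(key)
    return(rgba(m[1L], m[2L], m[3L]))
  }
  NULL
}

#' Map a DOT node shape name to the model vocabulary
#'
#' Supported shapes: triangle, diamond, ellipse, hexagon, octagon,
#' parallelogram, rectangle (also spelled `rect` and `box`), square, and
#' circle. `Msquare`, `Mcircle`, and `Mdiamond` render the same as square,
#' circle, and diamond.
#'
#' @param value A DOT `shape` attribute value.
#' @return The model shape name, or `NULL` for unsupported shapes.
#' @export
map_node_shape <- function(value) {
  switch(value,
    triangle = "triangle", diamond = "diamond", ellipse = "ellipse",
    circle = "circle", hexagon = "hexagon", octagon = "octagon",
    parallelogram = "parallelogram", rectangle = "rectangle",
    rect = "rectangle", box = "rectangle", square = "square",
    Msquare = "square", Mcircle = "circle", Mdiamond = "diamond",
    NULL
  )
}

#' Map a DOT arrow shape name to the model vocabulary
#'
#' Supported arrows: vee, lvee, rvee, dot, normal, diamond, none, and tee.
#' The open variants `odot`, `onormal`, and `odiamond` render the same as
#' dot, normal, and diamond.
#'
#' @param value A DOT `arrowhead`/`arrowtail` value.
#' @return The model arrow name, or `NULL` for unsupported arrows.
#' @export
map_arrow_shape <- function(value) {
  switch(value,
    vee = "vee", lvee = "lvee", rvee = "rvee", dot = "dot",
    normal = "normal", diamond = "diamond", none = "none", tee = "tee",
    odot = "dot", onormal = "normal", odiamond = "diamond",
    NULL
  )
}

#' Parse a DOT node position
#'
#' A node `pos` is a coordinate pair `"x,y"` in points (an optional trailing
#' `!` pin flag is discarded). Positions pass through without unit
#' conversion, but the y value is negated: DOT's y axis points up while the
#' stored coordinates follow Cytoscape's downward y axis. The flip is its
#' own inverse, so export restores the original string.
#'
#' @param value A DOT `pos` attribute value.
#' @return A named numeric vector `c(x =, y =)`, or `NULL` if malformed.
#' @export
parse_pos <- function(value) {
  v <- sub("!$", "", trimws(value))
  parts <- strsplit(v, ",", fixed = TRUE)[[1]]
  if (length(parts) != 2L) return(NULL)
  xy <- suppressWarnings(as.numeric(trimws(parts)))
  if (anyNA(xy)) return(NULL)
  c(x = xy[1L], y = -xy[2L])
}

.num_or_null <- function(value) {
  x <- suppressWarnings(as.numeric(value))
  if (is.na(x)) NULL else x
}

#' Apply DOT style keywords
#'
#' Interprets the comma-separated `style` attribute: `solid`/`dashed`/
#' `dotted` set the border or edge line type, `invis` hides the element,
#' `filled` makes a node opaque (transparency 255), and `rounded` turns the
#' shape into a round-rectangle — but only when the `shape` attribute is in
#' the rectangle family, per the mapping-table footnote. Unsupported
#' keywords (`bold`, `tapered`, `diagonals`, `striped`, `wedged`, ...) are
#' skipped with a log entry. Duplicate keywords: last wins.
#'
#' @param style_value The `style` attribute value.
#' @param element_kind `"node"` or `"edge"`.
#' @param shape_attr The element's raw `shape` attribute, or `NULL`.
#' @return `list(overrides =, log =)`; `log` is a list of skipped-keyword
#'   records.
#' @export
apply_style_keywords <- function(style_value, element_kind = c("node", "edge"),
                                 shape_attr = NULL) {
  element_kind <- match.arg(element_kind)
  keywords <- trimws(strsplit(style_value, ",", fixed = TRUE)[[1]])
  keywords <- keywords[nzchar(keywords)]
  overrides <- list()
  log <- list()
  line_key <- if (element_kind == "node") "NODE_BORDER_LINE_TYPE" else
    "EDGE_LINE_TYPE"
  rect_family <- c("rectangle", "rect", "box")
  for (kw in keywords) {
    if (kw %in% .line_types) {
      overrides[[line_key]] <- kw
    } else if (kw == "invis") {
      overrides[[paste0(toupper(element_kind), "_VISIBLE")]] <- FALSE
    } else if (kw == "rounded" && element_kind == "node") {
      if (!is.null(shape_attr) && shape_attr %in% rect_family) {
        overrides[["NODE_SHAPE"]] <- "round-rectangle"
      } else {
        log[[length(log) + 1L]] <- .log_row(
          "style", kw, "'rounded' only affects rectangle-shaped nodes")
      }
    } else if (kw == "filled" && element_kind == "node") {
      overrides[["NODE_TRANSPARENCY"]] <- 255
    } else {
      log[[length(log) + 1L]] <- .log_row(
        "style", kw, "unsupported style keyword")
    }
  }
  list(overrides = overrides, log = log)
}

#' Map resolved DOT node attributes onto visual-property overrides
#'
#' Applies the node mapping table: `label`/`xlabel` to the node label (a
#' `\N` value resolves to the node's name), `color` to the border paint,
#' `fillcolor` to the fill, `penwidth` to the border width (points, 1:1),
#' `width`/`height` to the node size (inches converted to points),
#' `shape`, the font attributes, `style` (see [apply_style_keywords()]),
#' `pos` (see [parse_pos()]), and `tooltip`. Anything unconvertible —
#' unknown attributes, unsupported shapes, unparseable values — is returned
#' as log records, never an error.
#'
#' @param attrs A resolved attribute map (named character vector).
#' @param name The node's name, used to resolve `\N` labels; `NULL` leaves
#'   `\N` literal (as when mapping a default statement into style defaults).
#' @return `list(overrides =, log =)`.
#' @export
map_node_attrs <- function(attrs, name = NULL) {
  overrides <- list()
  log <- list()
  note <- function(a, v, r) log[[length(log) + 1L]] <<- .log_row(a, v, r)
  shape_attr <- if ("shape" %in% names(attrs)) attrs[["shape"]] else NULL
  set_color <- function(key, nm, v) {
    col <- parse_color(v)
    if (is.null(col)) note(nm, v, "no equivalent color value")
    else overrides[[key]] <<- col
  }
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    if (nm %in% c("label", "xlabel")) {
      overrides[["NODE_LABEL"]] <-
        if (identical(v, "\\N") && !is.null(name)) name else v
    } else if (nm == "color") {
      set_color("NODE_BORDER_PAINT", nm, v)
    } else if (nm == "fillcolor") {
      set_color("NODE_FILL_COLOR", nm, v)
    } else if (nm == "fontcolor") {
      set_color("NODE_LABEL_FONT_COLOR", nm, v)
    } else if (nm == "penwidth") {
      x <- .num_or_null(v)
      if (is.null(x)) note(nm, v, "not a number") else
        overrides[["NODE_BORDER_WIDTH"]] <- x
    } else if (nm %in% c("width", "height")) {
      x <- .num_or_null(v)
      if (is.null(x) || x < 0) note(nm, v, "not a non-negative length") else
        overrides[[if (nm == "width") "NODE_WIDTH" else "NODE_HEIGHT"]] <-
          inches_to_points(x)
    } else if (nm == "shape") {
      shp <- map_node_shape(v)
      if (is.null(shp)) note(nm, v, "unsupported node shape") else
        overrides[["NODE_SHAPE"]] <- shp
    } else if (nm == "fontname") {
      overrides[["NODE_LABEL_FONT_FACE"]] <- v
    } else if (nm == "fontsize") {
      x <- .num_or_null(v)
      if (is.null(x)) note(nm, v, "not a number") else
        overrides[["NODE_LABEL_FONT_SIZE"]] <- x
    } else if (nm == "style") {
      st <- apply_style_keywords(v, "node", shape_attr)
      overrides[names(st$overrides)] <- st$overrides
      log <- c(log, st$log)
    } else if (nm == "pos") {
      xy <- parse_pos(v)
      if (is.null(xy)) note(nm, v, "malformed position") else {
        overrides[["NODE_X_POSITION"]] <- unname(xy["x"])
        overrides[["NODE_Y_POSITION"]] <- unname(xy["y"])
      }
    } else if (nm == "tooltip") {
      overrides[["NODE_TOOLTIP"]] <- v
    } else {
      note(nm, v, "no corresponding Cytoscape visual property")
    }
  }
  list(overrides = overrides, log = log)
}

#' Map resolved DOT edge attributes onto visual-property overrides
#'
#' Applies the edge mapping table: `label`/`xlabel`, `color` to the
#' unselected paint, `penwidth` to the edge width, the font attributes,
#' `style`, `arrowhead`/`arrowtail` to target/source arrow shapes, and
#' `tooltip`. The `weight` attribute has no visual property: its parsed
#' value is returned separately for the network's edge table. An edge `pos`
#' (a spline) is ignored with a log entry — edges render as straight lines.
#'
#' @param attrs A resolved attribute map.
#' @return `list(overrides =, weight =, log =)`; `weight` is `NA` when the
#'   attribute is absent or unparseable.
#' @export
map_edge_attrs <- function(attrs) {
  overrides <- list()
  log <- list()
  weight <- NA_real_
  note <- function(a, v, r) log[[length(log) + 1L]] <<- .log_row(a, v, r)
  set_color <- function(key, nm, v) {
    col <- parse_color(v)
    if (is.null(col)) note(nm, v, "no equivalent color value")
    else overrides[[key]] <<- col
  }
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    if (nm %in% c("label", "xlabel")) {
      overrides[["EDGE_LABEL"]] <- v
    } else if (nm == "weight") {
      x <- .num_or_null(v)
      if (is.null(x)) note(nm, v, "not a number") else weight <- x
    } else if (nm == "color") {
      set_color("EDGE_UNSELECTED_PAINT", nm, v)
    } else if (nm == "fontcolor") {
      set_color("EDGE_LABEL_FONT_COLOR", nm, v)
    } else if (nm == "penwidth") {
      x <- .num_or_null(v)
      if (is.null(x)) note(nm, v, "not a number") else
        overrides[["EDGE_WIDTH"]] <- x
    } else if (nm == "fontname") {
      overrides[["EDGE_LABEL_FONT_FACE"]] <- v
    } else if (nm == "fontsize") {
      x <- .num_or_null(v)
      if (is.null(x)) note(nm, v, "not a number") else
        overrides[["EDGE_LABEL_FONT_SIZE"]] <- x
    } else if (nm == "style") {
      st <- apply_style_keywords(v, "edge")
      overrides[names(st$overrides)] <- st$overrides
      log <- c(log, st$log)
    } else if (nm == "arrowhead") {
      arr <- map_arrow_shape(v)
      if (is.null(arr)) note(nm, v, "unsupported arrow shape") else
        overrides[["EDGE_TARGET_ARROW_SHAPE"]] <- arr
    } else if (nm == "arrowtail") {
      arr <- map_arrow_shape(v)
      if (is.null(arr)) note(nm, v, "unsupported arrow shape") else
        overrides[["EDGE_SOURCE_ARROW_SHAPE"]] <- arr
    } else if (nm == "tooltip") {
      overrides[["EDGE_TOOLTIP"]] <- v
    } else if (nm == "pos") {
      note(nm, v, "pos is ignored on edges; edges render as straight lines")
    } else {
      note(nm, v, "no corresponding Cytoscape visual property")
    }
  }
  list(overrides = overrides, weight = weight, log = log)
}

# graph-level attributes recognized on import; everything else is logged
.map_graph_attr <- function(state, nm, v) {
  if (nm == "bgcolor") {
    col <- parse_color(v)
    if (is.null(col)) {
      state$log <- c(state$log, list(.log_row(nm, v, "no equivalent color value")))
    } else {
      state$style$defaults$NETWORK_BACKGROUND_PAINT <- col
    }
  } else if (nm == "label") {
    state$style$defaults$NETWORK_TITLE <- v
  } else if (nm == "labelloc") {
    state$label_loc <- switch(v, t = "top", b = "bottom", "none")
  } else {
    state$log <- c(state$log,
                   list(.log_row(nm, v, "no corresponding Cytoscape visual property")))
  }
  state
}

#' Import a parsed DOT document into Cytoscape-side models
#'
#' Produces one result per top-level graph. The visual style starts from
#' `seed_style`, root-graph default statements (and top-level graph
#' attributes such as `bgcolor` and `label`) then override the style
#' defaults, and each element's resolved attributes become per-element view
#' overrides wherever they deviate from the style. Unmapped or unsupported
#' attributes are appended to the ignored-attribute log; import never fails
#' on a parseable document.
#'
#' @param doc A `dot_document`.
#' @param seed_style Style supplying defaults for properties the file does
#'   not set. The default, [cytoscape_default_style()], mirrors a stock
#'   Cytoscape session; pass [dot_implicit_style()] for Graphviz-faithful
#'   defaults instead. For directed graphs the seed's target-arrow default
#'   is promoted to `normal`, DOT's implicit arrowhead for digraphs.
#' @return A list of `cy_import` objects, each with fields `network`,
#'   `style`, `views`, `log` (a data frame with columns element, attribute,
#'   value, reason) and `label_loc`.
#' @export
import_document <- function(doc, seed_style = cytoscape_default_style()) {
  stopifnot(inherits(doc, "dot_document"))
  lapply(doc$graphs, .import_graph, seed_style = seed_style)
}

.import_graph <- function(g, seed_style) {
  style <- seed_style
  style$defaults$NETWORK_TITLE <- g$name
  if (g$directed) style$defaults$EDGE_TARGET_ARROW_SHAPE <- "normal"
  state <- list(style = style, label_loc = "none", log = list())
  log_df <- .empty_log()
  push_log <- function(rows, element) {
    if (length(rows)) log_df <<- rbind(log_df, .bind_log(rows, element))
  }

  defaults <- list(node = .empty_attrs(), edge = .empty_attrs())
  node_order <- character(0)
  node_eff <- list()
  edge_list <- list()
  nkey <- function(id) paste0("id:", id)  # "" is a legal node id

  walk <- function(stmts, depth) {
    for (s in stmts) {
      if (s$type == "default" && depth == 0L) {
        if (s$target == "node") {
          defaults$node <<- .merge_attrs(defaults$node, s$attrs)
          m <- map_node_attrs(s$attrs, name = NULL)
          for (k in setdiff(names(m$overrides),
                            c("NODE_X_POSITION", "NODE_Y_POSITION"))) {
            state$style$defaults[[k]] <<- m$overrides[[k]]
          }
          push_log(m$log, "node defaults")
        } else if (s$target == "edge") {
          defaults$edge <<- .merge_attrs(defaults$edge, s$attrs)
          m <- map_edge_attrs(s$attrs)
          for (k in names(m$overrides)) {
            state$style$defaults[[k]] <<- m$overrides[[k]]
          }
          push_log(m$log, "edge defaults")
        } else {
          for (nm in names(s$attrs)) {
            state <<- .map_graph_attr(state, nm, s$attrs[[nm]])
          }
          push_log(state$log, "graph")
          state$log <<- list()
        }
      } else if (s$type == "graphattr" && depth == 0L) {
        for (nm in names(s$attrs)) {
          state <<- .map_graph_attr(state, nm, s$attrs[[nm]])
        }
        push_log(state$log, "graph")
        state$log <<- list()
      } else if (s$type == "node") {
        eff <- .merge_attrs(defaults$node, s$attrs)
        prev <- node_eff[[nkey(s$id)]]
        if (is.null(prev)) {
          node_order <<- c(node_order, s$id)
          prev <- .empty_attrs()
        }
        node_eff[[nkey(s$id)]] <<- .merge_attrs(prev, eff)
      } else if (s$type == "edge") {
        edge_list[[length(edge_list) + 1L]] <<- list(
          source = s$source, target = s$target,
          attrs = .merge_attrs(defaults$edge, s$attrs)
        )
      } else if (s$type == "subgraph") {
        walk(s$statements, depth + 1L)
      }
    }
  }
  walk(g$statements, 0L)

  network <- cy_network(name = g$name, directed = g$directed)
  for (id in node_order) network <- add_node(network, id)
  suid_of <- function(id) {
    network$nodes$suid[match(id, network$nodes$shared_name)]
  }

  views <- new_views()
  style_now <- state$style
  for (id in node_order) {
    m <- map_node_attrs(node_eff[[nkey(id)]], name = id)
    suid <- suid_of(id)
    for (k in names(m$overrides)) {
      v <- m$overrides[[k]]
      if (!.vp_equal(v, style_now$defaults[[k]])) {
        views <- set_override(views, "node", suid, k, v)
      }
    }
    push_log(m$log, id)
  }
  for (e in edge_list) {
    m <- map_edge_attrs(e$attrs)
    network <- add_edge(network, suid_of(e$source), suid_of(e$target),
                        weight = m$weight)
    suid <- network$edges$suid[nrow(network$edges)]
    for (k in names(m$overrides)) {
      v <- m$overrides[[k]]
      if (!.vp_equal(v, style_now$defaults[[k]])) {
        views <- set_override(views, "edge", suid, k, v)
      }
    }
    push_log(m$log, paste(e$source, if (g$directed) "->" else "--", e$target))
  }

  structure(list(network = network, style = style_now, views = views,
                 log = log_df, label_loc = state$label_loc),
            class = "cy_import")
}

#' Import a DOT file
#'
#' Convenience wrapper: [read_dot()] then [import_document()].
#'
#' @inheritParams import_document
#' @param path Path to a `.dot` or `.gv` file.
#' @return A list of `cy_import` objects, one per graph in the file.
#' @export
import_dot <- function(path, seed_style = cytoscape_default_style()) {
  import_document(read_dot(path), seed_style = seed_style)
}

#' @export
print.cy_import <- function(x, ...) {
  cat(sprintf("<cy_import '%s': %d nodes, %d edges, %d ignored attribute(s)>\n",
              x$network$name, nrow(x$network$nodes), nrow(x$network$edges),
              nrow(x$log)))
  invisible(x)
}
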