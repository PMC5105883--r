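# Cytoscape -> DOT export: header block, default statements, per-element
# deviations, name-SUID ids and 6-decimal formatting.

# the edge default statement always advertises the stock stroke color; edges
# whose effective paint differs (including the stock unselected paint) are
# written with their own color attribute
.EDGE_DEFAULT_COLOR <- "#848484FF"

#' Format a real for DOT output
#'
#' Sizes, widths and coordinates are rendered with exactly six decimal
#' places, the convention of the exported listings.
#'
#' @param x A numeric vector.
#' @return Character, e.g. `35` points becomes `"0.486111"` inches after
#'   [points_to_inches()].
#' @export
format_real <- function(x) sprintf("%.6f", x)

#' Format a color as hex-with-alpha
#'
#' @param c An [rgba()] quadruple.
#' @return `"#RRGGBBAA"`, uppercase.
#' @export
format_color <- function(c) {
  stopifnot(is_rgba(c))
  v <- unclass(c)
  sprintf("#%02X%02X%02X%02X", v[["r"]], v[["g"]], v[["b"]], v[["a"]])
}

# font sizes print as the shortest exact decimal ("12", not "12.000000")
.format_fontsize <- function(x) {
  if (abs(x - round(x)) < 1e-9) return(sprintf("%d", as.integer(round(x))))
  sub("\\.?0+$", "", sprintf("%.6f", x))
}

#' Compose the exported node id
#'
#' Exported node ids append the element SUID to the node name, separated by
#' a section sign, e.g. `"Node 1§64"`. Quoting is the serializer's job.
#'
#' @param name Node shared name.
#' @param suid Node SUID.
#' @return The composite id string.
#' @export
make_node_id <- function(name, suid) paste0(name, "\u00a7", suid)

#' Value of the splines graph attribute for each edge style
#'
#' `"straight"` writes `splines = "false"`, `"curved"` writes
#' `splines = "curved"`, and `"routed"` (curved segments routed around
#' nodes) writes `splines = "true"`.
#'
#' @param edge_style One of `"straight"`, `"curved"`, `"routed"`.
#' @return The DOT `splines` value.
#' @export
splines_value <- function(edge_style = c("straight", "curved", "routed")) {
  switch(match.arg(edge_style),
         straight = "false", curved = "curved", routed = "true")
}

#' Compose the DOT style keyword list for a node
#'
#' The node `style` value is determined by several visual properties at
#' once, joined in a fixed order: the border line type, then `rounded` when
#' the shape is a round-rectangle, then `invis` when the node is hidden,
#' then `filled` when the transparency is above zero.
#'
#' @param shape Model shape name.
#' @param border_line_type `"solid"`, `"dashed"`, or `"dotted"`.
#' @param visible Logical.
#' @param transparency Integer 0-255.
#' @return The comma-joined keyword string, e.g. `"solid,rounded,filled"`.
#' @export
compose_node_style <- function(shape, border_line_type, visible,
                               transparency) {
  kw <- border_line_type
  if (identical(shape, "round-rectangle")) kw <- c(kw, "rounded")
  if (!isTRUE(visible)) kw <- c(kw, "invis")
  if (transparency > 0) kw <- c(kw, "filled")
  paste(kw, collapse = ",")
}

.compose_edge_style <- function(line_type, visible) {
  kw <- line_type
  if (!isTRUE(visible)) kw <- c(kw, "invis")
  paste(kw, collapse = ",")
}

#' Node label attribute fragments for a label-location option
#'
#' For `"center"`, `"top"`, and `"bottom"` the label is written as the
#' `label` attribute and the location as `labelloc` (`"c"`, `"t"`, `"b"`)
#' in the node default list; the `"external"` option writes each node's
#' label as `xlabel` instead, so Graphviz places it beside the node.
#'
#' @param label The label text.
#' @param loc One of `"center"`, `"top"`, `"bottom"`, `"external"`.
#' @return `list(attr =, value =, labelloc =)`; `labelloc` is `NULL` for
#'   `"external"`.
#' @export
node_label_attrs <- function(label, loc = c("center", "top", "bottom",
                                            "external")) {
  loc <- match.arg(loc)
  if (loc == "external") {
    list(attr = "xlabel", value = label, labelloc = NULL)
  } else {
    list(attr = "label", value = label,
         labelloc = c(center = "c", top = "t", bottom = "b")[[loc]])
  }
}

.esc_value <- function(v) gsub("\"", "\\\\\"", v)

.pair <- function(name, value) paste0(name, " = \"", .esc_value(value), "\"")

.dot_shape_name <- function(shape) {
  if (identical(shape, "round-rectangle")) "rectangle" else shape
}

#' Export a network to DOT text
#'
#' Serializes a network, its visual style and its per-element views into a
#' DOT file following the converter's output conventions: a fixed header
#' block (`bgcolor`, `splines`, `outputorder = "edgesfirst"`, `esep = "0"`,
#' `pad = "2"`, optionally the network label), one `node [...]` and one
#' `edge [...]` default statement built from the style defaults
#' (`fixedsize = "true"` is always written so Graphviz honors the exported
#' sizes), then node and edge statements carrying only the attributes whose
#' effective value deviates from those defaults. Node ids are
#' [make_node_id()] composites; elements are written newest-first.
#' Undirected networks use the `--` operator with `arrowhead`/`arrowtail`
#' `"none"` and `dir = "both"` in the edge defaults; directed networks use
#' `->`.
#'
#' @param network A `cy_network`.
#' @param style A `cy_visual_style`.
#' @param views A views container (as from [import_document()]).
#' @param options An [export_options()] object.
#' @return A `dot_output`: `$text` (which reparses under [parse_dot()]) and
#'   `$warnings`, notices about information DOT cannot represent.
#' @export
export_network <- function(network, style, views = new_views(),
                           options = export_options()) {
  stopifnot(inherits(network, "cy_network"),
            inherits(style, "cy_visual_style"),
            inherits(options, "cy_export_options"))
  d <- style$defaults
  warnings <- character(0)
  external <- options$node_label_loc == "external"
  lab <- node_label_attrs("", options$node_label_loc)

  header <- paste0(
    if (network$directed) "digraph" else "graph",
    if (nzchar(network$name)) paste0(" ", .quote_id(network$name)) else "",
    " {")

  bg <- effective_value(style, views, "network", NULL,
                        "NETWORK_BACKGROUND_PAINT")
  lines <- c(
    header,
    .pair("bgcolor", format_color(bg)),
    .pair("splines", splines_value(options$edge_style)),
    .pair("outputorder", "edgesfirst"),
    .pair("esep", "0"),
    .pair("pad", "2")
  )
  if (options$network_label_loc != "none") {
    title <- effective_value(style, views, "network", NULL, "NETWORK_TITLE")
    if (!nzchar(title)) title <- network$name
    lines <- c(lines,
               .pair("label", title),
               .pair("labelloc",
                     if (options$network_label_loc == "top") "t" else "b"))
  }

  # declared defaults; per-element emission diffs against these values
  decl_label <- if (external) "" else d$NODE_LABEL
  node_decl <- c(
    .pair("label", decl_label),
    .pair("penwidth", format_real(d$NODE_BORDER_WIDTH)),
    .pair("height", format_real(points_to_inches(d$NODE_HEIGHT))),
    .pair("width", format_real(points_to_inches(d$NODE_WIDTH))),
    .pair("tooltip", d$NODE_TOOLTIP),
    .pair("color", format_color(d$NODE_BORDER_PAINT)),
    .pair("fillcolor", format_color(d$NODE_FILL_COLOR)),
    .pair("shape", .dot_shape_name(d$NODE_SHAPE)),
    .pair("style", compose_node_style(d$NODE_SHAPE, d$NODE_BORDER_LINE_TYPE,
                                      d$NODE_VISIBLE, d$NODE_TRANSPARENCY)),
    .pair("fontname", d$NODE_LABEL_FONT_FACE),
    .pair("fontsize", .format_fontsize(d$NODE_LABEL_FONT_SIZE)),
    .pair("fontcolor", format_color(d$NODE_LABEL_FONT_COLOR)),
    .pair("fixedsize", "true"),
    if (!external) .pair("labelloc", lab$labelloc)
  )
  arrow_head <- if (network$directed) d$EDGE_TARGET_ARROW_SHAPE else "none"
  arrow_tail <- if (network$directed) d$EDGE_SOURCE_ARROW_SHAPE else "none"
  edge_decl <- c(
    .pair("label", d$EDGE_LABEL),
    .pair("penwidth", format_real(d$EDGE_WIDTH)),
    .pair("tooltip", d$EDGE_TOOLTIP),
    .pair("arrowhead", arrow_head),
    .pair("arrowtail", arrow_tail),
    .pair("color", .EDGE_DEFAULT_COLOR),
    .pair("fontname", d$EDGE_LABEL_FONT_FACE),
    .pair("fontsize", .format_fontsize(d$EDGE_LABEL_FONT_SIZE)),
    .pair("fontcolor", format_color(d$EDGE_LABEL_FONT_COLOR)),
    .pair("style", .compose_edge_style(d$EDGE_LINE_TYPE, d$EDGE_VISIBLE)),
    if (!network$directed) .pair("dir", "both")
  )
  lines <- c(lines,
             paste0("node [", paste(node_decl, collapse = ","), "]"),
             paste0("edge [", paste(edge_decl, collapse = ","), "]"))

  node_style_decl <- compose_node_style(d$NODE_SHAPE, d$NODE_BORDER_LINE_TYPE,
                                        d$NODE_VISIBLE, d$NODE_TRANSPARENCY)
  edge_style_decl <- .compose_edge_style(d$EDGE_LINE_TYPE, d$EDGE_VISIBLE)
  edge_decl_color <- parse_color(.EDGE_DEFAULT_COLOR)

  eff <- function(class, suid, key) effective_value(style, views, class, suid,
                                                    key)
  emit_if <- function(parts, cond, name, value) {
    if (cond) c(parts, .pair(name, value)) else parts
  }

  # newest-first element order
  for (i in rev(seq_len(nrow(network$nodes)))) {
    suid <- network$nodes$suid[i]
    nm <- network$nodes$shared_name[i]
    ov <- get_overrides(views, "node", suid)
    parts <- character(0)
    label <- eff("node", suid, "NODE_LABEL")
    if (identical(label, "\\N")) label <- nm
    if (external) {
      parts <- emit_if(parts, nzchar(label), "xlabel", label)
    } else {
      parts <- emit_if(parts, !.vp_equal(label, decl_label), "label", label)
    }
    bw <- eff("node", suid, "NODE_BORDER_WIDTH")
    parts <- emit_if(parts, !.vp_equal(bw, d$NODE_BORDER_WIDTH),
                     "penwidth", format_real(bw))
    ht <- eff("node", suid, "NODE_HEIGHT")
    parts <- emit_if(parts, !.vp_equal(ht, d$NODE_HEIGHT),
                     "height", format_real(points_to_inches(ht)))
    wd <- eff("node", suid, "NODE_WIDTH")
    parts <- emit_if(parts, !.vp_equal(wd, d$NODE_WIDTH),
                     "width", format_real(points_to_inches(wd)))
    if (!is.null(ov$NODE_X_POSITION) || !is.null(ov$NODE_Y_POSITION)) {
      x <- ov$NODE_X_POSITION %||% 0
      y <- ov$NODE_Y_POSITION %||% 0
      parts <- c(parts, .pair("pos", paste0(format_real(x), ",",
                                            format_real(-y))))
    }
    bp <- eff("node", suid, "NODE_BORDER_PAINT")
    parts <- emit_if(parts, !.vp_equal(bp, d$NODE_BORDER_PAINT),
                     "color", format_color(bp))
    fc <- eff("node", suid, "NODE_FILL_COLOR")
    parts <- emit_if(parts, !.vp_equal(fc, d$NODE_FILL_COLOR),
                     "fillcolor", format_color(fc))
    shp <- eff("node", suid, "NODE_SHAPE")
    parts <- emit_if(parts,
                     !identical(.dot_shape_name(shp),
                                .dot_shape_name(d$NODE_SHAPE)),
                     "shape", .dot_shape_name(shp))
    st <- compose_node_style(shp, eff("node", suid, "NODE_BORDER_LINE_TYPE"),
                             eff("node", suid, "NODE_VISIBLE"),
                             eff("node", suid, "NODE_TRANSPARENCY"))
    parts <- emit_if(parts, !identical(st, node_style_decl), "style", st)
    fn <- eff("node", suid, "NODE_LABEL_FONT_FACE")
    parts <- emit_if(parts, !identical(fn, d$NODE_LABEL_FONT_FACE),
                     "fontname", fn)
    fs <- eff("node", suid, "NODE_LABEL_FONT_SIZE")
    parts <- emit_if(parts, !.vp_equal(fs, d$NODE_LABEL_FONT_SIZE),
                     "fontsize", .format_fontsize(fs))
    fcl <- eff("node", suid, "NODE_LABEL_FONT_COLOR")
    parts <- emit_if(parts, !.vp_equal(fcl, d$NODE_LABEL_FONT_COLOR),
                     "fontcolor", format_color(fcl))
    tt <- eff("node", suid, "NODE_TOOLTIP")
    parts <- emit_if(parts, !identical(tt, d$NODE_TOOLTIP), "tooltip", tt)
    lines <- c(lines, paste0(
      .quote_id(make_node_id(nm, suid)),
      if (length(parts)) paste0(" [", paste(parts, collapse = ","), "]")
      else ""))
  }

  name_of <- stats::setNames(network$nodes$shared_name,
                             as.character(network$nodes$suid))
  op <- if (network$directed) " -> " else " -- "
  for (i in rev(seq_len(nrow(network$edges)))) {
    suid <- network$edges$suid[i]
    src <- network$edges$source_suid[i]
    tgt <- network$edges$target_suid[i]
    parts <- character(0)
    lb <- eff("edge", suid, "EDGE_LABEL")
    parts <- emit_if(parts, !identical(lb, d$EDGE_LABEL), "label", lb)
    pw <- eff("edge", suid, "EDGE_WIDTH")
    parts <- emit_if(parts, !.vp_equal(pw, d$EDGE_WIDTH),
                     "penwidth", format_real(pw))
    cl <- eff("edge", suid, "EDGE_UNSELECTED_PAINT")
    parts <- emit_if(parts, !.vp_equal(cl, edge_decl_color),
                     "color", format_color(cl))
    fn <- eff("edge", suid, "EDGE_LABEL_FONT_FACE")
    parts <- emit_if(parts, !identical(fn, d$EDGE_LABEL_FONT_FACE),
                     "fontname", fn)
    fs <- eff("edge", suid, "EDGE_LABEL_FONT_SIZE")
    parts <- emit_if(parts, !.vp_equal(fs, d$EDGE_LABEL_FONT_SIZE),
                     "fontsize", .format_fontsize(fs))
    fcl <- eff("edge", suid, "EDGE_LABEL_FONT_COLOR")
    parts <- emit_if(parts, !.vp_equal(fcl, d$EDGE_LABEL_FONT_COLOR),
                     "fontcolor", format_color(fcl))
    st <- .compose_edge_style(eff("edge", suid, "EDGE_LINE_TYPE"),
                              eff("edge", suid, "EDGE_VISIBLE"))
    parts <- emit_if(parts, !identical(st, edge_style_decl), "style", st)
    ah <- eff("edge", suid, "EDGE_TARGET_ARROW_SHAPE")
    parts <- emit_if(parts, !identical(ah, arrow_head), "arrowhead", ah)
    at <- eff("edge", suid, "EDGE_SOURCE_ARROW_SHAPE")
    parts <- emit_if(parts, !identical(at, arrow_tail), "arrowtail", at)
    tt <- eff("edge", suid, "EDGE_TOOLTIP")
    parts <- emit_if(parts, !identical(tt, d$EDGE_TOOLTIP), "tooltip", tt)
    lines <- c(lines, paste0(
      .quote_id(make_node_id(name_of[[as.character(src)]], src)), op,
      .quote_id(make_node_id(name_of[[as.character(tgt)]], tgt)),
      if (length(parts)) paste0(" [", paste(parts, collapse = ","), "]")
      else ""))
  }
  lines <- c(lines, "}")

  if (any(!is.na(network$edge_table$weight))) {
    warnings <- c(warnings,
                  "edge table data (including the weight column) is not written to DOT")
  }
  structure(list(text = paste0(paste(lines, collapse = "\n"), "\n"),
                 warnings = warnings),
            class = "dot_output")
}

#' Export a network to a DOT file
#'
#' @inheritParams export_network
#' @param path Output path (`.dot` or `.gv`).
#' @return Invisibly, the `dot_output` (text and warnings).
#' @export
export_dot <- function(network, style, views = new_views(),
                       path, options = export_options()) {
  out <- export_network(network, style, views, options)
  writeLines(out$text, path, sep = "")
  invisible(out)
}

#' @export
print.dot_output <- function(x, ...) {
  cat(x$text)
  if (length(x$warnings)) {
    cat("## warnings:\n")
    for (w in x$warnings) cat("## -", w, "\n")
  }
  invisible(x)
}
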