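# Cytoscape.js JSON (.cyjs) network I/O and the JSON visual-style sidecar.
#
# .cyjs carries topology and node positions; it has no style section, so the
# visual style travels in a sidecar document {"defaults": {...}} and
# per-element visual overrides are embedded in each element's "view" object.

.vp_to_json <- function(key, value) {
  if (key %in% .vp_color_keys) format_color(value) else value
}

.vp_from_json <- function(key, raw, path) {
  fail <- function(why) {
    stop(sprintf("invalid value at %s: %s", path, why), call. = FALSE)
  }
  if (key %in% .vp_color_keys) {
    if (!is.character(raw) || length(raw) != 1L) fail("expected a hex color string")
    col <- parse_color(raw)
    if (is.null(col) || !grepl("^#", raw)) fail("expected a hex color string")
    return(col)
  }
  if (key %in% .vp_numeric_keys) {
    x <- suppressWarnings(as.numeric(raw))
    if (length(x) != 1L || is.na(x)) fail("expected a number")
    return(x)
  }
  if (key %in% .vp_logical_keys) {
    if (!is.logical(raw) || length(raw) != 1L) fail("expected a boolean")
    return(raw)
  }
  if (!is.character(raw) && !is.numeric(raw)) fail("expected a string")
  value <- as.character(raw)
  .check_style_value(key, value)
  value
}

.view_to_json <- function(ov) {
  out <- list()
  for (k in names(ov)) {
    if (k %in% c("NODE_X_POSITION", "NODE_Y_POSITION")) next
    out[[k]] <- .vp_to_json(k, ov[[k]])
  }
  out
}

#' Write a network to Cytoscape.js JSON
#'
#' Positions are stored in the standard `position` object (points, y axis
#' downward); every other per-element visual override is embedded in a
#' `view` object on the element so that [read_cyjs()] restores the model
#' exactly. Colors are written as `#RRGGBBAA` hex strings.
#'
#' @param network A `cy_network`.
#' @param views A views container.
#' @param path Output path (`.cyjs`).
#' @export
write_cyjs <- function(network, views, path) {
  nodes <- lapply(seq_len(nrow(network$nodes)), function(i) {
    suid <- network$nodes$suid[i]
    nm <- network$nodes$shared_name[i]
    ov <- get_overrides(views, "node", suid)
    el <- list(data = list(id = as.character(suid), SUID = suid,
                           name = nm, shared_name = nm))
    if (!is.null(ov$NODE_X_POSITION) || !is.null(ov$NODE_Y_POSITION)) {
      el$position <- list(x = ov$NODE_X_POSITION %||% 0,
                          y = ov$NODE_Y_POSITION %||% 0)
    }
    view <- .view_to_json(ov)
    if (length(view)) el$view <- view
    el
  })
  edges <- lapply(seq_len(nrow(network$edges)), function(i) {
    suid <- network$edges$suid[i]
    w <- network$edge_table$weight[match(suid, network$edge_table$suid)]
    data <- list(id = as.character(suid), SUID = suid,
                 source = as.character(network$edges$source_suid[i]),
                 target = as.character(network$edges$target_suid[i]))
    if (!is.na(w)) data$weight <- w
    el <- list(data = data)
    view <- .view_to_json(get_overrides(views, "edge", suid))
    if (length(view)) el$view <- view
    el
  })
  obj <- list(
    format_version = "1.0",
    generated_by = "cydot",
    target_cytoscapejs_version = "~2.1",
    data = list(name = network$name, shared_name = network$name,
                directed = network$directed),
    elements = list(nodes = nodes, edges = edges)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

.read_json_file <- function(path) {
  tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("'%s' is not valid JSON: %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
}

.require_field <- function(obj, field, path) {
  if (is.null(obj[[field]])) {
    stop(sprintf("missing required field at %s.%s", path, field),
         call. = FALSE)
  }
  obj[[field]]
}

#' Read a Cytoscape.js JSON network
#'
#' Schema violations are reported with the JSON path of the offending
#' element (e.g. `$.elements.nodes[3].data.id`); a node without a
#' `position` simply yields a view without position overrides.
#'
#' @param path Path to a `.cyjs` file.
#' @return `list(network =, views =)`.
#' @export
read_cyjs <- function(path) {
  obj <- .read_json_file(path)
  elements <- .require_field(obj, "elements", "$")
  network <- cy_network(
    name = as.character(obj$data$name %||% ""),
    directed = isTRUE(obj$data$directed)
  )
  views <- new_views()
  id_suid <- new.env(parent = emptyenv())

  nodes <- elements$nodes %||% list()
  for (i in seq_along(nodes)) {
    jpath <- sprintf("$.elements.nodes[%d]", i)
    data <- .require_field(nodes[[i]], "data", jpath)
    id <- .require_field(data, "id", paste0(jpath, ".data"))
    suid <- suppressWarnings(as.integer(data$SUID %||% data$id))
    if (is.na(suid) || suid < 1L || suid %in% network$nodes$suid) {
      suid <- fresh_suid(network)
    }
    nm <- as.character(data$name %||% data$shared_name %||% id)
    network$nodes[nrow(network$nodes) + 1L, ] <-
      list(suid = suid, shared_name = nm)
    assign(as.character(id), suid, envir = id_suid)
    pos <- nodes[[i]]$position
    if (!is.null(pos)) {
      x <- suppressWarnings(as.numeric(pos$x %||% NA))
      y <- suppressWarnings(as.numeric(pos$y %||% NA))
      if (is.na(x) || is.na(y)) {
        stop(sprintf("invalid value at %s.position", jpath), call. = FALSE)
      }
      views <- set_override(views, "node", suid, "NODE_X_POSITION", x)
      views <- set_override(views, "node", suid, "NODE_Y_POSITION", y)
    }
    for (k in names(nodes[[i]]$view %||% list())) {
      if (!k %in% .node_vp_keys) {
        stop(sprintf("unknown visual property at %s.view.%s", jpath, k),
             call. = FALSE)
      }
      views <- set_override(views, "node", suid, k,
                            .vp_from_json(k, nodes[[i]]$view[[k]],
                                          sprintf("%s.view.%s", jpath, k)))
    }
  }

  edges <- elements$edges %||% list()
  for (i in seq_along(edges)) {
    jpath <- sprintf("$.elements.edges[%d]", i)
    data <- .require_field(edges[[i]], "data", jpath)
    src <- as.character(.require_field(data, "source", paste0(jpath, ".data")))
    tgt <- as.character(.require_field(data, "target", paste0(jpath, ".data")))
    for (endpoint in c(src, tgt)) {
      if (!exists(endpoint, envir = id_suid, inherits = FALSE)) {
        stop(sprintf("unknown node id '%s' at %s.data", endpoint, jpath),
             call. = FALSE)
      }
    }
    w <- suppressWarnings(as.numeric(data$weight %||% NA))
    network <- add_edge(network, get(src, envir = id_suid),
                        get(tgt, envir = id_suid), weight = w)
    suid <- network$edges$suid[nrow(network$edges)]
    for (k in names(edges[[i]]$view %||% list())) {
      if (!k %in% .edge_vp_keys) {
        stop(sprintf("unknown visual property at %s.view.%s", jpath, k),
             call. = FALSE)
      }
      views <- set_override(views, "edge", suid, k,
                            .vp_from_json(k, edges[[i]]$view[[k]],
                                          sprintf("%s.view.%s", jpath, k)))
    }
  }
  list(network = network, views = views)
}

#' Write a visual style to its JSON sidecar
#'
#' @param style A `cy_visual_style`.
#' @param path Output path.
#' @export
write_style <- function(style, path) {
  stopifnot(inherits(style, "cy_visual_style"))
  defaults <- list()
  for (k in names(style$defaults)) {
    defaults[[k]] <- .vp_to_json(k, style$defaults[[k]])
  }
  jsonlite::write_json(list(defaults = defaults), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a visual style from its JSON sidecar
#'
#' Missing keys fall back to the stock Cytoscape defaults; unknown keys are
#' reported with their JSON path.
#'
#' @param path Path to a style JSON document.
#' @return A `cy_visual_style`.
#' @export
read_style <- function(path) {
  obj <- .read_json_file(path)
  defaults <- .require_field(obj, "defaults", "$")
  style <- cytoscape_default_style()
  for (k in names(defaults)) {
    if (!k %in% visual_property_keys()) {
      stop(sprintf("unknown visual property at $.defaults.%s", k),
           call. = FALSE)
    }
    style$defaults[[k]] <- .vp_from_json(k, defaults[[k]],
                                         sprintf("$.defaults.%s", k))
  }
  new_visual_style(style$defaults)
}
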