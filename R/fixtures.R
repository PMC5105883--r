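# Deterministic DOT fixture generator, restricted to the supported
# attribute vocabulary so that importing a fixture never logs an ignored
# attribute.

#' Specify a random DOT fixture
#'
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param n_nodes Number of nodes.
#' @param edge_prob Probability of an edge between each node pair.
#' @param directed Generate a digraph.
#' @param attr_density Probability that any candidate attribute is attached
#'   to an element.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_nodes = 8L, edge_prob = 0.3,
                         directed = FALSE, attr_density = 0.5) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(n_nodes), n_nodes >= 0,
            edge_prob >= 0, edge_prob <= 1,
            attr_density >= 0, attr_density <= 1)
  structure(list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 edge_prob = edge_prob, directed = isTRUE(directed),
                 attr_density = attr_density),
            class = "fixture_spec")
}

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.hex_color <- function(alpha = FALSE) {
  ch <- sample(0:255, if (alpha) 4L else 3L, replace = TRUE)
  paste0("#", paste(sprintf("%02X", ch), collapse = ""))
}

.fixture_named_colors <- c("red", "blue", "navy", "gold", "tomato",
                           "lightgrey", "seagreen", "orchid")

#' Generate a DOT fixture
#'
#' Emits a parseable DOT file that uses only the supported attribute
#' vocabulary (supported shapes and arrow heads, hex and X11 colors, the
#' supported style keywords, node positions, sizes, fonts, labels, weights),
#' so a round trip through the importer produces no ignored-attribute log
#' entries. Output is byte-identical for identical specs; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [fixture_spec()].
#' @return DOT text (single string).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_nodes
    names <- vapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.25) sprintf("node %d", i) else sprintf("n%d", i)
    }, "")
    lines <- sprintf("%s fixture_%d {",
                     if (spec$directed) "digraph" else "graph", spec$seed)
    if (stats::runif(1) < 0.4) {
      lines <- c(lines, sprintf("  bgcolor=%s;", .quote_id(.hex_color(TRUE))))
    }
    if (stats::runif(1) < 0.5) {
      lines <- c(lines, sprintf("  node [fillcolor=%s, style=filled];",
                                .quote_id(.hex_color())))
    }
    if (stats::runif(1) < 0.5) {
      lines <- c(lines, sprintf("  edge [penwidth=%s];",
                                .quote_id(sprintf("%.2f", stats::runif(1, 0.5, 4)))))
    }
    p <- spec$attr_density
    shapes <- c("ellipse", "circle", "triangle", "diamond", "hexagon",
                "octagon", "parallelogram", "rectangle", "rect", "box",
                "square", "Msquare", "Mcircle", "Mdiamond")
    arrows <- c("vee", "lvee", "rvee", "dot", "normal", "diamond", "none",
                "tee", "odot", "onormal", "odiamond")
    for (i in seq_len(n)) {
      attrs <- character(0)
      put <- function(nm, v) attrs <<- c(attrs, paste0(nm, "=", .quote_id(v)))
      shape <- NULL
      if (stats::runif(1) < p) {
        shape <- sample(shapes, 1L)
        put("shape", shape)
      }
      if (stats::runif(1) < p) put("label", sprintf("label %d", i))
      if (stats::runif(1) < p) {
        put("fillcolor", if (stats::runif(1) < 0.5) .hex_color(TRUE) else
          sample(.fixture_named_colors, 1L))
      }
      if (stats::runif(1) < p) put("color", .hex_color())
      if (stats::runif(1) < p) put("penwidth", sprintf("%.2f", stats::runif(1, 0, 5)))
      if (stats::runif(1) < p) put("height", sprintf("%.3f", stats::runif(1, 0.2, 2)))
      if (stats::runif(1) < p) put("width", sprintf("%.3f", stats::runif(1, 0.2, 2)))
      if (stats::runif(1) < p) {
        put("pos", sprintf("%.4f,%.4f", stats::runif(1, -200, 200),
                           stats::runif(1, -200, 200)))
      }
      if (stats::runif(1) < p) put("fontsize", as.character(sample(6:30, 1L)))
      if (stats::runif(1) < p) {
        put("fontname", sample(c("Times-Roman", "Helvetica", "Courier"), 1L))
      }
      if (stats::runif(1) < p) put("fontcolor", .hex_color())
      if (stats::runif(1) < p) put("tooltip", sprintf("tip %d", i))
      if (stats::runif(1) < p) {
        choices <- c("filled", "dashed", "dotted", "solid", "invis",
                     "filled,dashed")
        if (!is.null(shape) && shape %in% c("rectangle", "rect", "box")) {
          choices <- c(choices, "rounded", "rounded,filled")
        }
        put("style", sample(choices, 1L))
      }
      lines <- c(lines, sprintf("  %s%s;", .quote_id(names[i]),
                                if (length(attrs))
                                  paste0(" [", paste(attrs, collapse = ", "), "]")
                                else ""))
    }
    if (n >= 2L) {
      pairs <- utils::combn(n, 2L)
      for (k in seq_len(ncol(pairs))) {
        if (stats::runif(1) >= spec$edge_prob) next
        a <- pairs[1L, k]
        b <- pairs[2L, k]
        attrs <- character(0)
        put <- function(nm, v) attrs <<- c(attrs, paste0(nm, "=", .quote_id(v)))
        if (stats::runif(1) < p) put("color", .hex_color(TRUE))
        if (stats::runif(1) < p) put("penwidth", sprintf("%.2f", stats::runif(1, 0.5, 6)))
        if (stats::runif(1) < p) put("weight", sprintf("%.2f", stats::runif(1, 0, 10)))
        if (stats::runif(1) < p) put("label", sprintf("e%d_%d", a, b))
        if (stats::runif(1) < p) put("fontsize", as.character(sample(6:20, 1L)))
        if (stats::runif(1) < p) put("fontcolor", .hex_color())
        if (stats::runif(1) < p) put("tooltip", sprintf("edge %d-%d", a, b))
        if (stats::runif(1) < p) {
          put("style", sample(c("solid", "dashed", "dotted", "invis"), 1L))
        }
        if (spec$directed) {
          if (stats::runif(1) < p) put("arrowhead", sample(arrows, 1L))
          if (stats::runif(1) < p) put("arrowtail", sample(arrows, 1L))
        }
        lines <- c(lines, sprintf("  %s %s %s%s;",
                                  .quote_id(names[a]),
                                  if (spec$directed) "->" else "--",
                                  .quote_id(names[b]),
                                  if (length(attrs))
                                    paste0(" [", paste(attrs, collapse = ", "), "]")
                                  else ""))
      }
    }
    paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
  })
}
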