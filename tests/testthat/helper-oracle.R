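# Test helpers: an independent line-oriented DOT mini-parser used as an
# oracle against the package serializer (it shares no code with the real
# parser and only understands the serializer's one-statement-per-line
# subset), plus model-equivalence utilities for round-trip checks.

SECT <- "\u00a7"

strip_suid <- function(x) sub(paste0(SECT, "[0-9]+$"), "", x)

wildcard_suids <- function(lines) {
  gsub(paste0(SECT, "[0-9]+"), paste0(SECT, "<SUID>"), lines)
}

# tokenizes one serialized line; understands quoted strings with \" escapes
mini_tokens <- function(line) {
  pat <- "\"(?:[^\"\\\\]|\\\\.)*\"|[\\[\\]=,;]|[^\"\\s\\[\\]=,;]+"
  regmatches(line, gregexpr(pat, line, perl = TRUE))[[1]]
}

mini_unquote <- function(t) {
  if (startsWith(t, "\"")) {
    gsub("\\\\\"", "\"", substr(t, 2L, nchar(t) - 1L))
  } else {
    t
  }
}

mini_read_attrs <- function(toks) {
  attrs <- stats::setNames(character(0), character(0))
  i <- 1L
  while (i <= length(toks)) {
    if (toks[i] %in% c("[", "]", ",", ";")) {
      i <- i + 1L
      next
    }
    stopifnot(i + 2L <= length(toks), toks[i + 1L] == "=")
    attrs[[mini_unquote(toks[i])]] <- mini_unquote(toks[i + 2L])
    i <- i + 3L
  }
  attrs
}

mini_merge <- function(base, new) {
  for (nm in names(new)) base[[nm]] <- new[[nm]]
  base
}

# returns list(directed, nodes, edges, node_resolved, edge_resolved)
mini_parse_dot <- function(text) {
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  directed <- grepl("^(strict\\s+)?digraph\\b", lines[1])
  body <- lines[-c(1L, length(lines))]
  node_defaults <- stats::setNames(character(0), character(0))
  edge_defaults <- node_defaults
  nodes <- character(0)
  node_resolved <- list()
  edges <- list()
  for (line in body) {
    toks <- mini_tokens(line)
    if (!length(toks)) next
    if (toks[1] %in% c("node", "edge", "graph") && length(toks) > 1 &&
        toks[2] == "[") {
      attrs <- mini_read_attrs(toks[-1])
      if (toks[1] == "node") node_defaults <- mini_merge(node_defaults, attrs)
      if (toks[1] == "edge") edge_defaults <- mini_merge(edge_defaults, attrs)
      next
    }
    if (length(toks) >= 3 && toks[2] == "=") next  # graph attribute
    first <- mini_unquote(toks[1])
    if (length(toks) >= 3 && toks[2] %in% c("--", "->")) {
      second <- mini_unquote(toks[3])
      attrs <- if (length(toks) > 3) mini_read_attrs(toks[-(1:3)]) else
        stats::setNames(character(0), character(0))
      for (id in c(first, second)) {
        if (!id %in% nodes) {
          nodes <- c(nodes, id)
          node_resolved[[id]] <- node_defaults
        }
      }
      edges[[length(edges) + 1L]] <- list(
        source = first, target = second,
        resolved = mini_merge(edge_defaults, attrs)
      )
    } else {
      attrs <- if (length(toks) > 1) mini_read_attrs(toks[-1]) else
        stats::setNames(character(0), character(0))
      if (!first %in% nodes) nodes <- c(nodes, first)
      node_resolved[[first]] <- mini_merge(node_defaults, attrs)
    }
  }
  list(directed = directed, nodes = nodes, edges = edges,
       node_resolved = node_resolved)
}

sorted_chr <- function(x) {
  x <- unname(vapply(x, as.character, "", USE.NAMES = FALSE))
  sort(x, method = "radix")
}

# keys compared between an original import result and its re-import after
# export, with per-key numeric tolerances
.rt_node_keys <- c(
  NODE_LABEL = NA, NODE_BORDER_PAINT = NA, NODE_FILL_COLOR = NA,
  NODE_BORDER_WIDTH = 1e-6, NODE_WIDTH = 1e-4, NODE_HEIGHT = 1e-4,
  NODE_SHAPE = NA, NODE_LABEL_FONT_FACE = NA, NODE_LABEL_FONT_SIZE = 1e-6,
  NODE_LABEL_FONT_COLOR = NA, NODE_X_POSITION = 1e-3, NODE_Y_POSITION = 1e-3,
  NODE_TOOLTIP = NA, NODE_BORDER_LINE_TYPE = NA, NODE_VISIBLE = NA,
  NODE_TRANSPARENCY = 1e-6
)
.rt_edge_keys <- c(
  EDGE_LABEL = NA, EDGE_UNSELECTED_PAINT = NA, EDGE_WIDTH = 1e-6,
  EDGE_LABEL_FONT_FACE = NA, EDGE_LABEL_FONT_SIZE = 1e-6,
  EDGE_LABEL_FONT_COLOR = NA, EDGE_LINE_TYPE = NA, EDGE_VISIBLE = NA,
  EDGE_TARGET_ARROW_SHAPE = NA, EDGE_SOURCE_ARROW_SHAPE = NA,
  EDGE_TOOLTIP = NA
)

.value_close <- function(a, b, tol) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (inherits(a, "rgba") && inherits(b, "rgba")) {
    return(all(unclass(a) == unclass(b)))
  }
  if (!is.na(tol) && is.numeric(a) && is.numeric(b)) {
    return(abs(a - b) <= tol)
  }
  identical(a, b)
}

# Exports an import result, re-imports the text, and checks that topology
# and every effective visual value survive within the stated tolerances.
expect_roundtrip_equivalent <- function(res, options = export_options(),
                                        info = NULL) {
  out <- export_network(res$network, res$style, res$views, options)
  res2 <- import_document(parse_dot(out$text))[[1]]
  n1 <- res$network
  n2 <- res2$network
  expect_identical(n2$directed, n1$directed, info = info)
  expect_identical(sorted_chr(strip_suid(n2$nodes$shared_name)),
                   sorted_chr(n1$nodes$shared_name), info = info)

  suid1 <- stats::setNames(n1$nodes$suid, n1$nodes$shared_name)
  suid2 <- stats::setNames(n2$nodes$suid, strip_suid(n2$nodes$shared_name))
  nm1 <- stats::setNames(n1$nodes$shared_name, as.character(n1$nodes$suid))
  nm2 <- stats::setNames(strip_suid(n2$nodes$shared_name),
                         as.character(n2$nodes$suid))

  pair_key <- function(net, names_of) {
    paste(names_of[as.character(net$edges$source_suid)],
          names_of[as.character(net$edges$target_suid)], sep = " | ")
  }
  k1 <- pair_key(n1, nm1)
  k2 <- pair_key(n2, nm2)
  expect_identical(sorted_chr(k2), sorted_chr(k1), info = info)

  for (nm in n1$nodes$shared_name) {
    for (key in names(.rt_node_keys)) {
      v1 <- effective_value(res$style, res$views, "node", suid1[[nm]], key)
      v2 <- effective_value(res2$style, res2$views, "node", suid2[[nm]], key)
      expect_true(.value_close(v1, v2, .rt_node_keys[[key]]),
                  info = paste0(info, " node '", nm, "' ", key))
    }
  }
  esuid1 <- stats::setNames(n1$edges$suid, k1)
  esuid2 <- stats::setNames(n2$edges$suid, k2)
  for (ek in k1) {
    for (key in names(.rt_edge_keys)) {
      v1 <- effective_value(res$style, res$views, "edge", esuid1[[ek]], key)
      v2 <- effective_value(res2$style, res2$views, "edge", esuid2[[ek]], key)
      expect_true(.value_close(v1, v2, .rt_edge_keys[[key]]),
                  info = paste0(info, " edge '", ek, "' ", key))
    }
  }
  invisible(res2)
}

toy_path <- function() system.file("extdata", "toy_example.gv",
                                   package = "cydot")
toy_export_path <- function() system.file("extdata", "toy_example_export.gv",
                                          package = "cydot")
operation_path <- function() system.file("extdata", "operation_example.gv",
                                         package = "cydot")

read_utf8 <- function(path) readLines(path, warn = FALSE, encoding = "UTF-8")
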