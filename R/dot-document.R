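# DOT document model: tokenizer, parser, serializer, default resolution.

.dot_keywords <- c("graph", "digraph", "subgraph", "node", "edge", "strict")

# Single-pass token scan. Works on bytes so that multibyte identifier
# characters (anything >= 0x80, e.g. "§") are accepted, as Graphviz does.
.dot_token_pattern <- paste0(
  "(?s)",
  "\"(?:[^\"\\\\]|\\\\.)*\"",                    # quoted string, \" escapes
  "|/\\*.*?\\*/",                                # block comment
  "|//[^\n]*",                                   # line comment
  "|#[^\n]*",                                    # preprocessor line
  "|->|--",                                      # edge operators
  "|[{}\\[\\];,=:>]",                            # punctuation
  "|[A-Za-z_\\x80-\\xFF][0-9A-Za-z_\\x80-\\xFF]*", # identifier
  "|-?(?:\\.[0-9]+|[0-9]+(?:\\.[0-9]*)?)",       # numeral
  "|<",                                          # start of HTML-like string
  "|[ \t\r\n]+"                                  # whitespace
)

.dot_line_col <- function(text, byte_pos) {
  raw <- charToRaw(text)
  nl <- which(raw[seq_len(min(byte_pos - 1L, length(raw)))] == as.raw(10L))
  line <- length(nl) + 1L
  col <- byte_pos - (if (length(nl)) nl[length(nl)] else 0L)
  c(line = line, col = col)
}

.stop_parse <- function(msg, line = NA_integer_, col = NA_integer_,
                        class = "dot_parse_error") {
  loc <- if (!is.na(line)) sprintf(" at line %d, column %d", line, col) else ""
  cond <- structure(
    class = c(class, "dot_parse_error", "error", "condition"),
    list(message = paste0(msg, loc), call = NULL,
         line = line, col = col)
  )
  stop(cond)
}

# Quoted-string unescaping: \" becomes ", a backslash-newline pair is removed
# (line continuation), every other backslash pair is kept verbatim so that
# Graphviz escapes such as \N survive as data.
.dot_unescape <- function(s) {
  s <- substr(s, 2L, nchar(s) - 1L)
  s <- gsub("\\\\\n", "", s)
  gsub("\\\\\"", "\"", s)
}

dot_tokenize <- function(text) {
  text <- enc2utf8(paste(text, collapse = "\n"))
  empty <- list(type = character(0), value = character(0),
                line = integer(0), col = integer(0))
  if (!nzchar(text)) return(empty)
  # any "<" outside a quoted string or comment opens an HTML-like string,
  # which is unsupported; find it on a copy with strings/comments blanked
  masked <- text
  mm <- gregexpr("(?s)\"(?:[^\"\\\\]|\\\\.)*\"|/\\*.*?\\*/|//[^\n]*",
                 masked, perl = TRUE, useBytes = TRUE)[[1]]
  if (mm[1] != -1L) {
    regmatches(masked, list(mm)) <- list(
      vapply(attr(mm, "match.length"),
             function(n) strrep(" ", n), ""))
  }
  lt <- regexpr("<", masked, fixed = TRUE, useBytes = TRUE)
  if (lt != -1L) {
    lc <- .dot_line_col(text, as.integer(lt))
    .stop_parse("HTML-like labels are not supported", lc["line"], lc["col"],
                class = "dot_html_error")
  }
  m <- gregexpr(.dot_token_pattern, text, perl = TRUE, useBytes = TRUE)[[1]]
  nb <- nchar(text, type = "bytes")
  if (m[1] == -1L) {
    lc <- .dot_line_col(text, 1L)
    .stop_parse("unexpected character", lc["line"], lc["col"])
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  ends <- starts + lens - 1L
  expected <- c(1L, ends[-length(ends)] + 1L)
  bad <- which(starts != expected)
  if (length(bad)) {
    lc <- .dot_line_col(text, expected[bad[1]])
    .stop_parse("unexpected character", lc["line"], lc["col"])
  }
  if (ends[length(ends)] != nb) {
    lc <- .dot_line_col(text, ends[length(ends)] + 1L)
    .stop_parse("unexpected character", lc["line"], lc["col"])
  }
  vals <- regmatches(text, list(m))[[1]]
  Encoding(vals) <- "UTF-8"
  first <- substr(vals, 1L, 1L)
  keep <- !(first %in% c(" ", "\t", "\r", "\n")) &
    !(first == "/" & nchar(vals) > 1L)
  lcs <- vapply(starts, function(p) .dot_line_col(text, p), integer(2))
  type <- character(length(vals))
  type[first == "\""] <- "str"
  type[vals %in% c("--", "->")] <- "edgeop"
  type[vals %in% c("{", "}", "[", "]", ";", ",", "=", ":", ">")] <- "punct"
  type[first == "<"] <- "html"
  type[first == "#"] <- "pre"
  type[type == ""] <- "id"
  # preprocessor lines are only legal at the start of a line
  pre_bad <- which(type == "pre" & lcs[2, ] != 1L)
  if (length(pre_bad)) {
    .stop_parse("'#' is only allowed at the start of a line",
                lcs[1, pre_bad[1]], lcs[2, pre_bad[1]])
  }
  keep <- keep & type != "pre"
  vals[type == "str"] <- vapply(vals[type == "str"], .dot_unescape, "")
  list(type = type[keep], value = vals[keep],
       line = lcs[1, keep], col = lcs[2, keep])
}

# -- parser ------------------------------------------------------------------

.new_cursor <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$i <- 1L
  env$n <- length(toks$type)
  env$sid <- 0L
  env
}

.peek <- function(p, k = 0L) {
  i <- p$i + k
  if (i > p$n) {
    last <- if (p$n) p$toks$line[p$n] else 1L
    return(list(type = "eof", value = "", line = last, col = 1L))
  }
  list(type = p$toks$type[i], value = p$toks$value[i],
       line = p$toks$line[i], col = p$toks$col[i])
}

.advance <- function(p) {
  t <- .peek(p)
  p$i <- p$i + 1L
  t
}

.next_sid <- function(p) {
  p$sid <- p$sid + 1L
  p$sid
}

.is_idlike <- function(t) t$type %in% c("id", "str")

.expect_id <- function(p, what = "identifier") {
  t <- .advance(p)
  if (t$type == "html") {
    .stop_parse("HTML-like labels are not supported", t$line, t$col,
                class = "dot_html_error")
  }
  if (!.is_idlike(t)) {
    .stop_parse(sprintf("expected %s, got '%s'", what, t$value),
                t$line, t$col)
  }
  t$value
}

.expect_punct <- function(p, ch) {
  t <- .advance(p)
  if (!(t$type == "punct" && t$value == ch)) {
    .stop_parse(sprintf("expected '%s', got '%s'", ch, t$value),
                t$line, t$col)
  }
  invisible(t)
}

.empty_attrs <- function() stats::setNames(character(0), character(0))

.merge_attrs <- function(base, new) {
  for (nm in names(new)) base[[nm]] <- new[[nm]]
  base
}

.parse_attr_lists <- function(p) {
  attrs <- .empty_attrs()
  while (.peek(p)$type == "punct" && .peek(p)$value == "[") {
    .advance(p)
    repeat {
      t <- .peek(p)
      if (t$type == "punct" && t$value == "]") {
        .advance(p)
        break
      }
      name <- .expect_id(p, "attribute name")
      .expect_punct(p, "=")
      value <- .expect_id(p, "attribute value")
      attrs[[name]] <- value
      t <- .peek(p)
      if (t$type == "punct" && t$value %in% c(",", ";")) .advance(p)
    }
  }
  attrs
}

# node endpoint: ID with optional :port[:compass] suffix (suffix discarded)
.parse_node_id <- function(p) {
  id <- .expect_id(p, "node id")
  had_port <- FALSE
  while (.peek(p)$type == "punct" && .peek(p)$value == ":") {
    .advance(p)
    .expect_id(p, "port name")
    had_port <- TRUE
  }
  if (had_port) {
    warning(sprintf("port suffix on node '%s' discarded (record nodes are not supported)",
                    id), call. = FALSE)
  }
  id
}

.collect_node_ids <- function(statements) {
  ids <- character(0)
  for (s in statements) {
    ids <- switch(s$type,
      node = c(ids, s$id),
      edge = c(ids, s$source, s$target),
      subgraph = c(ids, .collect_node_ids(s$statements)),
      ids
    )
  }
  unique(ids)
}

.parse_subgraph <- function(p, depth, directed) {
  name <- ""
  t <- .peek(p)
  if (t$type == "id" && tolower(t$value) == "subgraph") {
    .advance(p)
    if (.is_idlike(.peek(p))) name <- .advance(p)$value
  }
  .expect_punct(p, "{")
  stmts <- .parse_stmt_list(p, depth + 1L, directed)
  .expect_punct(p, "}")
  list(type = "subgraph", name = name, statements = stmts, sid = .next_sid(p))
}

.parse_stmt_list <- function(p, depth, directed) {
  stmts <- list()
  repeat {
    t <- .peek(p)
    if (t$type == "eof" || (t$type == "punct" && t$value == "}")) break
    if (t$type == "punct" && t$value == ";") {
      .advance(p)
      next
    }
    if (t$type == "html") {
      .stop_parse("HTML-like labels are not supported", t$line, t$col,
                  class = "dot_html_error")
    }
    is_sub <- (t$type == "punct" && t$value == "{") ||
      (t$type == "id" && tolower(t$value) == "subgraph" &&
         !(.peek(p, 1L)$type == "punct" && .peek(p, 1L)$value == "="))
    if (is_sub) {
      sg <- .parse_subgraph(p, depth, directed)
      stmts[[length(stmts) + 1L]] <- sg
      if (.peek(p)$type == "edgeop") {
        stmts <- c(stmts, .parse_edge_chain(p, .collect_node_ids(sg$statements),
                                            depth, directed))
      }
      next
    }
    kw <- if (t$type == "id") tolower(t$value) else ""
    nxt <- .peek(p, 1L)
    if (kw %in% c("node", "edge", "graph") &&
        nxt$type == "punct" && nxt$value == "[") {
      .advance(p)
      attrs <- .parse_attr_lists(p)
      stmts[[length(stmts) + 1L]] <- list(type = "default", target = kw,
                                          attrs = attrs, scope_depth = depth,
                                          sid = .next_sid(p))
      next
    }
    if (.is_idlike(t) && nxt$type == "punct" && nxt$value == "=") {
      name <- .advance(p)$value
      .advance(p)
      value <- .expect_id(p, "attribute value")
      stmts[[length(stmts) + 1L]] <- list(
        type = "graphattr",
        attrs = stats::setNames(value, name),
        scope_depth = depth, sid = .next_sid(p)
      )
      next
    }
    if (.is_idlike(t)) {
      id <- .parse_node_id(p)
      if (.peek(p)$type == "edgeop") {
        stmts <- c(stmts, .parse_edge_chain(p, id, depth, directed))
      } else {
        attrs <- .parse_attr_lists(p)
        stmts[[length(stmts) + 1L]] <- list(type = "node", id = id,
                                            attrs = attrs, sid = .next_sid(p))
      }
      next
    }
    .stop_parse(sprintf("unexpected token '%s'", t$value), t$line, t$col)
  }
  stmts
}

# Edge chains (a -- b -- c) expand into pairwise edge statements; subgraph
# endpoints expand over their contained node ids.
.parse_edge_chain <- function(p, first_endpoint, depth, directed) {
  endpoints <- list(first_endpoint)
  extra <- list()
  while (.peek(p)$type == "edgeop") {
    op <- .advance(p)
    if (directed && op$value != "->") {
      .stop_parse("undirected edge operator '--' in a digraph", op$line, op$col)
    }
    if (!directed && op$value != "--") {
      .stop_parse("directed edge operator '->' in an undirected graph",
                  op$line, op$col)
    }
    t <- .peek(p)
    is_sub <- (t$type == "punct" && t$value == "{") ||
      (t$type == "id" && tolower(t$value) == "subgraph")
    if (is_sub) {
      sg <- .parse_subgraph(p, depth, directed)
      extra[[length(extra) + 1L]] <- sg
      endpoints[[length(endpoints) + 1L]] <- .collect_node_ids(sg$statements)
    } else {
      endpoints[[length(endpoints) + 1L]] <- .parse_node_id(p)
    }
  }
  attrs <- .parse_attr_lists(p)
  edges <- list()
  for (k in seq_len(length(endpoints) - 1L)) {
    for (a in endpoints[[k]]) {
      for (b in endpoints[[k + 1L]]) {
        edges[[length(edges) + 1L]] <- list(type = "edge", source = a,
                                            target = b, attrs = attrs,
                                            sid = .next_sid(p))
      }
    }
  }
  c(extra, edges)
}

.parse_graph <- function(p) {
  t <- .advance(p)
  strict <- FALSE
  if (t$type == "id" && tolower(t$value) == "strict") {
    strict <- TRUE
    t <- .advance(p)
  }
  if (!(t$type == "id" && tolower(t$value) %in% c("graph", "digraph"))) {
    .stop_parse(sprintf("expected 'graph' or 'digraph', got '%s'", t$value),
                t$line, t$col)
  }
  directed <- tolower(t$value) == "digraph"
  name <- ""
  if (.is_idlike(.peek(p))) name <- .advance(p)$value
  .expect_punct(p, "{")
  stmts <- .parse_stmt_list(p, 0L, directed)
  .expect_punct(p, "}")
  g <- list(name = name, directed = directed, strict = strict,
            statements = stmts, graph_attrs = .empty_attrs())
  g <- .normalize_graph(g, p)
  g$graph_attrs <- .root_graph_attrs(g$statements)
  class(g) <- "dot_graph"
  g
}

.root_graph_attrs <- function(statements) {
  attrs <- .empty_attrs()
  for (s in statements) {
    if (s$type == "graphattr" && s$scope_depth == 0L) {
      attrs <- .merge_attrs(attrs, s$attrs)
    } else if (s$type == "default" && s$target == "graph" &&
               s$scope_depth == 0L) {
      attrs <- .merge_attrs(attrs, s$attrs)
    }
  }
  attrs
}

# Nodes first referenced by an edge are declared implicitly, with empty
# attributes, immediately before the referencing edge statement.
.normalize_graph <- function(g, p) {
  declared <- new.env(parent = emptyenv())
  key <- function(id) paste0("id:", id)  # "" is a legal quoted node id
  rebuild <- function(stmts) {
    out <- list()
    for (s in stmts) {
      if (s$type == "node") {
        assign(key(s$id), TRUE, envir = declared)
      } else if (s$type == "edge") {
        for (id in c(s$source, s$target)) {
          if (!exists(key(id), envir = declared, inherits = FALSE)) {
            assign(key(id), TRUE, envir = declared)
            out[[length(out) + 1L]] <- list(type = "node", id = id,
                                            attrs = .empty_attrs(),
                                            sid = .next_sid(p))
          }
        }
      } else if (s$type == "subgraph") {
        s$statements <- rebuild(s$statements)
      }
      out[[length(out) + 1L]] <- s
    }
    out
  }
  g$statements <- rebuild(g$statements)
  g
}

#' Parse DOT text into a document model
#'
#' Parses one or more graphs written in the Graphviz DOT language into a
#' `dot_document`: an ordered list of `dot_graph` objects, each holding its
#' statements (node, edge, default-attribute, graph-attribute and subgraph
#' statements) in document order. Comments are discarded, edge chains
#' (`a -- b -- c`) are expanded into pairwise edge statements, port suffixes
#' on edge endpoints are discarded with a warning, and nodes first referenced
#' by an edge are implicitly declared with empty attributes.
#'
#' @param text DOT source, a character vector (joined with newlines).
#' @return A `dot_document`; `$graphs` lists the parsed graphs in file order.
#' @details Malformed input raises a classed condition (`dot_parse_error`)
#'   carrying the line and column of the offending token. HTML-like labels
#'   (`label=<...>`) are not supported and raise the more specific
#'   `dot_html_error`.
#' @seealso [serialize_dot()], [read_dot()], [resolve_attrs()]
#' @examples
#' doc <- parse_dot("digraph g { a -> b }")
#' length(doc$graphs[[1]]$statements)
#' @export
parse_dot <- function(text) {
  toks <- dot_tokenize(text)
  p <- .new_cursor(toks)
  graphs <- list()
  while (.peek(p)$type != "eof") {
    graphs[[length(graphs) + 1L]] <- .parse_graph(p)
  }
  structure(list(graphs = graphs), class = "dot_document")
}

#' Read a DOT file
#'
#' Reads and parses a Graphviz file. The `.dot` and `.gv` extensions are
#' interchangeable; no distinction is made between them.
#'
#' @param path Path to a `.dot` or `.gv` file.
#' @return A `dot_document`.
#' @export
read_dot <- function(path) {
  parse_dot(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

# -- accessors ---------------------------------------------------------------

#' List the nodes of a parsed graph
#'
#' Returns the graph's nodes in first-appearance order (implicit declarations
#' included). Repeated declarations of the same id are merged, later
#' attribute values winning.
#'
#' @param graph A `dot_graph`.
#' @return A list of `list(id, attrs)` records.
#' @export
dot_nodes <- function(graph) {
  order <- character(0)
  attrs <- list()
  key <- function(id) paste0("id:", id)
  walk <- function(stmts) {
    for (s in stmts) {
      if (s$type == "node") {
        if (!(s$id %in% order)) {
          order <<- c(order, s$id)
          attrs[[key(s$id)]] <<- .empty_attrs()
        }
        attrs[[key(s$id)]] <<- .merge_attrs(attrs[[key(s$id)]], s$attrs)
      } else if (s$type == "subgraph") {
        walk(s$statements)
      }
    }
  }
  walk(graph$statements)
  lapply(order, function(id) list(id = id, attrs = attrs[[key(id)]]))
}

#' List the edges of a parsed graph
#'
#' @param graph A `dot_graph`.
#' @return The graph's edge statements, flattened in document order
#'   (statements inside subgraphs appear at the subgraph's position).
#' @export
dot_edges <- function(graph) {
  edges <- list()
  walk <- function(stmts) {
    for (s in stmts) {
      if (s$type == "edge") {
        edges[[length(edges) + 1L]] <<- s
      } else if (s$type == "subgraph") {
        walk(s$statements)
      }
    }
  }
  walk(graph$statements)
  edges
}

#' Resolve default-attribute inheritance for one element
#'
#' Computes the merged attribute map for a node or edge statement: the
#' root-graph default statements of the matching kind that appear before the
#' element, applied in document order, overlaid by the element's own
#' attributes. Default statements declared inside subgraphs are ignored —
#' only defaults set within the root graph participate.
#'
#' @param graph A `dot_graph`.
#' @param element A node or edge statement taken from `graph$statements`
#'   (possibly nested in a subgraph).
#' @return A named character vector of resolved attributes.
#' @export
resolve_attrs <- function(graph, element) {
  if (!element$type %in% c("node", "edge")) {
    stop("element must be a node or edge statement")
  }
  defaults <- list(node = .empty_attrs(), edge = .empty_attrs())
  result <- NULL
  walk <- function(stmts, depth) {
    for (s in stmts) {
      if (!is.null(result)) return()
      if (identical(s$sid, element$sid)) {
        kind <- element$type
        result <<- .merge_attrs(defaults[[kind]], element$attrs)
        return()
      }
      if (s$type == "default" && depth == 0L &&
          s$target %in% c("node", "edge")) {
        defaults[[s$target]] <<- .merge_attrs(defaults[[s$target]], s$attrs)
      } else if (s$type == "subgraph") {
        walk(s$statements, depth + 1L)
      }
    }
  }
  walk(graph$statements, 0L)
  if (is.null(result)) stop("element not found in graph")
  result
}

# -- serializer --------------------------------------------------------------

.id_needs_quotes <- function(s) {
  if (!nzchar(s)) return(TRUE)
  if (tolower(s) %in% .dot_keywords) return(TRUE)
  plain <- grepl("^[A-Za-z_][A-Za-z0-9_]*$", s)
  numeral <- grepl("^-?(\\.[0-9]+|[0-9]+(\\.[0-9]*)?)$", s)
  !(plain || numeral)
}

.quote_id <- function(s) {
  if (!.id_needs_quotes(s)) return(s)
  # the only escape in a DOT quoted string is \"; a literal backslash
  # immediately before a quote cannot be represented and is doubled
  s <- gsub("\\\\(?=\")", "\\\\\\\\", s, perl = TRUE)
  paste0("\"", gsub("\"", "\\\\\"", s), "\"")
}

.ser_attrs <- function(attrs, always = FALSE) {
  if (!length(attrs) && !always) return("")
  body <- paste(vapply(names(attrs), function(nm) {
    paste0(.quote_id(nm), "=", .quote_id(attrs[[nm]]))
  }, ""), collapse = ", ")
  paste0(" [", body, "]")
}

.ser_stmt <- function(s, indent, directed) {
  switch(s$type,
    node = paste0(indent, .quote_id(s$id), .ser_attrs(s$attrs), ";"),
    edge = paste0(indent, .quote_id(s$source),
                  if (directed) " -> " else " -- ",
                  .quote_id(s$target), .ser_attrs(s$attrs), ";"),
    default = paste0(indent, s$target, .ser_attrs(s$attrs, always = TRUE), ";"),
    graphattr = paste0(indent, .quote_id(names(s$attrs)), " = ",
                       .quote_id(s$attrs[[1L]]), ";"),
    subgraph = c(
      paste0(indent, "subgraph ",
             if (nzchar(s$name)) paste0(.quote_id(s$name), " ") else "", "{"),
      unlist(lapply(s$statements, .ser_stmt, indent = paste0(indent, "  "),
                    directed = directed)),
      paste0(indent, "}")
    )
  )
}

.ser_graph <- function(g) {
  header <- paste0(
    if (g$strict) "strict " else "",
    if (g$directed) "digraph" else "graph",
    if (nzchar(g$name)) paste0(" ", .quote_id(g$name)) else "",
    " {"
  )
  body <- unlist(lapply(g$statements, .ser_stmt, indent = "  ",
                        directed = g$directed))
  paste(c(header, body, "}"), collapse = "\n")
}

#' Serialize a DOT document back to text
#'
#' Emits grammar-valid DOT. Identifiers are quoted whenever they contain
#' characters outside `[A-Za-z0-9_]`, start with a digit while containing
#' non-digits, are empty, or collide with a DOT keyword; plain numerals stay
#' unquoted. Reparsing the output yields a structurally equal document.
#'
#' @param doc A `dot_document`.
#' @return A single string of DOT text, newline-terminated.
#' @seealso [parse_dot()], [dot_equal()]
#' @export
serialize_dot <- function(doc) {
  stopifnot(inherits(doc, "dot_document"))
  paste0(paste(vapply(doc$graphs, .ser_graph, ""), collapse = "\n"), "\n")
}

#' Write a DOT document to a file
#'
#' @param doc A `dot_document`.
#' @param path Output path (`.dot` or `.gv`).
#' @export
write_dot <- function(doc, path) {
  writeLines(serialize_dot(doc), path, sep = "", useBytes = FALSE)
  invisible(path)
}

.strip_sids <- function(x) {
  if (is.list(x)) {
    x$sid <- NULL
    x[] <- lapply(x, .strip_sids)
  }
  x
}

#' Structural equality of DOT documents
#'
#' Compares two parsed documents field by field (graph order, names,
#' directedness, statement order, attribute maps), ignoring internal
#' statement identifiers. This is the equality under which
#' `parse_dot(serialize_dot(doc))` reproduces `doc`.
#'
#' @param a,b `dot_document` objects.
#' @return `TRUE` or `FALSE`.
#' @export
dot_equal <- function(a, b) {
  identical(.strip_sids(unclass(a)), .strip_sids(unclass(b)))
}

#' @export
print.dot_document <- function(x, ...) {
  cat(sprintf("<dot_document: %d graph(s)>\n", length(x$graphs)))
  for (g in x$graphs) {
    cat(sprintf("  %s %s: %d nodes, %d edges\n",
                if (g$directed) "digraph" else "graph",
                if (nzchar(g$name)) g$name else "<unnamed>",
                length(dot_nodes(g)), length(dot_edges(g))))
  }
  invisible(x)
}
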