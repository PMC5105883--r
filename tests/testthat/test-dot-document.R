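test_that("the toy neato listing parses with the expected structure", {
  doc <- read_dot(toy_path())
  expect_length(doc$graphs, 1L)
  g <- doc$graphs[[1]]
  expect_false(g$directed)
  expect_identical(g$name, "toy_example")
  expect_length(dot_nodes(g), 4L)
  expect_length(dot_edges(g), 5L)
  defaults <- Filter(function(s) s$type == "default" && s$target == "node",
                     g$statements)
  expect_length(defaults, 1L)
  expect_identical(
    defaults[[1]]$attrs,
    c(fillcolor = "#888888", label = "\\N", style = "filled")
  )
})

test_that("a minimal digraph parses", {
  g <- parse_dot("digraph g { a -> b }")$graphs[[1]]
  expect_true(g$directed)
  expect_identical(vapply(dot_nodes(g), `[[`, "", "id"), c("a", "b"))
  expect_length(dot_edges(g), 1L)
  expect_identical(dot_edges(g)[[1]]$source, "a")
})

test_that("HTML-like labels raise a distinct error class", {
  expect_error(parse_dot("graph g { a [label=<<b>x</b>>] }"),
               class = "dot_html_error")
  expect_error(parse_dot("graph g { a [label=<<b>x</b>>] }"),
               class = "dot_parse_error")
})

test_that("malformed input reports line and column", {
  err <- tryCatch(parse_dot("graph g {\n  a [color= }\n}"),
                  dot_parse_error = function(e) e)
  expect_s3_class(err, "dot_parse_error")
  expect_match(conditionMessage(err), "line 2")
  expect_error(parse_dot("graph {"), class = "dot_parse_error")
  expect_error(parse_dot("graph g { a -> b }"), class = "dot_parse_error")
})

test_that("comments of all three kinds are consumed and discarded", {
  with_comments <- paste(
    "# preprocessor line",
    "graph g { // trailing",
    "  /* block",
    "     comment */ a -- b;",
    "}", sep = "\n")
  expect_true(dot_equal(parse_dot(with_comments),
                        parse_dot("graph g { a -- b }")))
})

test_that("default resolution follows document order within the root graph", {
  doc <- read_dot(toy_path())
  g <- doc$graphs[[1]]
  node1 <- Filter(function(s) s$type == "node" && s$id == "1",
                  g$statements)[[1]]
  expect_identical(
    resolve_attrs(g, node1),
    c(fillcolor = "#888888", label = "\\N", style = "filled",
      height = "0.5", pos = "-58.648,-8.4777", width = "0.75")
  )

  # defaults declared after an element do not reach it
  g2 <- parse_dot("graph g { a; node [shape=box]; b }")$graphs[[1]]
  stmts <- Filter(function(s) s$type == "node", g2$statements)
  expect_identical(resolve_attrs(g2, stmts[[1]]),
                   stats::setNames(character(0), character(0)))
  expect_identical(resolve_attrs(g2, stmts[[2]]), c(shape = "box"))
})

test_that("defaults declared inside subgraphs are ignored", {
  g <- parse_dot("graph g { subgraph s { node [shape=box] } c }")$graphs[[1]]
  c_stmt <- Filter(function(s) s$type == "node" && s$id == "c",
                   g$statements)[[1]]
  expect_identical(resolve_attrs(g, c_stmt),
                   stats::setNames(character(0), character(0)))
  # but root defaults do reach elements inside subgraphs
  g2 <- parse_dot(
    "graph g { node [shape=box]; subgraph s { c } }")$graphs[[1]]
  c2 <- Filter(function(s) s$type == "node" && s$id == "c",
               g2$statements[[2]]$statements)[[1]]
  expect_identical(resolve_attrs(g2, c2), c(shape = "box"))
})

test_that("edge chains expand into pairwise edges with shared attrs", {
  g <- parse_dot("digraph g { a -> b -> c [penwidth=2] }")$graphs[[1]]
  edges <- dot_edges(g)
  expect_length(edges, 2L)
  expect_identical(edges[[1]]$attrs, c(penwidth = "2"))
  expect_identical(edges[[2]]$source, "b")
})

test_that("port suffixes are discarded with a warning", {
  expect_warning(doc <- parse_dot("digraph g { a:n -> b }"), "port suffix")
  e <- dot_edges(doc$graphs[[1]])[[1]]
  expect_identical(c(e$source, e$target), c("a", "b"))
  doc2 <- suppressWarnings(parse_dot("digraph g { a:n -> b:port:sw }"))
  e2 <- dot_edges(doc2$graphs[[1]])[[1]]
  expect_identical(c(e2$source, e2$target), c("a", "b"))
})

test_that("repeated node declarations merge with last-wins", {
  g <- parse_dot(
    "graph g { a [color=red, shape=box]; a [color=blue] }")$graphs[[1]]
  nodes <- dot_nodes(g)
  expect_length(nodes, 1L)
  expect_identical(nodes[[1]]$attrs, c(color = "blue", shape = "box"))
})

test_that("strict and multiple graphs per file are preserved in order", {
  doc <- parse_dot("strict digraph a { x } graph b { y }")
  expect_length(doc$graphs, 2L)
  expect_true(doc$graphs[[1]]$strict)
  expect_identical(vapply(doc$graphs, `[[`, "", "name"), c("a", "b"))
  expect_match(serialize_dot(doc), "^strict digraph a \\{")
})

test_that("serialization round-trips structurally", {
  samples <- c(
    "graph {}",
    "digraph g { a -> b [label=\"x y\"] }",
    'graph g2 { "Node 1" [label="say \\"hi\\""]; "Node 1" -- b }',
    "graph g3 { node [shape=box]; s = v; subgraph inner { a -- b } }"
  )
  for (txt in samples) {
    doc <- parse_dot(txt)
    expect_true(dot_equal(parse_dot(serialize_dot(doc)), doc), info = txt)
  }
  toy <- read_dot(toy_path())
  expect_true(dot_equal(parse_dot(serialize_dot(toy)), toy))
})

test_that("identifiers are quoted exactly when the grammar requires it", {
  txt <- serialize_dot(parse_dot(
    'graph { "Node 1§64"; plain_id; 42; -58.6; "2x"; "" }'))
  expect_match(txt, "\"Node 1§64\";", fixed = TRUE)
  expect_match(txt, "\n  plain_id;", fixed = TRUE)
  expect_match(txt, "\n  42;", fixed = TRUE)
  expect_match(txt, "\n  -58.6;", fixed = TRUE)
  expect_match(txt, "\"2x\";", fixed = TRUE)
  expect_match(txt, "\"\";", fixed = TRUE)
})

test_that("an empty graph serializes to the minimal form", {
  expect_identical(serialize_dot(parse_dot("graph {}")), "graph {\n}\n")
})

test_that("escaped quotes and \\N survive the value round trip", {
  g <- parse_dot('graph { a [label="a\\"b", tag="\\N"] }')$graphs[[1]]
  attrs <- dot_nodes(g)[[1]]$attrs
  expect_identical(unname(attrs["label"]), "a\"b")
  expect_identical(unname(attrs["tag"]), "\\N")
  doc <- parse_dot('graph { a [label="a\\"b"] }')
  expect_true(dot_equal(parse_dot(serialize_dot(doc)), doc))
})

test_that("the parser reads DOT written by igraph", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:12, 1L)
    ig <- igraph::sample_gnp(n, 0.4, directed = seed %% 2 == 0)
    path <- withr::local_tempfile(fileext = ".gv")
    suppressWarnings(igraph::write_graph(ig, path, format = "dot"))
    g <- suppressWarnings(read_dot(path))$graphs[[1]]
    expect_identical(g$directed, igraph::is_directed(ig))
    expect_length(dot_nodes(g), igraph::vcount(ig))
    el <- igraph::as_edgelist(ig, names = FALSE) - 1L
    ours <- t(vapply(dot_edges(g),
                     function(e) as.integer(c(e$source, e$target)),
                     integer(2)))
    key <- function(m) {
      if (!igraph::is_directed(ig)) m <- t(apply(m, 1L, sort))
      sort(paste(m[, 1], m[, 2]))
    }
    if (nrow(el)) expect_identical(key(ours), key(el)) else
      expect_identical(nrow(ours), 0L)
  }
})
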