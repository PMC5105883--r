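test_that("unit conversion between inches and points is exact", {
  expect_identical(inches_to_points(0.5), 36)
  expect_identical(inches_to_points(0.75), 54)
  expect_identical(inches_to_points(0), 0)
  expect_equal(inches_to_points(1.041667), 75.000024)
  expect_identical(points_to_inches(36), 0.5)
  expect_error(inches_to_points(-1), "negative")
  x <- c(0.1, 0.5, 35, 72.3)
  expect_equal(points_to_inches(inches_to_points(x)), x, tolerance = 1e-12)
})

test_that("node positions parse with the self-inverse y flip", {
  expect_equal(parse_pos("-58.648,-8.4777"), c(x = -58.648, y = 8.4777))
  expect_equal(parse_pos("8.8474,55.497"), c(x = 8.8474, y = -55.497))
  expect_equal(parse_pos("0,0"), c(x = 0, y = 0))
  expect_equal(parse_pos("1.5,2.5!"), c(x = 1.5, y = -2.5))  # pin flag
  expect_null(parse_pos("1.5"))
  expect_null(parse_pos("a,b"))
})

test_that("colors parse from hex and X11 names, rejecting lists and schemes", {
  expect_identical(parse_color("#FFFFFFFF"), rgba(255, 255, 255, 255))
  expect_identical(parse_color("#888888"), rgba(136, 136, 136, 255))
  expect_identical(parse_color("#8040C080"), rgba(128, 64, 192, 128))
  expect_identical(parse_color("red"), rgba(255, 0, 0))
  expect_identical(parse_color("LightGrey"), rgba(211, 211, 211))
  expect_null(parse_color("red:blue"))            # parallel-edge color list
  expect_null(parse_color("red:blue;0.5"))        # weighted list
  expect_null(parse_color("0.482 0.714 0.878"))   # HSV triple
  expect_null(parse_color("/accent3/2"))          # brewer scheme reference
  expect_null(parse_color("notacolorname"))
})

test_that("hex fill colors agree with an independent hex-decode oracle", {
  oracle <- function(hex) {
    # independent decode path: byte-wise strtoi over the raw string
    chans <- strtoi(substring(hex, seq(2, nchar(hex) - 1, 2),
                              seq(3, nchar(hex), 2)), base = 16L)
    if (length(chans) == 3L) chans <- c(chans, 255L)
    chans
  }
  for (seed in 1:20) {
    fix <- generate_fixture(fixture_spec(seed, n_nodes = 6L,
                                         attr_density = 0.9))
    res <- import_document(parse_dot(fix))[[1]]
    g <- parse_dot(fix)$graphs[[1]]
    for (node in dot_nodes(g)) {
      fill <- node$attrs["fillcolor"]
      if (is.na(fill) || !startsWith(unname(fill), "#")) next
      suid <- res$network$nodes$suid[
        res$network$nodes$shared_name == node$id]
      eff <- effective_value(res$style, res$views, "node", suid,
                             "NODE_FILL_COLOR")
      expect_identical(unname(unclass(eff)), oracle(unname(fill)))
    }
  }
})

test_that("node shapes map to the supported vocabulary", {
  expect_identical(map_node_shape("box"), "rectangle")
  expect_identical(map_node_shape("rect"), "rectangle")
  expect_identical(map_node_shape("Mdiamond"), "diamond")
  expect_identical(map_node_shape("Msquare"), "square")
  expect_identical(map_node_shape("Mcircle"), "circle")
  expect_identical(map_node_shape("ellipse"), "ellipse")
  expect_null(map_node_shape("cylinder"))
  expect_null(map_node_shape("star"))
})

test_that("arrow shapes map with open variants collapsing to closed", {
  expect_identical(map_arrow_shape("tee"), "tee")
  expect_identical(map_arrow_shape("onormal"), "normal")
  expect_identical(map_arrow_shape("odot"), "dot")
  expect_identical(map_arrow_shape("odiamond"), "diamond")
  expect_null(map_arrow_shape("crow"))
})

test_that("style keywords map per element kind", {
  r <- apply_style_keywords("filled", "node", "ellipse")
  expect_identical(r$overrides, list(NODE_TRANSPARENCY = 255))
  expect_length(r$log, 0L)

  r <- apply_style_keywords("invis", "edge")
  expect_identical(r$overrides, list(EDGE_VISIBLE = FALSE))

  # rounded only affects rectangle-family shapes
  r <- apply_style_keywords("rounded", "node", "ellipse")
  expect_identical(r$overrides, list())
  expect_length(r$log, 1L)
  r <- apply_style_keywords("rounded", "node", "box")
  expect_identical(r$overrides, list(NODE_SHAPE = "round-rectangle"))

  r <- apply_style_keywords("dashed,bold", "node", NULL)
  expect_identical(r$overrides, list(NODE_BORDER_LINE_TYPE = "dashed"))
  expect_length(r$log, 1L)

  # duplicates: last wins
  r <- apply_style_keywords("dashed,dotted", "edge")
  expect_identical(r$overrides, list(EDGE_LINE_TYPE = "dotted"))
})

test_that("node attribute maps follow the conversion table", {
  m <- map_node_attrs(c(height = "0.5", width = "0.75"))
  expect_identical(m$overrides,
                   list(NODE_HEIGHT = 36, NODE_WIDTH = 54))

  m <- map_node_attrs(c(label = "\\N"), name = "2")
  expect_identical(m$overrides$NODE_LABEL, "2")
  m <- map_node_attrs(c(label = "\\N"))
  expect_identical(m$overrides$NODE_LABEL, "\\N")

  m <- map_node_attrs(c(shape = "star"))
  expect_length(m$overrides, 0L)
  expect_length(m$log, 1L)

  m <- map_node_attrs(c(xlabel = "X", fontsize = "9.5", penwidth = "2",
                        tooltip = "t", fontname = "Courier"))
  expect_identical(m$overrides$NODE_LABEL, "X")
  expect_identical(m$overrides$NODE_LABEL_FONT_SIZE, 9.5)
  expect_identical(m$overrides$NODE_BORDER_WIDTH, 2)
  expect_identical(m$overrides$NODE_TOOLTIP, "t")
})

test_that("edge attribute maps route weight to the data table slot", {
  m <- map_edge_attrs(c(weight = "3"))
  expect_identical(m$weight, 3)
  expect_length(m$overrides, 0L)
  expect_length(m$log, 0L)

  m <- map_edge_attrs(c(pos = "10.278,0.079128 -2.8626,-1.5522"))
  expect_length(m$overrides, 0L)
  expect_length(m$log, 1L)
  expect_match(m$log[[1]]$reason, "straight lines")

  m <- map_edge_attrs(c(arrowhead = "odot", arrowtail = "vee",
                        color = "#11223344"))
  expect_identical(m$overrides$EDGE_TARGET_ARROW_SHAPE, "dot")
  expect_identical(m$overrides$EDGE_SOURCE_ARROW_SHAPE, "vee")
  expect_identical(m$overrides$EDGE_UNSELECTED_PAINT, rgba(17, 34, 51, 68))
})

test_that("importing the toy listing builds the expected model", {
  res <- import_document(read_dot(toy_path()))[[1]]
  net <- res$network
  expect_false(net$directed)
  expect_identical(net$name, "toy_example")
  expect_identical(sort(net$nodes$shared_name), c("1", "2", "3", "4"))
  expect_identical(nrow(net$edges), 5L)
  expect_identical(res$style$defaults$NODE_FILL_COLOR, rgba(136, 136, 136))
  expect_identical(res$style$defaults$NODE_LABEL, "\\N")
  expect_identical(res$style$defaults$NODE_TRANSPARENCY, 255)

  suid1 <- net$nodes$suid[net$nodes$shared_name == "1"]
  ov <- cydot:::get_overrides(res$views, "node", suid1)
  expect_identical(ov$NODE_LABEL, "1")
  expect_identical(ov$NODE_HEIGHT, 36)
  expect_identical(ov$NODE_WIDTH, 54)
  expect_equal(ov$NODE_X_POSITION, -58.648)
  expect_equal(ov$NODE_Y_POSITION, 8.4777)

  # weight slots exist for every edge (all empty here)
  expect_identical(nrow(res$network$edge_table), 5L)
  expect_true(all(is.na(res$network$edge_table$weight)))

  # edge pos and the unknown graph attributes are logged, not fatal
  expect_true(all(c("bb", "overlap") %in% res$log$attribute))
  expect_identical(sum(res$log$attribute == "pos"), 5L)
})

test_that("import is total on odd but parseable input", {
  txt <- paste(
    "digraph g {",
    "  rankdir=LR;",
    "  a [penwidth=\"abc\", color=\"red:blue\", shape=cylinder,",
    "     colorscheme=\"accent3\", pos=\"bad\"];",
    "  a -> b [weight=\"heavy\", arrowhead=crow];",
    "}", sep = "\n")
  res <- import_document(parse_dot(txt))[[1]]
  expect_identical(nrow(res$network$nodes), 2L)
  expect_identical(nrow(res$network$edges), 1L)
  expect_true(is.na(res$network$edge_table$weight[1]))
  expect_identical(
    sort(res$log$attribute),
    sort(c("rankdir", "penwidth", "color", "shape", "colorscheme", "pos",
           "weight", "arrowhead")))
})

test_that("an attribute-free graph yields zero overrides", {
  res <- import_document(parse_dot("graph plain { a -- b; c }"))[[1]]
  expect_identical(nrow(res$network$nodes), 3L)
  expect_length(res$views$nodes, 0L)
  expect_length(res$views$edges, 0L)
  expect_identical(nrow(res$log), 0L)
  # seed style untouched for an undirected graph (title aside)
  seed <- cytoscape_default_style()
  seed$defaults$NETWORK_TITLE <- "plain"
  expect_identical(res$style$defaults, seed$defaults)
})

test_that("an empty graph imports as an empty network", {
  res <- import_document(parse_dot("graph {}"))[[1]]
  expect_identical(nrow(res$network$nodes), 0L)
  expect_identical(nrow(res$network$edges), 0L)
})

test_that("directed graphs promote the implicit arrowhead to normal", {
  res <- import_document(parse_dot("digraph g { a -> b }"))[[1]]
  expect_identical(res$style$defaults$EDGE_TARGET_ARROW_SHAPE, "normal")
  expect_identical(res$style$defaults$EDGE_SOURCE_ARROW_SHAPE, "none")
})

test_that("one import result is produced per top-level graph", {
  res <- import_document(parse_dot("graph a { x } digraph b { y -> z }"))
  expect_length(res, 2L)
  expect_identical(res[[1]]$network$name, "a")
  expect_true(res[[2]]$network$directed)
})

test_that("graph-level bgcolor and label reach the network style", {
  txt <- "graph g { bgcolor=\"#10203040\"; label=\"My net\"; a }"
  res <- import_document(parse_dot(txt))[[1]]
  expect_identical(res$style$defaults$NETWORK_BACKGROUND_PAINT,
                   rgba(16, 32, 48, 64))
  expect_identical(res$style$defaults$NETWORK_TITLE, "My net")
})
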