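Package: cydot
Title: Convert Between Graphviz DOT Files and Cytoscape Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bidirectional converter between Graphviz DOT (.dot, .gv) files
    and a Cytoscape-compatible network plus visual-style representation.
    Provides a DOT-language parser and serializer, an attribute importer that
    maps DOT node, edge and style attributes onto Cytoscape visual properties
    (with unit conversion between inches and points and a log of ignored
    attributes), an exporter that writes Cytoscape networks back to DOT with
    configurable edge routing and label placement, Cytoscape.js JSON I/O, a
    deterministic fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
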