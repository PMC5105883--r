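# cydot

Graphviz DOT files (`.dot`, `.gv` — the two extensions are interchangeable)
carry graph topology together with layout and styling: node positions,
shapes, fill and border colors, pen widths, fonts, arrow heads. Cytoscape
and Cytoscape.js represent the same information quite differently, as a
network (nodes, edges, a data table) plus a *visual style* — a table of
default visual-property values — and per-element *view* overrides. Moving a
network between the two worlds by hand, or through an intermediate format
that drops styling, loses exactly the information a figure depends on.

`cydot` is a bidirectional converter between the two representations, for
anyone who lays out networks with Graphviz tools (`dot`, `neato`) and
analyses or restyles them in Cytoscape — or the other way around. It
implements:

* a DOT-language **parser and serializer** (`parse_dot()`,
  `serialize_dot()`): quoted/numeral identifiers, attribute lists, default
  attribute statements (`node [...]`, `edge [...]`), subgraphs, comments,
  edge chains, with structural round-trip identity;
* an **importer** (`import_document()`) that maps DOT attributes onto
  Cytoscape visual properties: `label`/`xlabel` → `NODE_LABEL` (with `\N`
  resolving to the node name), `fillcolor` → `NODE_FILL_COLOR`,
  `penwidth` → border/edge width, `shape` and `arrowhead`/`arrowtail`
  within their supported vocabularies, the `style` keyword list
  (`solid`, `dashed`, `dotted`, `invis`, `rounded`, `filled`), `pos` →
  node coordinates, and the non-visual `weight` attribute into a weight
  column of the edge table. Node sizes convert between DOT inches and
  Cytoscape points at exactly **1 in = 72 pt**; everything unconvertible
  goes into an ignored-attribute log instead of failing;
* an **exporter** (`export_network()`) writing the conventional output:
  fixed header (`bgcolor`, `splines`, `outputorder = "edgesfirst"`,
  `esep = "0"`, `pad = "2"`), `node`/`edge` default statements derived from
  the visual style, per-element statements carrying only deviations,
  `name§SUID` node ids, six-decimal formatting, and the three export
  choices: edge routing (`splines` `"false"`/`"curved"`/`"true"`), node
  label location (`labelloc` or per-node `xlabel`), network label location;
* **Cytoscape.js JSON I/O** (`read_cyjs()`/`write_cyjs()` plus a JSON
  visual-style sidecar), a deterministic DOT **fixture generator**
  (`generate_fixture()`), and a **command line** (`dot_cli()`, installed
  wrapper in `inst/cli/cydot`).

## Worked example

```r
library(cydot)

toy <- system.file("extdata", "toy_example.gv", package = "cydot")
res <- import_document(read_dot(toy))[[1]]
res
#> <cy_import 'toy_example': 4 nodes, 5 edges, 8 ignored attribute(s)>

suid <- res$network$nodes$suid[res$network$nodes$shared_name == "1"]
effective_value(res$style, res$views, "node", suid, "NODE_WIDTH")
#> [1] 54                                # width=0.75 in  ->  54 pt
effective_value(res$style, res$views, "node", suid, "NODE_X_POSITION")
#> [1] -58.648                           # pos passes through in points
format_color(res$style$defaults$NODE_FILL_COLOR)
#> [1] "#888888FF"                       # node default fillcolor="#888888"

head(res$log, 3)                        # what was ignored, and why
#>   element   attribute                         value
#> 1   graph          bb -85.648,-58.068,63.891,73.497
#> 2   graph outputorder                    edgesfirst
#> 3   graph     overlap                         false
#>                                       reason
#> 1 no corresponding Cytoscape visual property
#> 2 no corresponding Cytoscape visual property
#> 3 no corresponding Cytoscape visual property

out <- export_network(res$network, res$style, res$views, export_options())
cat(substr(out$text, 1, 120))
#> graph toy_example {
#> bgcolor = "#FFFFFFFF"
#> splines = "false"
#> outputorder = "edgesfirst"
#> esep = "0"
#> pad = "2"
```

The 8 ignored attributes are the three layout-only graph attributes above
plus the five edge `pos` splines (edges are always re-exported as straight
lines). The exported text ends with statements such as
`"1§4" [label = "1",height = "0.500000",width = "0.750000",pos = "-58.648000,-8.477700"]`
— the original coordinates and sizes restored exactly, with the element
SUID appended to each node name.

From a shell:

```sh
inst/cli/cydot import  inst/extdata/toy_example.gv -o toy.cyjs --style toy-style.json --log toy.log.tsv
inst/cli/cydot export  toy.cyjs --style toy-style.json -o toy.gv --edge-style curved
inst/cli/cydot roundtrip inst/extdata/toy_example.gv
```

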