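---
title: "Converting between Graphviz DOT and Cytoscape network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting between Graphviz DOT and Cytoscape network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cydot)
```

## The two models

A DOT file describes a graph as an ordered list of statements: node and
edge declarations with attribute lists, *default attribute statements*
(`node [...]`, `edge [...]`, `graph [...]`) that apply to subsequently
declared elements, bare `name = value` graph attributes, and subgraphs.
Styling and layout are carried in well-known attributes (`fillcolor`,
`penwidth`, `pos`, `shape`, `style`, ...), with sizes in inches and
positions in points, y axis pointing up.

Cytoscape separates the same information into three layers: a network
(topology plus a data table), a *visual style* holding one default value
per visual property (`NODE_FILL_COLOR`, `EDGE_WIDTH`, ...), and
per-element *views* holding only deviations from the style. `cydot`
mirrors that split: `cy_network`, `cy_visual_style`, and a views container
keyed by SUID (the per-element integer identifier, assigned sequentially
from 1 in an import session).

## Import

`parse_dot()` builds a document model with a hand-written tokenizer and
recursive-descent parser. Normalizations applied at parse time: comments
are discarded; edge chains `a -- b -- c` expand into pairwise edge
statements sharing the chain's attribute list; nodes first referenced by
an edge are implicitly declared (empty attributes) just before that edge;
port/compass suffixes are dropped with a warning; repeated declarations of
one node merge attributes with last-wins. HTML-like labels (`label=<...>`)
raise a distinct condition class (`dot_html_error`) — they have no
counterpart on the Cytoscape side.

Attribute resolution follows standard DOT scoping with one restriction:
**only default statements in the root graph participate**, applied in
document order before the element's own attributes. Defaults inside
subgraphs are parsed but ignored for resolution. A default written after
an element does not reach it; this document-order rule is ordinary
Graphviz semantics and is the package's choice where the interchange
convention is silent.

`import_document()` then

1. seeds the visual style (see below), promoting the target-arrow default
   to `normal` for digraphs (DOT's implicit arrowhead);
2. folds root default statements and top-level graph attributes
   (`bgcolor`, `label`) into the style defaults;
3. maps each element's resolved attributes through the conversion tables
   and stores as view overrides only values that differ from the style —
   so an attribute-free graph imports with zero overrides;
4. parses `weight` into the edge table's weight column (it has no visual
   property), and appends every unconvertible or unknown attribute to an
   ignored-attribute log (element, attribute, value, reason). Import never
   fails on a parseable document.

Unit handling: node `height`/`width` convert at exactly 1 in = 72 pt,
both directions. `fontsize` and `penwidth` are already in points and pass
through 1:1. Node `pos` passes through unscaled, but the y coordinate is
negated: stored coordinates follow the downward y axis used by
Cytoscape(.js), DOT's y axis points up, and negation is its own inverse,
so a re-exported file restores the original `pos` strings exactly. Edge
`pos` (spline control points) is ignored with a log entry — edges are
always straight lines in this model.

Color values accept `#RRGGBB`, `#RRGGBBAA`, and X11 names (matched
case-insensitively through R's color table, which is X11-derived). Color
lists (`a:b`, Graphviz's parallel/segmented edge paint), HSV triples, and
brewer-scheme references have no single-color equivalent and are logged.
When `filled` appears together with an explicit fill alpha, the channel
alpha wins; `filled` itself maps to full opacity (`NODE_TRANSPARENCY`
255), its absence to 0, which keeps unfilled DOT nodes hollow.

## The seed style

The style a freshly imported network starts from is
`cytoscape_default_style()`: rounded rectangles of 35 pt × 75 pt with no
border ink, light-blue fill, SansSerif 12 pt labels, 2 pt dark-grey edges
without arrows. These are the values a stock Cytoscape session applies
before any file defaults override them, and they are what the
conventional exported header and default statements advertise — including
the familiar size strings `"0.486111"`/`"1.041667"` (35 pt and 75 pt in
inches). Seeding with these values is what makes import → export
reproduce the reference listings token for token.

`dot_implicit_style()` — ellipses, 0.5 in × 0.75 in, Times-Roman 14 pt,
light-grey fill when filled — is also provided and can be passed as
`seed_style` when Graphviz-faithful defaults matter more than Cytoscape
conventions. The choice is a genuine design fork: the interchange
convention documents both value sets, and the exporter's output format is
anchored to the Cytoscape-session set, so that is the default.

One related constant: the edge default statement always writes
`color = "#848484FF"` (Cytoscape's stock edge *stroke* paint) while the
style's effective edge paint defaults to `#404040FF` (the *unselected*
paint). Each edge whose effective paint differs from the declared constant
— including every edge of a plain import — therefore carries its own
`color` attribute, which is exactly the convention of the reference
output.

## Export

`export_network()` writes, in order: the header block (`bgcolor`,
`splines`, `outputorder = "edgesfirst"`, `esep = "0"`, `pad = "2"`, and
optionally the network `label`/`labelloc`); one `node [...]` and one
`edge [...]` default statement derived from the style; node statements;
edge statements. Conventions:

* **Minimality** — element statements carry only attributes whose
  effective value deviates from the declared defaults, in a fixed order
  (`label`, `penwidth`, `height`, `width`, `pos`, `color`, then the
  remaining attributes), so output is deterministic and golden-testable.
* **Composite values** — the node `style` keyword list is rebuilt from
  several properties in fixed order: line type, `rounded` (only for
  round-rectangles, whose `shape` prints as `rectangle`), `invis` when
  hidden, `filled` when transparency is above zero.
* **Ids** — node ids are `name§SUID` composites; the serializer quotes any
  identifier containing characters outside `[A-Za-z0-9_]`. Reals print
  with six decimals; colors as uppercase `#RRGGBBAA`; font sizes as the
  shortest exact decimal.
* **Directedness** — undirected networks use `--` with
  `arrowhead`/`arrowtail` `"none"` and `dir = "both"` in the edge
  defaults; digraphs use `->` with the style's arrow defaults.
* **Element order** — newest-first (descending creation order), matching
  the conventional output of the reference implementation.
* **Options** — the three export choices map to `splines`
  (`"false"`/`"curved"`/`"true"`), to `labelloc` in the node defaults (or
  per-node `xlabel` for external labels, applied globally), and to the
  graph `label`/`labelloc` pair. `fixedsize = "true"` is always written so
  Graphviz honors the exported sizes. A 2-inch pad keeps labels from being
  clipped.

What DOT cannot carry is reported in `$warnings` rather than silently
dropped; with this model that is chiefly the edge table (including the
imported weight column).

## Cytoscape.js JSON and the style sidecar

`.cyjs` files store topology, data and positions but no style, so the
visual style travels in a JSON sidecar (`{"defaults": {...}}`, colors as
hex strings) and per-element visual overrides are embedded in a `view`
object on each element. This keeps write → read an identity on the model
while remaining ordinary Cytoscape.js JSON for consumers that ignore
unknown keys. Schema violations are reported with the JSON path of the
offending element (e.g. `$.elements.nodes[3].data.id`).

## The fixture generator

`generate_fixture()` emits random DOT files restricted to the supported
vocabulary: supported shapes and arrow heads (including the
`rect`/`box`/`Msquare`-style aliases), hex and X11 colors, the supported
style keywords (`rounded` only on rectangle-family shapes), positions,
sizes, pen widths, fonts, labels, tooltips, weights, and occasional root
default statements; roughly a quarter of node names contain a space to
exercise quoting. Generation is deterministic per seed and restores the
caller's RNG state.

That restriction is deliberate: fixtures are closed under the supported
subset, so importing one must produce an *empty* ignored-attribute log,
and round-trip properties test the converter rather than the fallback
rules. What the generator does **not** emulate: HTML labels, record
labels, clusters, edge splines, color lists, brewer schemes, gradients,
multi-edges, self-loops, and subgraph structure. Tests passing on
fixtures therefore say nothing about those features beyond the explicit
fallback tests (ignore + log, or a classed parse error).

Test problem sizes, chosen to keep the suite fast while covering the
combinatorics: parse/serialize identity on 100 documents of 3–10 nodes;
import/export model equivalence on 100 networks of 3–8 nodes (positions
compared to 1e-3 pt, sizes to 1e-4 pt, colors and vocabularies exactly);
independent mini-parser agreement on 50 fixtures; 10 igraph-written files
for the parser cross-check.

## Numerical and degenerate-input choices

* Override-vs-default comparison uses an absolute 1e-9 tolerance for
  numerics and exact equality for colors and vocabulary values.
* Six-decimal formatting means a re-imported default height of
  `"0.486111"` is 34.999992 pt, not 35 pt; round-trip comparisons use the
  tolerances above rather than exact float identity.
* Degenerate inputs: empty graphs parse, import (0 nodes) and export
  (header plus defaults only); the empty string is a legal quoted node
  id; duplicate style keywords resolve last-wins; a malformed `pos` or
  non-numeric `penwidth` is logged, never fatal.
* `strict` is parsed and preserved but has no conversion effect;
  multi-edges are not deduplicated.

## Known limitations

Layout is never computed — positions are copied, so a file without `pos`
imports with no coordinates. Cluster semantics, record sectioning, per-
subgraph defaults, edge spline geometry, gradients and parallel-edge
color lists are out of scope by design; each falls back to ignore-and-log.
On export, node names containing a literal `§` would collide with the
`name§SUID` convention when re-imported names are compared after
stripping the suffix. The X11 name table is R's color set; the handful of
Graphviz X11 names absent from it fall back to the log.
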