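Package: expgraph
Title: Capture, Annotate and Export Laboratory Experiment Metadata as Provenance Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Records a laboratory experiment as a typed provenance graph
    (biosources, containers and assays linked by protocol applications),
    annotates nodes and arcs with terms from OBO-format ontologies via a
    ranked lookup service and a whole-graph 'terminize' traversal, manages
    immutable protocols with searchable comments and minimum-information
    technology templates, enforces object-level access control with
    private-by-default investigations and read-only or full access groups,
    and exports studies as structurally validated ISA-Tab bundles and
    human-readable reports. Includes seedable synthetic fixture generators
    and a command-line interface over a versioned JSON store.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
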