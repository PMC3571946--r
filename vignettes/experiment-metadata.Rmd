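---
title: "Capturing laboratory experiments as typed provenance graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capturing laboratory experiments as typed provenance graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expgraph)
```

## The problem

Multi-modality biological experiments — a transcriptomics run here, a batch
of microscopy images there, all derived from the same animals and cultures —
are routinely deposited with minimal annotation, because describing them in
the required standards (ISA-Tab, MIAME-style minimum-information checklists,
a zoo of ontologies) is tedious for the bench scientist. `expgraph` models
the experiment the way the scientist thinks about it: as a provenance graph
in which nodes are physical things (raw biological **biosources**,
laboratory **containers**, measurement **assays**) and arcs are the actions
that connect them (extraction, aliquoting, pooling, measuring), each action
optionally carrying a registered laboratory protocol. Everything else —
ontology annotation, minimum-information capture, access control, ISA-Tab
export — hangs off that graph.

## The graph model and its typing rules

An `Investigation` is the root container: it owns a list of studies, a fixed
set of ontology sources, and its own automatically created access group. A
`Study` is one experiment: a weakly connected, acyclic graph with a single
root node representing the study as a whole. The typing rules are strict and
enforced at construction time:

| parent     | allowed children        |
|------------|-------------------------|
| root       | biosource               |
| biosource  | container               |
| container  | container, assay        |
| assay      | — (assays are sinks)    |

Arcs out of the root carry no protocol application — they represent the
inclusion of a biosource in the study, not a laboratory action. Splitting a
sample is simply repeated `add_child()` on one container; pooling
(`pool()`) gives the pooled child one incoming arc per parent. We allow
pooling into a container or directly into a jointly measured assay, but a
biosource always has exactly one parent (the root): `validate_graph()`
flags multi-parent biosources as `MULTIPARENT_KIND`. `validate_graph()`
re-checks all invariants as a batch (codes `UNIQUE_ROOT`, `ILLEGAL_CHILD`,
`CYCLE`, `DISCONNECTED`, `ROOT_ARC_PROTOCOL`, `MULTIPARENT_KIND`) so that
graphs arriving from outside the constructors — a hand-edited store file,
an imported bundle — can be rejected before export.

Deletion is conservative: removing a node with children requires an
explicit `cascade = TRUE`, which then also prunes every node left
unreachable from the root. An implicit cascade would make a mis-click
destroy a subtree silently; an orphaned subtree would violate
connectivity. Bulk operations (`bulk_add_children()`, `bulk_edit()`) are
deliberately restricted to selections of a single node kind — mixed
selections almost always indicate a selection mistake, and the kind
determines which children/fields are legal. `bulk_edit()` replaces an
existing annotation of the same name (first occurrence) rather than
appending a duplicate, matching the "alter the properties of the selected
items" intent; plain `annotate()` appends, since repeated name/value pairs
are legal and order-preserving.

Node and arc identifiers are deterministic per-study counters (`n1`,
`n2`, …, `a1`, …) and investigation ids are slugified titles. Random ids
would work equally well, but deterministic ids make stores, exports and
test fixtures byte-reproducible, which is the foundation of every
determinism guarantee below.

## Ontology lookup

`load_obo()` parses OBO 1.2 flat files, reading only the tags a lookup
service needs (`id`, `name`, `synonym`, `def`, `is_obsolete`, `alt_id`,
`namespace`); typedefs and cross-products are ignored because the service
does lookup, not reasoning. Obsolete terms stay in the index but are
excluded from results unless `include_obsolete = TRUE`, the standard OBO
convention.

Matching is deliberately lexical and fully deterministic, so that an
independent brute-force scan can verify every ranking. Case-insensitive
match classes, best class wins per term:

* `exact_name` (score 1.0) — query equals the term name;
* `exact_synonym` (0.9) — query equals any synonym;
* `token` (0.7) — every whitespace token of the query occurs as a whole
  token of the name or a synonym;
* `substring` (0.5) — query is a contiguous substring.

Ties are broken by accession ascending, which makes result order total and
stable; increasing the `limit` therefore only extends the result prefix.
The scores are rank separators, not probabilities — any strictly
decreasing assignment would behave identically. No embedding or semantic
similarity is attempted: for short laboratory strings ("chicken", "RNA
extract") exact and token matching against names and curated synonyms is
both predictable and auditable, and a synonym-aware exact match is how a
curator would resolve these strings anyway.

`terminize()` walks the study breadth-first from the root (children in arc
insertion order, a node's incoming arcs directly after the node) and
submits every node label, annotation name, annotation value and
protocol-application deviation text to the search, recording candidates
for every field — including empty candidate lists, so the report doubles
as an inventory of the annotatable surface. Attachment is explicit and
idempotent (`attach_term()`), and only terms from the investigation's
declared ontology sources may be attached: a fixed per-investigation
source list is what keeps annotation consistent across studies. We scan
only graph-resident text, not protocol bodies: protocol text is shared
across experiments and would produce the same candidates for every study.

## Protocols, templates, minimum information

Protocol text is immutable from the moment of registration (the binding is
locked; `set_protocol_text()` exists only to refuse). The remedy for a
deviation is the `action` field of the protocol application on the arc
where the deviation happened — the protocol stays a truthful record of the
written method. "Editing" is registering a new protocol under a new id; no
version chain is kept, because the deviation field, not versioning, is the
model's change mechanism. Comments are append-only, timestamped
(injectable timestamps keep records reproducible) and searched together
with the body by case-insensitive substring; search results are filtered
by readability, so a private protocol is invisible rather than forbidden.

Technology templates capture per-technology minimum information as ordered
required/optional fields; a completed template (one concrete platform) can
be associated with many data files in one call.
`compile_minimum_info()` merges a biosource's MIABS fields (species,
strain, genetic modification and the like — the set is extensible) with
the completed template's values, prefixing the latter with `tech:` so the
two key sets cannot collide and the merge stays lossless. No published
checklist is hard-coded: MIABS is a minimal technology-independent field
set, not an implementation of MIAME/MIAPE item lists.

## Access control

Every securable object (investigation, study, protocol) is private by
default: only its creator can read, write or delete. Sharing happens by
granting an access group `read_only` (read) or `full` (read, write,
delete) on the object. Each investigation gets its own group at creation,
initially containing only the owner; objects inside an investigation
honour the investigation's grants in addition to their own (union
semantics — an object-level grant can widen but never narrow inherited
access, which is the least surprising interaction and keeps revocation
exact: removing a grant restores precisely the prior matrix). Only holders
of full permission administer grants. User identities are trusted inputs;
authentication and session management are out of scope.

## ISA-Tab dialect

`export_isatab()` writes one investigation file, one sample/study file per
study and one assay file per (study, modality). The study file has one
data row per distinct root → assay-input path, where an assay-input is a
container feeding at least one assay; this makes pooled containers repeat
their Sample Name across their parents' rows and splits repeat the Source
Name, which is exactly how ISA-Tab expresses pooling and splitting. The
row-count law (rows = number of such paths) is verified against an
independent path enumerator in the tests.

Mapping choices where ISA-Tab leaves room:

* the terminal container is the `Sample Name`; intermediate containers on
  longer chains are emitted as their `Protocol REF` step followed by
  `Comment[Sample Name]` and `Comment[Characteristics[...]]` columns, so
  their labels and annotations survive the round trip without breaking the
  one-sample-column convention;
* node annotations become `Characteristics[name]` columns (insertion
  order); when a term is attached, `Term Source REF` and `Term Accession
  Number` columns follow. One term pair is emitted per characteristic (the
  first attached term) and only for biosources and terminal containers —
  terms on intermediate-container annotations and second-and-later terms
  are a documented limitation of the tabular form;
* protocol parameters become `Parameter Value[name]` columns after their
  `Protocol REF`; deviation text, performer and date have no ISA-Tab slot
  and are not exported (they live in the expgraph-1 store);
* rows are sorted in lexicographic path order, files are UTF-8 with LF
  endings, so identical inputs export byte-identically.

`import_isatab()` reads this dialect back (merging nodes by label within a
study) and is the round-trip oracle: for every generated fixture,
`import(export(G))` preserves the multiset of root-to-assay paths with
labels, annotations, attached terms, protocol names and parameters —
`study_paths()` renders both sides canonically for comparison. Protocol
bodies are not part of ISA-Tab, so imported protocols carry placeholder
text under their original names. `validate_isatab()` implements the core
structural rules (section order, declared files present, `Protocol REF`
and `Term Source REF` declared, assay samples known to their study file)
as an in-package check with machine-readable violation codes; it is a
structural subset of the full standard's rule set, sufficient for the
exporter's contract, not a replacement for a community validator.

## Synthetic fixtures

`generate_fixture_graph()` is first-class, tested code; its defaults are
the study conditions the rest of the package is exercised under, chosen
once to mirror the worked example: 4 biosources, a 30% pooling and 30%
split probability, chains up to depth 4 (root, biosource, container,
assay) by default, two assay modalities (sequencing and imaging), species
and strain annotations with ontology terms on ~80% of species values, and
a protocol with parameters on every non-root arc. Labels are unique per
study and annotation names unique per node, which real notebooks
approximate but do not guarantee; the generator also never produces
assay-less dangling containers, tab characters in labels, conflicting
annotations for merged pooled rows, or multiple terms per annotation.
Passing round-trip tests on these fixtures therefore demonstrates the
exporter/importer on clean, well-labelled studies — not robustness to
degenerate labelling, which the importer does not claim.

`generate_toy_obo()` emits deterministic OBO files from a small controlled
vocabulary (adjective + noun phrases, EXACT synonyms at a configurable
rate, ~2% obsolete terms); `demo_study()` and `write_demo_obo()` build the
canonical worked example: one chicken split into two petri dishes feeding
imaging assays, three bacterial replicate cultures pooled into one
eppendorf tube feeding a sequencing assay.

## Problem sizes and numerical choices

The shipped checks run 1000 random construction sequences, single-edit
corruption sweeps over 100 graphs against an independent brute-force
invariant checker, 100 export/import round trips, and search-oracle
comparisons on a 10,000-term ontology with 1000 queries — sizes at which
the properties are exercised densely while the whole suite stays fast on
one CPU; the acceptance script re-derives the same quantities at
moderately smaller sizes (stated in its output's `n` fields). There is no
floating-point tolerance anywhere: every comparison in the package is on
exact strings, counts and byte streams. Tie-breaks are always lexical
(accession ascending in search, label order in export rows, name order in
protocol search) so that no result depends on hash or insertion order.

## Known limitations

* The ISA-Tab dialect is self-consistent and structurally valid but not
  guaranteed to round-trip third-party bundles; `import_isatab()` reads
  the package's own output.
* Ontology matching is lexical; misspelled annotations find nothing.
* Labels act as merge keys on import: two different containers with the
  same label in the same study would be merged (the generator and the
  constructors do not prevent duplicate labels — exporting such a study is
  the user's risk).
* No authentication, sessions, or external repository links beyond an
  opaque `external_link` field on assays.
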