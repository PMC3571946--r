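# expgraph

Capture, annotate and export laboratory experiment metadata as typed
provenance graphs.

`expgraph` is for the bench scientist (and the data manager standing behind
them) who needs multi-modality experiments — sequencing runs, microscopy
images, mass-spectrometry data derived from the same animals and cultures —
described well enough to analyse, share and deposit, without hand-editing
ISA-Tab files or hunting through ontology browsers. It models an experiment
the way it happens in the lab and generates the standards artefacts from
that model.

The core is a typed provenance graph per study. Nodes are physical
entities of three kinds — **biosources** *B* (raw biological input),
**containers** *C* (tubes, dishes, flasks) and **assays** *A* (measurement
events) — under a single root *r* representing the study. Arcs are
laboratory actions, each optionally carrying an immutable registered
protocol *P* plus a free-text deviation record. The only legal arc kinds
are *r→B*, *B→C*, *C→C* and *C→A*; splitting is multiple children of one
container, pooling gives a container (or assay) several parents. On top of
the graph sit:

* an **ontology service**: OBO files indexed for ranked, deterministic
  lexical lookup (exact name > exact synonym > token > substring, scores
  1.0/0.9/0.7/0.5), and a `terminize()` traversal that proposes candidate
  terms for every text field of a study;
* **protocols and templates**: immutable protocol bodies with append-only
  searchable comments, and technology templates compiled with per-sample
  MIABS fields into minimum-information records;
* **object-level access control**: everything private to its creator by
  default, shared via access groups at `read_only` or `full` level, with
  investigation-level grants inherited by contained objects;
* **exporters**: structurally validated ISA-Tab bundles (with an importer
  used as the round-trip oracle), plus plain-text/HTML study and protocol
  reports;
* **fixtures and a CLI**: seedable generators for study graphs and toy
  ontologies, the canonical demo study, and an `expgraph` command-line
  tool over a versioned JSON store (`expgraph-1`).

## Worked example

The canonical demo study: one chicken split into two petri dishes feeding
imaging assays, three bacterial replicate cultures pooled into one
eppendorf tube feeding a sequencing assay.

```r
library(expgraph)

st <- demo_study()
st
#> <study 'Infection time course' (s1): 4 biosource, 3 container, 3 assay node(s), 12 arc(s)>

nrow(validate_graph(st))          # structural violations
#> [1] 0

obo <- tempfile(fileext = ".obo")
write_demo_obo(obo)
idx <- load_obo(obo, source = "TOY")
search_terms(idx, "chicken")
#>     query   accession          name source    match_type score
#> 1 chicken TOY:0000001 Gallus gallus    TOY exact_synonym   0.9

terminize(st, idx)
#> <terminize report for study 's1': 33 field(s) scanned, 7 with candidates>

export_isatab(st$investigation, "isa_demo")
list.files("isa_demo")
#> [1] "a_s1_imaging.txt"            "a_s1_sequencing.txt"
#> [3] "i_chick_infection_study.txt" "s_s1.txt"
nrow(validate_isatab("isa_demo"))
#> [1] 0

cat(head(export_study_report(st$investigation, st), 9), sep = "\n")
#> STUDY REPORT: Infection time course
#> Investigation: Chick infection study
#> Study id: s1
#>
#> Items (10):
#>   - [biosource] chicken
#>       species = Gallus gallus [TOY:0000001]
#>       miabs:species = Gallus gallus
#>       miabs:age = 21 days
```

The study file `s_s1.txt` has five data rows — one per root→sample path:
two splits repeating the chicken as `Source Name`, three pooled rows
sharing the eppendorf tube as `Sample Name`. `import_isatab("isa_demo")`
rebuilds an equivalent investigation; `study_paths()` renders both sides
canonically if you want to compare them yourself.

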