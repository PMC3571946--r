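# OBO parsing, ranked search, term attachment and the terminize traversal.

local_demo_index <- function() {
  p <- tempfile(fileext = ".obo")
  write_demo_obo(p)
  load_obo(p, source = "TOY")
}

test_that("load_obo indexes term stanzas and flags obsolete terms", {
  p <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:1", "name: alpha cell",
    "synonym: \"first cell\" EXACT []", "",
    "[Term]", "id: T:2", "name: beta cell", "is_obsolete: true", "",
    "[Typedef]", "id: part_of", "name: part of", "",
    "[Term]", "id: T:3", "name: gamma tissue",
    "def: \"A tissue.\" [PMID:1]", ""
  ), p)
  idx <- load_obo(p, source = "T")
  expect_identical(idx$term_count, 3L)
  expect_identical(idx$synonyms[[1]][[1]]$scope, "EXACT")
  expect_identical(idx$definition[[3]], "A tissue.")
  expect_true(idx$obsolete[[2]])

  # obsolete excluded by default, included on request
  expect_identical(nrow(search_terms(idx, "beta cell")), 0L)
  expect_identical(search_terms(idx, "beta cell", include_obsolete = TRUE)$accession,
                   "T:2")
})

test_that("stanzas without id or name raise a ParseError naming the line", {
  p <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: T:1", "name: ok", "", "[Term]", "name: no id"), p)
  err <- tryCatch(load_obo(p), condition = identity)
  expect_s3_class(err, "ParseError")
  expect_identical(err$line, 5L)
  expect_error(load_obo(tempfile()), class = "IOError")
})

test_that("search ranks exact name above synonym, token and substring matches", {
  idx <- local_demo_index()
  r <- search_terms(idx, "Gallus gallus")
  expect_identical(r$match_type[[1]], "exact_name")
  expect_identical(r$score[[1]], 1.0)
  expect_identical(r$accession[[1]], "TOY:0000001")

  expect_identical(search_terms(idx, "chicken")$match_type, "exact_synonym")
  expect_identical(search_terms(idx, "gallus")$match_type, "token")
  r_sub <- search_terms(idx, "eppend")
  expect_identical(r_sub$match_type, "substring")

  expect_identical(nrow(search_terms(idx, "")), 0L)
  expect_identical(nrow(search_terms(idx, "   ")), 0L)
  expect_error(search_terms(idx, "x", limit = 0), class = "InvalidLimit")
  expect_error(search_terms(idx, "x", sources = "ZZZ"), class = "NoSuchSource")
})

test_that("search equals the per-term brute-force oracle on a toy corpus", {
  p <- tempfile(fileext = ".obo")
  generate_toy_obo(p, seed = 11, n_terms = 400, synonym_rate = 0.4,
                   obsolete_rate = 0.05)
  idx <- load_obo(p, source = "TOY")
  queries <- random_queries(idx, 60, seed = 12)
  for (q in queries) {
    expect_identical(search_terms(idx, q, limit = 15), bf_search(idx, q, limit = 15),
                     info = paste("query:", q))
  }
})

test_that("increasing the limit extends but never reorders the result prefix", {
  p <- tempfile(fileext = ".obo")
  generate_toy_obo(p, seed = 21, n_terms = 300, synonym_rate = 0.5)
  idx <- load_obo(p, source = "TOY")
  for (q in random_queries(idx, 15, seed = 22)) {
    small <- search_terms(idx, q, limit = 3)
    big <- search_terms(idx, q, limit = 50)
    expect_identical(small, head(big, nrow(small)))
  }
})

test_that("source restriction returns only terms of the named sources", {
  p1 <- tempfile(fileext = ".obo"); generate_toy_obo(p1, seed = 1, n_terms = 80)
  p2 <- tempfile(fileext = ".obo"); generate_toy_obo(p2, seed = 2, n_terms = 80,
                                                     source = "ALT")
  idx <- merge_indexes(load_obo(p1, source = "TOY"), load_obo(p2, source = "ALT"))
  expect_identical(idx$term_count, 160L)
  for (q in c("tissue", "cell", "culture sample")) {
    r <- search_terms(idx, q, sources = "ALT")
    expect_true(all(r$source == "ALT"))
    expect_identical(r, bf_search(idx, q, sources = "ALT"))
  }
})

test_that("attach_term is idempotent and refuses undeclared sources", {
  st <- demo_study()
  chicken <- names(Filter(function(n) n$label == "chicken", st$nodes))
  t1 <- ontology_term("TOY:0000001", "Gallus gallus", "TOY")

  attach_term(st, chicken, "species", t1)
  attach_term(st, chicken, "species", t1)
  ann <- get_node(st, chicken)$annotations[[1]]
  expect_length(ann$value_terms, 1)

  expect_error(attach_term(st, chicken, "species",
                           ontology_term("X:1", "x", "UNDECLARED")),
               class = "SourceNotRegistered")
  expect_error(attach_term(st, chicken, "nonexistent", t1),
               class = "NoSuchAnnotation")

  # a search-result row is accepted directly
  idx <- local_demo_index()
  attach_term(st, chicken, "species", search_terms(idx, "chicken"), slot = "name")
  expect_length(get_node(st, chicken)$annotations[[1]]$name_terms, 1)
})

test_that("terminize covers every annotatable field exactly once", {
  st <- demo_study()
  idx <- local_demo_index()
  rep <- terminize(st, idx)

  # expected multiset of (entity, field) keys, built structurally
  expected <- character(0)
  for (id in names(st$nodes)) {
    n <- st$nodes[[id]]
    expected <- c(expected, paste(id, "label"))
    for (i in seq_along(n$annotations)) {
      expected <- c(expected, paste(id, sprintf("annotation[%d].name", i)),
                    paste(id, sprintf("annotation[%d].value", i)))
    }
  }
  for (a in st$arcs) {
    if (!is.null(a$protocol_application)) {
      expected <- c(expected, paste(a$id, "protocol_application.action"))
    }
  }
  got <- vapply(rep$entries, function(e) paste(e$entity_id, e$field), character(1))
  expect_identical(sort(got), sort(expected))

  # every query text appears verbatim in the graph; the chicken label's top
  # match is the species term via its synonym
  chicken_entry <- Filter(function(e) e$field == "label" && e$query == "chicken",
                          rep$entries)
  expect_length(chicken_entry, 1)
  expect_identical(chicken_entry[[1]]$matches$accession[[1]], "TOY:0000001")

  # candidates agree with a direct search on the same field text
  for (e in rep$entries[1:10]) {
    expect_identical(e$matches, search_terms(idx, e$query, limit = 10))
  }
})

test_that("terminize on a bare study yields no candidate lists and is deterministic", {
  inv <- make_inv()
  st <- add_study(inv, "Empty-ish")
  idx <- local_demo_index()
  rep <- terminize(st, idx)
  expect_true(all(vapply(rep$entries, function(e) nrow(e$matches) == 0L, logical(1))))

  st2 <- demo_study()
  expect_identical(lookup_json(terminize(st2, idx)), lookup_json(terminize(st2, idx)))
})

test_that("the JSON adapter exposes the documented response schema", {
  idx <- local_demo_index()
  j <- jsonlite::fromJSON(lookup_json(search_terms(idx, "chicken")),
                          simplifyVector = FALSE)
  expect_named(j, c("query", "matches"))
  expect_named(j$matches[[1]],
               c("accession", "name", "source", "match_type", "score"))
})
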