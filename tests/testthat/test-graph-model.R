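# Graph model: construction constraints, shortcuts, validation.

test_that("investigation creation enforces its contract", {
  alice <- xr_user("alice")
  inv <- create_investigation("Chick infection study",
                              list(ontology_source("TOY")), alice)
  expect_length(inv$ontology_sources, 1)
  expect_identical(inv$access_group$members, "alice")
  expect_length(inv$studies, 0)

  expect_s3_class(create_investigation("X", list(), alice), "xr_investigation")
  expect_error(
    create_investigation("X", list(ontology_source("A"), ontology_source("A")), alice),
    class = "DuplicateOntologySource"
  )
  expect_error(create_investigation("  ", list(), alice), class = "InvalidTitle")
})

test_that("a new study is a bare root and study ids are distinct", {
  inv <- make_inv()
  s1 <- add_study(inv, "Study 1")
  expect_length(s1$nodes, 1)
  expect_identical(s1$nodes[[s1$root_id]]$kind, "root")
  expect_length(s1$arcs, 0)
  s2 <- add_study(inv, "Study 2")
  expect_length(inv$studies, 2)
  expect_false(identical(s1$id, s2$id))
})

test_that("users without write permission cannot add studies", {
  inv <- make_inv()
  expect_error(add_study(inv, "S", user = "bob"), class = "AccessDenied")
})

test_that("add_child follows the typing table", {
  st <- make_study()
  b <- add_child(st, st$root_id, "biosource", "chicken")
  expect_identical(b$kind, "biosource")
  expect_length(st$arcs, 1)
  expect_identical(st$arcs[[1]]$parent_id, st$root_id)

  expect_error(add_child(st, b$id, "assay", "seq"), class = "IllegalChildKind")
  expect_error(add_child(st, b$id, "biosource", "x"), class = "IllegalChildKind")
  expect_error(add_child(st, st$root_id, "container", "x"), class = "IllegalChildKind")
  expect_error(add_child(st, "nope", "container", "x"), class = "NoSuchNode")

  ct <- add_child(st, b$id, "container", "tube")
  aliquot <- add_child(st, ct$id, "container", "aliquot")
  expect_identical(aliquot$kind, "container")
  assay <- add_child(st, ct$id, "assay", "seq", modality = "sequencing")
  expect_identical(assay$modality, "sequencing")
  expect_error(add_child(st, assay$id, "container", "x"), class = "IllegalChildKind")
  expect_identical(nrow(validate_graph(st)), 0L)
})

test_that("pooling needs >= 2 same-kind parents and yields one multi-parent child", {
  st <- make_study()
  bios <- vapply(1:3, function(i) {
    add_child(st, st$root_id, "biosource", paste0("b", i))$id
  }, character(1))
  c1 <- add_child(st, bios[[1]], "container", "c1")

  node <- pool(st, bios, "container", "eppendorf")
  incoming <- Filter(function(a) a$child_id == node$id, st$arcs)
  expect_length(incoming, 3)
  expect_identical(nrow(validate_graph(st)), 0L)

  expect_error(pool(st, c(bios[[1]], c1$id), "container", "x"),
               class = "MixedSelection")
  expect_error(pool(st, bios[[1]], "container", "x"), class = "PoolArityError")
  expect_error(pool(st, bios[1:2], "assay", "x"), class = "IllegalChildKind")
})

test_that("bulk_add_children matches repeated add_child and labels children", {
  st <- make_study()
  bios <- vapply(1:3, function(i) {
    add_child(st, st$root_id, "biosource", paste0("b", i))$id
  }, character(1))
  kids <- bulk_add_children(st, bios, "container", "dish_")
  expect_length(kids, 3)
  expect_identical(vapply(kids, `[[`, character(1), "label"),
                   c("dish_1", "dish_2", "dish_3"))

  # oracle equivalence: same multiset of (parent kind, child kind, count)
  st2 <- make_study()
  bios2 <- vapply(1:3, function(i) {
    add_child(st2, st2$root_id, "biosource", paste0("b", i))$id
  }, character(1))
  for (i in seq_along(bios2)) add_child(st2, bios2[[i]], "container", paste0("dish_", i))
  sig <- function(s) {
    sort(vapply(s$arcs, function(a) {
      paste(s$nodes[[a$parent_id]]$kind, s$nodes[[a$child_id]]$label)
    }, character(1)))
  }
  expect_identical(sig(st), sig(st2))

  c1 <- add_child(st, bios[[1]], "container", "cX")
  expect_error(bulk_add_children(st, c(bios[[1]], c1$id), "container", "x"),
               class = "MixedSelection")
  expect_length(bulk_add_children(st, bios[[1]], "container", "y"), 1)
  expect_identical(bulk_add_children(st, character(0), "container", "z"), list())
})

test_that("duplicate_biosource deep-copies annotation under a fresh identity", {
  st <- make_study()
  b <- add_child(st, st$root_id, "biosource", "b1")
  annotate(st, b$id, "species", "E. coli")
  annotate(st, b$id, "strain", "K-12")
  set_miabs(st, b$id, "species", "E. coli")

  copy <- duplicate_biosource(st, b$id)
  expect_false(identical(copy$id, b$id))
  expect_identical(copy$annotations, get_node(st, b$id)$annotations)
  expect_identical(copy$miabs, get_node(st, b$id)$miabs)

  # mutating the copy leaves the original untouched
  bulk_edit(st, copy$id, "strain", "B")
  expect_identical(get_node(st, b$id)$annotations[[2]]$value, "K-12")
  expect_identical(get_node(st, copy$id)$annotations[[2]]$value, "B")

  ct <- add_child(st, b$id, "container", "c1")
  expect_error(duplicate_biosource(st, ct$id), class = "KindError")
  expect_identical(nrow(validate_graph(st)), 0L)
})

test_that("bulk_edit replaces by name or appends, across a same-kind selection", {
  st <- make_study()
  bios <- vapply(1:3, function(i) {
    add_child(st, st$root_id, "biosource", paste0("b", i))$id
  }, character(1))
  annotate(st, bios[[1]], "growth_temp", "30C")

  expect_identical(bulk_edit(st, bios, "growth_temp", "37C"), 3L)
  for (b in bios) {
    anns <- get_node(st, b)$annotations
    hits <- Filter(function(a) a$name == "growth_temp", anns)
    expect_length(hits, 1)
    expect_identical(hits[[1]]$value, "37C")
  }

  c1 <- add_child(st, bios[[1]], "container", "c1")
  expect_error(bulk_edit(st, c(bios[[1]], c1$id), "x", "y"), class = "MixedSelection")
  expect_identical(bulk_edit(st, character(0), "x", "y"), 0L)
})

test_that("protocol applications attach to non-root arcs only and replace on re-apply", {
  st <- make_study()
  prs <- make_registry_with("RNA extraction", "second protocol")
  b <- add_child(st, st$root_id, "biosource", "b1")
  ct <- add_child(st, b$id, "container", "c1")
  root_arc <- Filter(function(a) a$parent_id == st$root_id, st$arcs)[[1]]
  work_arc <- Filter(function(a) a$parent_id == b$id, st$arcs)[[1]]

  apply_protocol(st, work_arc$id, prs$protocols[["RNA extraction"]],
                 action = "incubated 5 min longer")
  pa <- get_arc(st, work_arc$id)$protocol_application
  expect_identical(pa$protocol_name, "RNA extraction")
  expect_identical(pa$action, "incubated 5 min longer")

  apply_protocol(st, work_arc$id, prs$protocols[["second protocol"]])
  expect_identical(get_arc(st, work_arc$id)$protocol_application$protocol_name,
                   "second protocol")

  expect_error(apply_protocol(st, root_arc$id, prs$protocols[[1]]),
               class = "RootArcError")
  fake <- structure(list(id = "px", name = "fake"), class = "xr_protocol")
  expect_error(apply_protocol(st, work_arc$id, fake), class = "NoSuchProtocol")
})

test_that("deleting a node with children requires cascade and prunes orphans", {
  st <- make_study()
  b <- add_child(st, st$root_id, "biosource", "b1")
  ct <- add_child(st, b$id, "container", "c1")
  a <- add_child(st, ct$id, "assay", "a1", modality = "imaging")

  expect_error(delete_node(st, ct$id), class = "CascadeRequired")
  removed <- delete_node(st, ct$id, cascade = TRUE)
  expect_setequal(removed, c(ct$id, a$id))
  expect_identical(nrow(validate_graph(st)), 0L)
  expect_error(delete_node(st, st$root_id), class = "KindError")
})

test_that("validate_graph flags each violation class with its code", {
  st <- demo_study()
  expect_identical(nrow(validate_graph(st)), 0L)
  for (nm in names(graph_corruptions)) {
    bad <- graph_corruptions[[nm]](st)
    if (is.null(bad)) next
    v <- validate_graph(bad)
    expect_gt(nrow(v), 0)
  }
  # specific codes
  expect_true("UNIQUE_ROOT" %in% validate_graph(graph_corruptions$second_root(st))$code)
  expect_true("ROOT_ARC_PROTOCOL" %in%
                validate_graph(graph_corruptions$root_arc_protocol(st))$code)
  expect_true("CYCLE" %in% validate_graph(graph_corruptions$container_cycle(st))$code)
  expect_true("DISCONNECTED" %in% validate_graph(graph_corruptions$detach_node(st))$code)
  expect_true("MULTIPARENT_KIND" %in%
                validate_graph(graph_corruptions$pooled_biosource(st))$code)
  expect_true("ILLEGAL_CHILD" %in% validate_graph(graph_corruptions$kind_flip(st))$code)
})

test_that("validate_graph agrees with the brute-force checker on random graphs", {
  for (seed in 1:25) {
    st <- random_ops_study(seed)
    expect_identical(nrow(validate_graph(st)), 0L)
    expect_identical(bf_check(st), character(0))
    for (corrupt in graph_corruptions) {
      bad <- corrupt(st)
      if (is.null(bad)) next
      expect_gt(nrow(validate_graph(bad)), 0)
      expect_gt(length(bf_check(bad)), 0)
    }
  }
})

test_that("file attachments record checksum and size for local files", {
  st <- make_study()
  b <- add_child(st, st$root_id, "biosource", "b1")
  f <- withr::local_tempfile(lines = "some raw data")
  att <- attach_file(st, b$id, f)
  expect_identical(att$checksum, unname(tools::md5sum(f)))
  expect_identical(att$size, file.size(f))
  expect_length(get_node(st, b$id)$attachments, 1)

  arc_id <- names(st$arcs)[[1]]
  attach_file(st, arc_id, "remote/uri.bin")
  expect_length(get_arc(st, arc_id)$attachments, 1)
  expect_true(is.na(get_arc(st, arc_id)$attachments[[1]]$checksum))
})
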