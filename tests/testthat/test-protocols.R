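# Protocol registry: immutability, searchable comments, sharing; technology
# templates and minimum-information records.

test_that("registered protocols are private and their text is immutable", {
  reg <- protocol_registry()
  p <- register_protocol(reg, "RNA extraction", "Step 1: lyse cells.", "alice")
  expect_identical(p$owner, "alice")
  expect_length(p$grants, 0)

  h0 <- p$text
  expect_error(set_protocol_text(p, "new text"), class = "ProtocolImmutable")
  expect_error(p$text <- "new text")              # locked binding
  expect_error(assign("text", "other", envir = p))
  add_protocol_comment(p, "bob", "works better at 4C", timestamp = "2013-01-16T00:00:00Z")
  expect_identical(p$text, h0)

  expect_error(register_protocol(reg, "x", "", "alice"), class = "EmptyProtocol")
  expect_error(register_protocol(reg, "x", "   ", "alice"), class = "EmptyProtocol")
})

test_that("search spans protocol text and comments, honouring visibility", {
  reg <- protocol_registry()
  p1 <- register_protocol(reg, "B extraction", "Use buffer AE.", "alice")
  p2 <- register_protocol(reg, "A digestion", "Trypsin overnight.", "alice")
  add_protocol_comment(p1, "alice", "works better at 4C",
                       timestamp = "2013-01-16T00:00:00Z")

  hits <- search_protocols(reg, "4C", "alice")
  expect_length(hits, 1)
  expect_identical(hits[[1]]$id, p1$id)
  expect_length(search_protocols(reg, "zzz-nomatch", "alice"), 0)

  # results ordered by name
  both <- search_protocols(reg, "t", "alice")
  expect_identical(vapply(both, `[[`, character(1), "name"),
                   sort(vapply(both, `[[`, character(1), "name")))

  # private protocols are invisible to others until shared
  expect_length(search_protocols(reg, "buffer", "bob"), 0)
  g <- access_group("lab", members = "bob")
  share_protocol(p1, g, "read_only", caller = "alice")
  expect_length(search_protocols(reg, "buffer", "bob"), 1)

  # search correctness vs linear scan over a larger corpus
  set.seed(5)
  words <- c("lyse", "spin", "elute", "wash", "incubate", "stain", "image")
  for (i in 1:50) {
    register_protocol(reg, sprintf("proto %02d", i),
                      paste(sample(words, 3), collapse = " "), "alice")
  }
  for (q in words) {
    mine <- search_protocols(reg, q, "alice")
    expected <- Filter(function(p) {
      hay <- tolower(paste(c(p$text, vapply(p$comments, `[[`, character(1), "text")),
                           collapse = "\n"))
      p$owner == "alice" && grepl(q, hay, fixed = TRUE)
    }, reg$protocols)
    expect_setequal(unname(vapply(mine, `[[`, character(1), "id")),
                    unname(vapply(expected, `[[`, character(1), "id")))
  }
})

test_that("templates enforce required fields and batch-associate files", {
  tpl <- technology_template("microarray", data.frame(
    field_name = c("array_design", "scanner"),
    required = c(TRUE, FALSE),
    description = c("Array design accession", "Scanner model")
  ))
  expect_error(technology_template("x", data.frame(
    field_name = c("a", "a"), required = FALSE, description = ""
  )), class = "DuplicateField")

  ct <- fill_template(tpl, list(array_design = "Hgu133"))
  ct <- associate_files(ct, sprintf("chip_%d.cel", 1:3))
  expect_length(ct$files, 3)
  expect_length(associate_files(ct, character(0))$files, 3)

  err <- tryCatch(fill_template(tpl, list()), condition = identity)
  expect_s3_class(err, "MissingField")
  expect_identical(err$fields, "array_design")
})

test_that("minimum-information records merge MIABS and tech fields losslessly", {
  st <- make_study()
  b <- add_child(st, st$root_id, "biosource", "b1")
  set_miabs(st, b$id, "species", "Gallus gallus")
  set_miabs(st, b$id, "strain", "broiler")
  tpl <- technology_template("microarray", data.frame(
    field_name = "array_design", required = TRUE, description = ""
  ))
  ct <- associate_files(fill_template(tpl, list(array_design = "Hgu133")),
                        c("a.cel", "b.cel"))

  rec <- compile_minimum_info(get_node(st, b$id), ct)
  expect_identical(names(rec$values), c("species", "strain", "tech:array_design"))
  expect_identical(rec$values$`tech:array_design`, "Hgu133")
  expect_identical(rec$data_files, c("a.cel", "b.cel"))

  # no template: MIABS only
  rec0 <- compile_minimum_info(get_node(st, b$id))
  expect_identical(names(rec0$values), c("species", "strain"))

  ctn <- add_child(st, b$id, "container", "c1")
  expect_error(compile_minimum_info(get_node(st, ctn$id)), class = "KindError")

  # injectivity: distinct inputs give distinct records
  st2 <- make_study()
  b2 <- add_child(st2, st2$root_id, "biosource", "b1")
  set_miabs(st2, b2$id, "species", "Mus musculus")
  expect_false(identical(compile_minimum_info(get_node(st2, b2$id))$values,
                         rec0$values))
})
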