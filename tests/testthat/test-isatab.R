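# ISA-Tab export, structural validation, import round-trip.

test_that("the demo study exports one investigation, one study and two assay files", {
  st <- demo_study()
  d <- tempfile()
  b <- export_isatab(st$investigation, d)
  expect_identical(b$investigation_file, "i_chick_infection_study.txt")
  expect_identical(unname(b$study_files), "s_s1.txt")
  expect_identical(sort(names(b$assay_files[["s1"]])), c("imaging", "sequencing"))
  expect_setequal(list.files(d), c("i_chick_infection_study.txt", "s_s1.txt",
                                   "a_s1_imaging.txt", "a_s1_sequencing.txt"))
  expect_identical(nrow(validate_isatab(d)), 0L)
})

test_that("study files follow the row-count law", {
  # linear chain: exactly one data row
  st <- make_study()
  b <- add_child(st, st$root_id, "biosource", "b1")
  ct <- add_child(st, b$id, "container", "c1")
  add_child(st, ct$id, "assay", "a1", modality = "sequencing")
  d <- tempfile()
  export_isatab(st$investigation, d)
  expect_length(readLines(file.path(d, "s_s1.txt")), 2L)

  # three biosources pooled into one container: 3 rows, one Sample Name
  st2 <- make_study()
  bios <- vapply(1:3, function(i) {
    add_child(st2, st2$root_id, "biosource", paste0("b", i))$id
  }, character(1))
  ep <- pool(st2, bios, "container", "eppendorf")
  add_child(st2, ep$id, "assay", "seq", modality = "sequencing")
  d2 <- tempfile()
  export_isatab(st2$investigation, d2)
  lines <- readLines(file.path(d2, "s_s1.txt"))
  expect_length(lines, 4L)
  header <- strsplit(lines[[1]], "\t")[[1]]
  samples <- vapply(strsplit(lines[-1], "\t"),
                    function(x) x[[which(header == "Sample Name")]], character(1))
  expect_identical(unique(samples), "eppendorf")

  # random graphs: rows == independent path count
  for (seed in 1:20) {
    stf <- generate_fixture_graph(fixture_spec(seed = seed, max_depth = 6))
    df <- tempfile()
    export_isatab(stf$investigation, df)
    rows <- length(readLines(file.path(df, paste0("s_", stf$id, ".txt")))) - 1L
    expect_identical(rows, bf_path_count(stf))
  }
})

test_that("export refuses invalid graphs", {
  st <- demo_study()
  bad <- graph_corruptions$second_root(st)
  bad$investigation$studies[[bad$id]] <- bad
  err <- tryCatch(export_isatab(bad$investigation, tempfile()),
                  condition = identity)
  expect_s3_class(err, "InvalidGraph")
  expect_true("UNIQUE_ROOT" %in% err$violations$code)
})

test_that("import(export(G)) preserves paths, labels, annotations, terms, protocols", {
  for (seed in c(1:15, 101:110)) {
    st <- generate_fixture_graph(fixture_spec(seed = seed, max_depth = 6))
    d <- tempfile()
    export_isatab(st$investigation, d)
    inv2 <- import_isatab(d)
    expect_identical(study_paths(inv2$studies[[1]]), study_paths(st),
                     info = paste("seed", seed))
    # protocol names survive via the registry
    expect_true(all(vapply(inv2$protocol_registry$protocols,
                           function(p) nzchar(p$text), logical(1))))
  }
})

test_that("the validator reports missing files and corrupted references", {
  st <- demo_study()
  d <- tempfile()
  export_isatab(st$investigation, d)
  expect_identical(nrow(validate_isatab(d)), 0L)

  expect_identical(validate_isatab(tempfile())$code, "NO_INVESTIGATION_FILE")

  d2 <- tempfile(); export_isatab(st$investigation, d2)
  file.remove(file.path(d2, "s_s1.txt"))
  expect_true("MISSING_FILE" %in% validate_isatab(d2)$code)
  err <- tryCatch(import_isatab(d2), condition = identity)
  expect_s3_class(err, "IsaTabError")

  d3 <- tempfile(); export_isatab(st$investigation, d3)
  sf <- file.path(d3, "s_s1.txt")
  writeLines(gsub("\tTOY\t", "\tZZZ\t", readLines(sf)), sf)
  expect_true("UNDECLARED_TERM_SOURCE" %in% validate_isatab(d3)$code)

  d4 <- tempfile(); export_isatab(st$investigation, d4)
  af <- file.path(d4, "a_s1_imaging.txt")
  writeLines(gsub("petri dish 1", "mystery sample", readLines(af)), af)
  expect_true("UNKNOWN_SAMPLE" %in% validate_isatab(d4)$code)

  d5 <- tempfile(); export_isatab(st$investigation, d5)
  af5 <- file.path(d5, "a_s1_imaging.txt")
  writeLines(gsub("image acquisition", "undeclared protocol", readLines(af5)), af5)
  expect_true("UNDECLARED_PROTOCOL" %in% validate_isatab(d5)$code)

  d6 <- tempfile(); export_isatab(st$investigation, d6)
  ifile <- file.path(d6, "i_chick_infection_study.txt")
  lines <- readLines(ifile)
  writeLines(rev(lines), ifile)
  expect_true("SECTION_ORDER" %in% validate_isatab(d6)$code)
})

test_that("export is byte-identical across runs on the same input", {
  st1 <- generate_fixture_graph(fixture_spec(seed = 9))
  st2 <- generate_fixture_graph(fixture_spec(seed = 9))
  d1 <- tempfile(); d2 <- tempfile()
  export_isatab(st1$investigation, d1)
  export_isatab(st2$investigation, d2)
  expect_identical(read_bundle_bytes(d1), read_bundle_bytes(d2))
})
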