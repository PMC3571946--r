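## Seedable synthetic fixtures: random-but-valid study graphs, toy OBO
## ontologies, and the canonical worked-example study (one chicken and
## three bacterial replicate cultures, split and pooled into imaging and
## sequencing assays). Every generated graph is built exclusively through
## the public construction operations, so it validates clean by
## construction; every generated ontology round-trips through load_obo.

#' Describe a synthetic study graph
#'
#' The defaults emulate a small multi-modality laboratory study: four
#' biosources (as in the worked example), provenance chains up to four
#' levels deep (root, biosource, containers, assay), a 30% chance that a
#' biosource is split into an extra container, a 30% chance that the first
#' biosources are pooled, and two assay modalities (sequencing and
#' imaging).
#'
#' @param seed Integer RNG seed; every quantity below is drawn under it.
#' @param n_biosources Number of biosources (>= 1).
#' @param max_depth Maximum node depth including root and assay (>= 4).
#' @param p_split Probability a biosource receives a second container.
#' @param p_pool Probability the study pools biosources into one container.
#' @param n_assay_modalities Number of distinct assay modalities (1-4).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_biosources = 4L, max_depth = 4L,
                         p_split = 0.3, p_pool = 0.3,
                         n_assay_modalities = 2L) {
  spec <- list(seed = as.integer(seed), n_biosources = as.integer(n_biosources),
               max_depth = as.integer(max_depth), p_split = p_split,
               p_pool = p_pool, n_assay_modalities = as.integer(n_assay_modalities))
  probs <- c(spec$p_split, spec$p_pool)
  if (spec$n_biosources < 1L || any(probs < 0) || any(probs > 1) ||
      spec$max_depth < 4L || spec$n_assay_modalities < 1L ||
      spec$n_assay_modalities > 4L) {
    xr_abort("FixtureSpecError", "invalid fixture specification")
  }
  structure(spec, class = "fixture_spec")
}

FIXTURE_SPECIES <- c("Gallus gallus", "Escherichia coli", "Mus musculus",
                     "Homo sapiens", "Saccharomyces cerevisiae")
FIXTURE_MATERIALS <- c("RNA extract", "DNA extract", "protein lysate",
                       "cell suspension")
FIXTURE_MODALITIES <- c("sequencing", "imaging", "mass spectrometry",
                        "metabolite profiling")

#' Generate a random valid study graph
#'
#' Builds a study (inside its own investigation, reachable as
#' `study$investigation`) using only the public construction operations:
#' biosources annotated with species (with an ontology term from the
#' investigation's TOY source) and strain, optional pooling of the first
#' biosources, optional splits, container chains within the depth budget,
#' annotated terminal containers, and one or two assays per terminal
#' container with protocols applied to every non-root arc. Deterministic
#' for a given spec; the serialized form is byte-identical across runs.
#'
#' @param spec A [fixture_spec()].
#' @return An `xr_study` that passes [validate_graph()].
#' @export
generate_fixture_graph <- function(spec = fixture_spec()) {
  if (!inherits(spec, "fixture_spec")) {
    xr_abort("FixtureSpecError", "spec must be created with fixture_spec()")
  }
  with_seed(spec$seed, {
    src <- ontology_source("TOY", file = "toy.obo", version = "1",
                           description = "toy fixture ontology")
    inv <- create_investigation(sprintf("Fixture investigation %d", spec$seed),
                                list(src), xr_user("fixture_bot"))
    st <- add_study(inv, sprintf("Fixture study %d", spec$seed))
    reg <- protocol_registry()
    p_extract <- register_protocol(reg, "sample extraction",
                                   "Extract material from the biosource.", "fixture_bot")
    p_aliquot <- register_protocol(reg, "aliquoting",
                                   "Transfer an aliquot to a fresh container.", "fixture_bot")
    p_pool <- register_protocol(reg, "pooling",
                                "Combine replicate samples into one container.", "fixture_bot")
    p_assay <- register_protocol(reg, "measurement",
                                 "Run the assay on the sample.", "fixture_bot")
    modalities <- FIXTURE_MODALITIES[seq_len(spec$n_assay_modalities)]

    species <- sample(FIXTURE_SPECIES, spec$n_biosources, replace = TRUE)
    bios <- character(spec$n_biosources)
    for (i in seq_len(spec$n_biosources)) {
      b <- add_child(st, st$root_id, "biosource", sprintf("biosource_%d", i))
      bios[[i]] <- b$id
      annotate(st, b$id, "species", species[[i]])
      acc <- sprintf("TOY:%07d", match(species[[i]], FIXTURE_SPECIES))
      if (stats::runif(1) < 0.8) {
        attach_term(st, b$id, "species",
                    ontology_term(acc, species[[i]], "TOY"))
      }
      annotate(st, b$id, "strain", sprintf("strain_%d", i))
      set_miabs(st, b$id, "species", species[[i]])
    }

    extract_arc <- function(bio_id, cont_id) {
      arc <- arc_between(st, bio_id, cont_id)
      apply_protocol(st, arc$id, p_extract,
                     parameters = list(temperature = "4C"))
    }

    containers <- character(0)
    remaining <- bios
    if (spec$n_biosources >= 3L && stats::runif(1) < spec$p_pool) {
      k <- sample(2:min(3L, spec$n_biosources), 1L)
      pooled_parents <- bios[seq_len(k)]
      node <- pool(st, pooled_parents, "container", "pooled_tube_1")
      for (p in pooled_parents) {
        arc <- arc_between(st, p, node$id)
        apply_protocol(st, arc$id, p_pool)
      }
      containers <- c(containers, node$id)
      remaining <- bios[-seq_len(k)]
    }
    ci <- length(containers)
    for (b in remaining) {
      n_cont <- 1L + (stats::runif(1) < spec$p_split)
      for (j in seq_len(n_cont)) {
        ci <- ci + 1L
        node <- add_child(st, b, "container", sprintf("tube_%d", ci))
        extract_arc(b, node$id)
        containers <- c(containers, node$id)
      }
    }

    # optionally extend chains within the depth budget
    # depth so far: root(1) -> biosource(2) -> container(3); assay adds one
    terminals <- character(0)
    for (c0 in containers) {
      depth <- 3L
      cur <- c0
      while (depth < spec$max_depth - 1L && stats::runif(1) < 0.35) {
        ci <- ci + 1L
        nxt <- add_child(st, cur, "container", sprintf("tube_%d", ci))
        arc <- arc_between(st, cur, nxt$id)
        apply_protocol(st, arc$id, p_aliquot)
        cur <- nxt$id
        depth <- depth + 1L
      }
      annotate(st, cur, "material", sample(FIXTURE_MATERIALS, 1L))
      terminals <- c(terminals, cur)
    }

    ai <- 0L
    for (tc in terminals) {
      n_assay <- 1L + (stats::runif(1) < 0.3)
      for (j in seq_len(n_assay)) {
        ai <- ai + 1L
        m <- modalities[[(ai - 1L) %% length(modalities) + 1L]]
        assay <- add_child(st, tc, "assay", sprintf("assay_%d", ai), modality = m)
        arc <- arc_between(st, tc, assay$id)
        apply_protocol(st, arc$id, p_assay,
                       action = if (stats::runif(1) < 0.2) "run repeated once" else "")
        attach_file(st, assay$id, sprintf("raw/assay_%d.dat", ai))
      }
    }
    st
  })
}

#' Write a deterministic toy ontology in OBO format
#'
#' Term names are drawn from a small controlled vocabulary of adjective +
#' noun phrases; a fraction of terms receive EXACT synonyms and a few are
#' marked obsolete. Byte-identical for the same arguments.
#'
#' @param path Output file.
#' @param seed Integer seed.
#' @param n_terms Number of `[Term]` stanzas (>= 1).
#' @param synonym_rate Fraction of terms given a synonym.
#' @param obsolete_rate Fraction of terms flagged obsolete.
#' @param source Accession prefix / source short name.
#' @return `path`, invisibly.
#' @export
generate_toy_obo <- function(path, seed = 1L, n_terms = 100L,
                             synonym_rate = 0.3, obsolete_rate = 0.02,
                             source = "TOY") {
  if (n_terms < 1L) xr_abort("FixtureSpecError", "n_terms must be >= 1")
  adjectives <- c("primary", "cultured", "frozen", "embryonic", "adult",
                  "infected", "wild", "mutant", "purified", "synthetic",
                  "aerobic", "anaerobic", "stained", "labelled", "control")
  nouns <- c("tissue", "cell", "culture", "sample", "membrane", "nucleus",
             "extract", "medium", "organ", "colony", "tube", "dish",
             "slide", "fraction", "buffer")
  with_seed(seed, {
    lines <- c("format-version: 1.2",
               sprintf("ontology: %s", tolower(source)), "")
    used <- character(0)
    for (i in seq_len(n_terms)) {
      repeat {
        nm <- paste(sample(adjectives, 1L), sample(nouns, 1L),
                    if (stats::runif(1) < 0.5) sample(nouns, 1L) else NULL)
        nm <- paste(c(nm, if (nm %in% used) as.character(i)), collapse = " ")
        if (!nm %in% used) break
      }
      used <- c(used, nm)
      lines <- c(lines, "[Term]",
                 sprintf("id: %s:%07d", source, i),
                 sprintf("name: %s", nm))
      if (stats::runif(1) < synonym_rate) {
        lines <- c(lines, sprintf("synonym: \"%s variant\" EXACT []", nm))
      }
      if (stats::runif(1) < obsolete_rate) {
        lines <- c(lines, "is_obsolete: true")
      }
      lines <- c(lines,
                 sprintf("def: \"A toy term standing in for %s.\" []", nm), "")
    }
    write_lines_lf(lines, path)
  })
}

#' Write the companion ontology for the demo study
#'
#' A hand-picked toy ontology (synthetic stand-in for a real vocabulary)
#' whose terms match the labels and annotations of [demo_study()]: species
#' terms ("Gallus gallus" with EXACT synonym "chicken", "Escherichia
#' coli"), container vocabulary and assay modalities.
#'
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_demo_obo <- function(path) {
  lines <- c(
    "format-version: 1.2", "ontology: toy", "",
    "[Term]", "id: TOY:0000001", "name: Gallus gallus",
    "synonym: \"chicken\" EXACT []",
    "def: \"The domestic chicken.\" []", "",
    "[Term]", "id: TOY:0000002", "name: Escherichia coli",
    "synonym: \"E. coli\" EXACT []",
    "def: \"A model bacterium.\" []", "",
    "[Term]", "id: TOY:0000003", "name: petri dish",
    "def: \"A shallow culture dish.\" []", "",
    "[Term]", "id: TOY:0000004", "name: eppendorf tube",
    "synonym: \"microcentrifuge tube\" EXACT []",
    "def: \"A small laboratory tube.\" []", "",
    "[Term]", "id: TOY:0000005", "name: sequencing assay",
    "def: \"A nucleic acid sequencing measurement.\" []", "",
    "[Term]", "id: TOY:0000006", "name: imaging assay",
    "def: \"A microscopy image acquisition.\" []", ""
  )
  write_lines_lf(lines, path)
}

#' Build the canonical demo study
#'
#' The worked example used throughout the package: an infection study with
#' four biosources — one chicken and three bacterial replicate cultures.
#' Material from the chicken is split into two petri dishes, each feeding
#' an imaging assay; the three bacterial replicates are pooled into a
#' single eppendorf tube feeding a sequencing assay. Every non-root arc
#' carries a registered protocol. The graph validates clean and its
#' ISA-Tab export passes the structural validator.
#'
#' @param owner The creating user.
#' @return An `xr_study`; its investigation is `study$investigation` and
#'   the protocol registry used is attached as
#'   `study$investigation$protocol_registry`.
#' @export
demo_study <- function(owner = xr_user("alice")) {
  src <- ontology_source("TOY", file = "toy.obo", version = "1",
                         description = "demo toy ontology")
  inv <- create_investigation("Chick infection study", list(src), owner,
                              description = "Worked example: split, pooled, two assay modalities.")
  st <- add_study(inv, "Infection time course")
  reg <- protocol_registry()
  inv$protocol_registry <- reg
  p_extract <- register_protocol(reg, "tissue extraction",
                                 "Dissect tissue and transfer to a dish.", owner)
  p_pool <- register_protocol(reg, "replicate pooling",
                              "Combine replicate cultures into one tube.", owner)
  p_image <- register_protocol(reg, "image acquisition",
                               "Acquire microscopy images of the dish.", owner)
  p_seq <- register_protocol(reg, "library sequencing",
                             "Prepare a library and sequence it.", owner)

  chicken <- add_child(st, st$root_id, "biosource", "chicken")
  annotate(st, chicken$id, "species", "Gallus gallus")
  attach_term(st, chicken$id, "species",
              ontology_term("TOY:0000001", "Gallus gallus", "TOY"))
  set_miabs(st, chicken$id, "species", "Gallus gallus")
  set_miabs(st, chicken$id, "age", "21 days")

  bact <- lapply(1:3, function(i) {
    b <- add_child(st, st$root_id, "biosource", sprintf("bacterial culture %d", i))
    annotate(st, b$id, "species", "Escherichia coli")
    attach_term(st, b$id, "species",
                ontology_term("TOY:0000002", "Escherichia coli", "TOY"))
    set_miabs(st, b$id, "species", "Escherichia coli")
    b
  })

  dishes <- lapply(1:2, function(i) {
    d <- add_child(st, chicken$id, "container", sprintf("petri dish %d", i))
    annotate(st, d$id, "material", "infected tissue")
    apply_protocol(st, arc_between(st, chicken$id, d$id)$id, p_extract)
    d
  })
  epp <- pool(st, vapply(bact, `[[`, character(1), "id"), "container",
              "eppendorf tube")
  annotate(st, epp$id, "material", "pooled culture")
  for (b in bact) {
    apply_protocol(st, arc_between(st, b$id, epp$id)$id, p_pool)
  }

  for (i in 1:2) {
    a <- add_child(st, dishes[[i]]$id, "assay", sprintf("imaging assay %d", i),
                   modality = "imaging")
    apply_protocol(st, arc_between(st, dishes[[i]]$id, a$id)$id, p_image)
    attach_file(st, a$id, sprintf("images/dish_%d.tif", i))
  }
  sq <- add_child(st, epp$id, "assay", "sequencing assay",
                  modality = "sequencing")
  apply_protocol(st, arc_between(st, epp$id, sq$id)$id, p_seq,
                 action = "library prepared with half input volume")
  attach_file(st, sq$id, "reads/pooled_culture.fastq")
  st
}
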