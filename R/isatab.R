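## ISA-Tab adapter: exporter, importer (the round-trip oracle) and a
## structural validator covering the core ISA-Tab 1.0 rules.
##
## Mapping (the package's own ISA-Tab dialect, byte-reproducible):
##  * one investigation file i_<inv>.txt, one study file s_<study>.txt per
##    study, one assay file a_<study>_<modality>.txt per distinct assay
##    modality in a study;
##  * one study-file data row per distinct root -> assay-input path
##    (assay-input = a container that parents at least one assay); pooled
##    containers repeat their Sample Name across the rows of their parents,
##    splits repeat the Source Name;
##  * Source Name = biosource label with its annotations as
##    Characteristics[...] columns (Term Source REF / Term Accession Number
##    follow a characteristic when a term is attached); Sample Name =
##    terminal container label, annotated likewise;
##  * every non-root arc on the path becomes a Protocol REF column (valued
##    with the protocol name) followed by its Parameter Value[...] columns;
##    intermediate containers on longer chains travel as Comment[Sample
##    Name] / Comment[Characteristics[...]] columns after their step;
##  * assay files carry Sample Name, Protocol REF, Assay Name and Raw Data
##    File. Rows are sorted in lexicographic path order, columns follow
##    annotation insertion order, files are UTF-8 with LF line endings.

TAB <- "\t"

arc_between <- function(study, parent_id, child_id) {
  for (a in study$arcs) {
    if (a$parent_id == parent_id && a$child_id == child_id) return(a)
  }
  NULL
}

first_term <- function(ann) {
  if (length(ann$value_terms)) ann$value_terms[[1]] else NULL
}

# Ordered union preserving first appearance.
ounion <- function(lists) unique(unlist(lists, use.names = FALSE)) %||% character(0)

modality_slug <- function(m) slugify(m)

#' Export an investigation as an ISA-Tab bundle
#'
#' Writes the investigation file, one sample/study file per study and one
#' assay file per (study, modality) into `out_dir` (created if needed).
#' Every study must pass [validate_graph()] first. The output is
#' deterministic: identical investigations produce byte-identical bundles.
#'
#' @param inv An `xr_investigation`.
#' @param out_dir Output directory.
#' @return Invisibly, an `isatab_bundle` list: `dir`, `investigation_file`,
#'   `study_files`, `assay_files` (paths).
#' @export
export_isatab <- function(inv, out_dir) {
  stopifnot(inherits(inv, "xr_investigation"))
  for (st in inv$studies) {
    viol <- validate_graph(st)
    if (nrow(viol)) {
      xr_abort("InvalidGraph",
               sprintf("study '%s' has %d validation violation(s); export refused",
                       st$id, nrow(viol)),
               violations = viol)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  study_files <- character(0)
  assay_files <- list()
  study_meta <- list()
  for (st in inv$studies) {
    sf <- paste0("s_", st$id, ".txt")
    tab <- study_table(st)
    write_lines_lf(tab, file.path(out_dir, sf))
    study_files[[st$id]] <- sf

    modalities <- sort(unique(vapply(
      Filter(function(n) n$kind == "assay", st$nodes),
      function(n) n$modality, character(1))))
    afiles <- character(0)
    for (m in modalities) {
      af <- paste0("a_", st$id, "_", modality_slug(m), ".txt")
      write_lines_lf(assay_table(st, m), file.path(out_dir, af))
      afiles[[m]] <- af
    }
    assay_files[[st$id]] <- afiles
    protos <- sort(unique(unlist(lapply(st$arcs, function(a) {
      a$protocol_application$protocol_name
    }))))
    study_meta[[st$id]] <- list(study = st, file = sf, assays = afiles,
                                protocols = protos %||% character(0))
  }

  ifile <- paste0("i_", inv$id, ".txt")
  write_lines_lf(investigation_lines(inv, study_meta), file.path(out_dir, ifile))

  invisible(structure(list(dir = out_dir, investigation_file = ifile,
                           study_files = study_files, assay_files = assay_files),
                      class = "isatab_bundle"))
}

investigation_lines <- function(inv, study_meta) {
  row <- function(...) paste(c(...), collapse = TAB)
  src <- inv$ontology_sources
  lines <- c(
    "ONTOLOGY SOURCE REFERENCE",
    row("Term Source Name", vapply(src, function(s) s$short_name, character(1))),
    row("Term Source File", vapply(src, function(s) s$file %||% "", character(1))),
    row("Term Source Version", vapply(src, function(s) s$version, character(1))),
    row("Term Source Description", vapply(src, function(s) s$description, character(1))),
    "INVESTIGATION",
    row("Investigation Identifier", inv$id),
    row("Investigation Title", inv$title),
    row("Investigation Description", inv$description)
  )
  for (sm in study_meta) {
    lines <- c(lines,
      "STUDY",
      row("Study Identifier", sm$study$id),
      row("Study Title", sm$study$title),
      row("Study File Name", sm$file),
      "STUDY PROTOCOLS",
      row("Study Protocol Name", sm$protocols),
      "STUDY ASSAYS",
      row("Study Assay File Name", unname(sm$assays)),
      row("Study Assay Measurement Type", names(sm$assays) %||% character(0))
    )
  }
  lines
}

# Assemble the sample-table lines for one study.
study_table <- function(study) {
  paths <- enumerate_paths(study)
  label_of <- function(id) study$nodes[[id]]$label
  # sort paths lexicographically by their label sequence
  keys <- vapply(paths, function(p) {
    paste(vapply(p, label_of, character(1)), collapse = "\x1f")
  }, character(1))
  paths <- paths[order(keys)]

  # decompose each path into biosource, intermediate steps, final step
  decomp <- lapply(paths, function(p) {
    chain <- p[-1]                       # biosource, containers...
    bio <- chain[[1]]
    conts <- chain[-1]
    steps <- lapply(seq_along(conts), function(k) {
      list(arc = arc_between(study, chain[[k]], chain[[k + 1]]),
           child = conts[[k]])
    })
    list(bio = bio, steps = steps)
  })

  bios <- unique(vapply(decomp, function(d) d$bio, character(1)))
  terminals <- unique(vapply(decomp, function(d) {
    d$steps[[length(d$steps)]]$child
  }, character(1)))
  inters <- ounion(lapply(decomp, function(d) {
    n <- length(d$steps)
    if (n > 1L) vapply(d$steps[-n], function(s) s$child, character(1)) else character(0)
  }))

  ann_names <- function(ids) {
    ounion(lapply(ids, function(id) {
      vapply(study$nodes[[id]]$annotations, function(a) a$name, character(1))
    }))
  }
  ann_of <- function(id, name) {
    for (a in study$nodes[[id]]$annotations) if (a$name == name) return(a)
    NULL
  }
  has_term <- function(ids, name) {
    any(vapply(ids, function(id) {
      a <- ann_of(id, name)
      !is.null(a) && !is.null(first_term(a))
    }, logical(1)))
  }
  pa_params <- function(steps_sel) {
    ounion(lapply(steps_sel, function(s) {
      names(s$arc$protocol_application$parameters) %||% character(0)
    }))
  }

  bio_ann <- ann_names(bios)
  bio_term <- vapply(bio_ann, function(nm) has_term(bios, nm), logical(1))
  term_ann <- ann_names(terminals)
  term_term <- vapply(term_ann, function(nm) has_term(terminals, nm), logical(1))
  inter_ann <- ann_names(inters)
  max_inter <- max(c(0L, vapply(decomp, function(d) length(d$steps) - 1L, integer(1))))
  inter_par <- pa_params(unlist(lapply(decomp, function(d) {
    n <- length(d$steps)
    if (n > 1L) d$steps[-n] else list()
  }), recursive = FALSE))
  final_par <- pa_params(lapply(decomp, function(d) d$steps[[length(d$steps)]]))

  # header
  header <- "Source Name"
  for (i in seq_along(bio_ann)) {
    header <- c(header, sprintf("Characteristics[%s]", bio_ann[[i]]))
    if (bio_term[[i]]) header <- c(header, "Term Source REF", "Term Accession Number")
  }
  inter_block <- c("Protocol REF",
                   if (length(inter_par)) sprintf("Parameter Value[%s]", inter_par),
                   "Comment[Sample Name]",
                   if (length(inter_ann)) sprintf("Comment[Characteristics[%s]]", inter_ann))
  header <- c(header, rep(inter_block, max_inter))
  header <- c(header, "Protocol REF",
              if (length(final_par)) sprintf("Parameter Value[%s]", final_par),
              "Sample Name")
  for (i in seq_along(term_ann)) {
    header <- c(header, sprintf("Characteristics[%s]", term_ann[[i]]))
    if (term_term[[i]]) header <- c(header, "Term Source REF", "Term Accession Number")
  }

  ann_cells <- function(id, names, with_term) {
    cells <- character(0)
    for (i in seq_along(names)) {
      a <- ann_of(id, names[[i]])
      cells <- c(cells, if (is.null(a)) "" else a$value)
      if (with_term[[i]]) {
        t <- if (is.null(a)) NULL else first_term(a)
        cells <- c(cells, t$source %||% "", t$accession %||% "")
      }
    }
    cells
  }
  pa_cells <- function(arc, par_names) {
    pa <- arc$protocol_application
    c(pa$protocol_name %||% "",
      vapply(par_names, function(p) {
        as.character(pa$parameters[[p]] %||% "")
      }, character(1)))
  }

  rows <- vapply(decomp, function(d) {
    cells <- c(label_of(d$bio), ann_cells(d$bio, bio_ann, bio_term))
    n <- length(d$steps)
    for (k in seq_len(max_inter)) {
      if (k <= n - 1L) {
        s <- d$steps[[k]]
        cells <- c(cells, pa_cells(s$arc, inter_par), label_of(s$child),
                   ann_cells(s$child, inter_ann, rep(FALSE, length(inter_ann))))
      } else {
        cells <- c(cells, rep("", length(inter_block)))
      }
    }
    fin <- d$steps[[n]]
    cells <- c(cells, pa_cells(fin$arc, final_par), label_of(fin$child),
               ann_cells(fin$child, term_ann, term_term))
    paste(cells, collapse = TAB)
  }, character(1))

  c(paste(header, collapse = TAB), rows)
}

assay_table <- function(study, modality) {
  header <- c("Sample Name", "Protocol REF", "Assay Name", "Raw Data File")
  assays <- Filter(function(n) n$kind == "assay" && n$modality == modality,
                   study$nodes)
  rows <- character(0)
  for (assay in assays) {
    files <- vapply(assay$attachments, function(a) a$filename, character(1))
    if (!is.null(assay$template_ref)) {
      files <- c(files, unlist(assay$template_ref$files, use.names = FALSE))
    }
    raw <- paste(files, collapse = ";")
    for (a in study$arcs) {
      if (a$child_id != assay$id) next
      rows <- c(rows, paste(c(study$nodes[[a$parent_id]]$label,
                              a$protocol_application$protocol_name %||% "",
                              assay$label, raw), collapse = TAB))
    }
  }
  c(paste(header, collapse = TAB), sort(rows))
}

## ---- parsing helpers shared by importer and validator -----------------

split_tsv <- function(line) strsplit(line, TAB, fixed = TRUE)[[1]]

read_isatab_lines <- function(path) {
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

SECTION_NAMES <- c("ONTOLOGY SOURCE REFERENCE", "INVESTIGATION", "STUDY",
                   "STUDY PROTOCOLS", "STUDY ASSAYS")

# Parse an investigation file into ontology sources, metadata and one
# record per STUDY block.
parse_investigation_file <- function(lines) {
  sec_at <- which(lines %in% SECTION_NAMES)
  fields <- list()
  cur <- ""
  studies <- list()
  study <- NULL
  for (line in lines) {
    if (line %in% SECTION_NAMES) {
      if (line == "STUDY") {
        if (!is.null(study)) studies[[length(studies) + 1L]] <- study
        study <- list(fields = list())
      }
      cur <- line
      next
    }
    cells <- split_tsv(line)
    if (!length(cells)) next
    key <- cells[[1]]
    vals <- if (length(cells) > 1L) cells[-1] else character(0)
    if (cur %in% c("STUDY", "STUDY PROTOCOLS", "STUDY ASSAYS") && !is.null(study)) {
      study$fields[[key]] <- vals
    } else {
      fields[[key]] <- vals
    }
  }
  if (!is.null(study)) studies[[length(studies) + 1L]] <- study
  list(fields = fields, studies = studies, section_positions = sec_at,
       sections = lines[lines %in% SECTION_NAMES])
}

field1 <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v) || !length(v)) "" else v[[1]]
}

# Decompose a study-file header into the positional blocks written by
# study_table().
parse_study_header <- function(header) {
  n <- length(header)
  i <- 1L
  stopifnot(header[[1]] == "Source Name")
  i <- i + 1L
  read_chars <- function(i, comment = FALSE) {
    pat <- if (comment) "^Comment\\[Characteristics\\[(.*)\\]\\]$" else
      "^Characteristics\\[(.*)\\]$"
    out <- list()
    while (i <= n && grepl(pat, header[[i]])) {
      nm <- sub(pat, "\\1", header[[i]])
      i <- i + 1L
      with_term <- !comment && i <= n && header[[i]] == "Term Source REF"
      if (with_term) i <- i + 2L
      out[[length(out) + 1L]] <- list(name = nm, with_term = with_term)
    }
    list(chars = out, i = i)
  }
  b <- read_chars(i)
  bio_chars <- b$chars; i <- b$i
  blocks <- list()
  while (i <= n && header[[i]] == "Protocol REF") {
    i <- i + 1L
    params <- character(0)
    while (i <= n && grepl("^Parameter Value\\[", header[[i]])) {
      params <- c(params, sub("^Parameter Value\\[(.*)\\]$", "\\1", header[[i]]))
      i <- i + 1L
    }
    if (i <= n && header[[i]] == "Comment[Sample Name]") {
      i <- i + 1L
      cb <- read_chars(i, comment = TRUE)
      blocks[[length(blocks) + 1L]] <-
        list(type = "intermediate", params = params, chars = cb$chars)
      i <- cb$i
    } else if (i <= n && header[[i]] == "Sample Name") {
      i <- i + 1L
      fb <- read_chars(i)
      blocks[[length(blocks) + 1L]] <-
        list(type = "final", params = params, chars = fb$chars)
      i <- fb$i
    } else {
      xr_abort("IsaTabError", "malformed study-file header after Protocol REF")
    }
  }
  list(bio_chars = bio_chars, blocks = blocks)
}

# Width in cells of a characteristics descriptor list.
chars_width <- function(chars) {
  sum(vapply(chars, function(ch) 1L + if (ch$with_term) 2L else 0L, integer(1)))
}

#' Import an ISA-Tab bundle produced by [export_isatab()]
#'
#' Reconstructs an investigation whose multiset of root-to-assay paths,
#' labels, annotations, attached terms and protocol names equals the
#' exported original's (protocol bodies are not part of ISA-Tab and are
#' re-registered with placeholder text). Primarily the round-trip oracle
#' for the exporter; reads only the package's own dialect.
#'
#' @param dir Directory holding the bundle.
#' @return The reconstructed `xr_investigation`; its protocol registry is
#'   available as `inv$protocol_registry`.
#' @export
import_isatab <- function(dir) {
  viol <- validate_isatab(dir)
  if (nrow(viol)) {
    xr_abort("IsaTabError",
             sprintf("bundle has structural violations: %s",
                     paste(unique(viol$code), collapse = ", ")),
             violations = viol)
  }
  ifile <- list.files(dir, pattern = "^i_.*\\.txt$", full.names = TRUE)
  parsed <- parse_investigation_file(read_isatab_lines(ifile[[1]]))

  srcs <- parsed$fields[["Term Source Name"]] %||% character(0)
  src_files <- parsed$fields[["Term Source File"]] %||% rep("", length(srcs))
  sources <- lapply(seq_along(srcs), function(i) {
    ontology_source(srcs[[i]], file = if (nzchar(src_files[[i]])) src_files[[i]] else NULL)
  })
  inv <- create_investigation(field1(parsed$fields, "Investigation Title"),
                              sources, xr_user("importer"),
                              description = field1(parsed$fields, "Investigation Description"))
  reg <- protocol_registry()
  inv$protocol_registry <- reg

  for (sm in parsed$studies) {
    st <- add_study(inv, field1(sm$fields, "Study Title"))
    protos <- list()
    for (pn in sm$fields[["Study Protocol Name"]] %||% character(0)) {
      if (nzchar(pn)) protos[[pn]] <- register_protocol(reg, pn, paste("Protocol:", pn), "importer")
    }
    by_label <- new.env(parent = emptyenv())
    get_or_create <- function(parent_id, kind, label, modality = NULL) {
      key <- paste0(kind, "\x1f", label)
      id <- by_label[[key]]
      if (is.null(id)) {
        node <- add_child(st, parent_id, kind, label, modality)
        by_label[[key]] <- node$id
        list(id = node$id, new = TRUE, arc = arc_between(st, parent_id, node$id))
      } else {
        arc <- arc_between(st, parent_id, id)
        if (is.null(arc)) arc <- link_nodes(st, parent_id, id)
        list(id = id, new = FALSE, arc = arc)
      }
    }
    set_chars <- function(id, chars, cells, offset) {
      j <- offset
      for (ch in chars) {
        val <- cells[[j]]; j <- j + 1L
        tsrc <- tacc <- ""
        if (ch$with_term) { tsrc <- cells[[j]]; tacc <- cells[[j + 1L]]; j <- j + 2L }
        if (nzchar(val)) {
          annotate(st, id, ch$name, val)
          if (nzchar(tacc)) {
            attach_term(st, id, ch$name, ontology_term(tacc, "", tsrc))
          }
        }
      }
      j
    }
    maybe_apply <- function(arc, name, params, cells, offset) {
      vals <- cells[seq_along(params) + offset - 1L]
      if (nzchar(name) && is.null(st$arcs[[arc$id]]$protocol_application)) {
        pl <- as.list(vals[nzchar(vals)])
        names(pl) <- params[nzchar(vals)]
        apply_protocol(st, arc$id, protos[[name]], parameters = pl)
      }
    }

    slines <- read_isatab_lines(file.path(dir, field1(sm$fields, "Study File Name")))
    hdr <- parse_study_header(split_tsv(slines[[1]]))
    for (line in slines[-1]) {
      cells <- split_tsv(line)
      length(cells) <- max(length(cells), length(split_tsv(slines[[1]])))
      cells[is.na(cells)] <- ""
      j <- 1L
      bio <- get_or_create(st$root_id, "biosource", cells[[j]]); j <- j + 1L
      if (bio$new) j <- set_chars(bio$id, hdr$bio_chars, cells, j) else
        j <- j + chars_width(hdr$bio_chars)
      prev <- bio$id
      for (blk in hdr$blocks) {
        if (blk$type == "intermediate") {
          width <- 1L + length(blk$params) + 1L + length(blk$chars)
          name_cell <- cells[[j]]
          sample_cell <- cells[[j + 1L + length(blk$params)]]
          if (nzchar(sample_cell)) {
            nodei <- get_or_create(prev, "container", sample_cell)
            maybe_apply(nodei$arc, name_cell, blk$params, cells, j + 1L)
            if (nodei$new) {
              k <- j + 2L + length(blk$params)
              for (ch in blk$chars) {
                if (nzchar(cells[[k]])) annotate(st, nodei$id, ch$name, cells[[k]])
                k <- k + 1L
              }
            }
            prev <- nodei$id
          }
          j <- j + width
        } else {
          name_cell <- cells[[j]]
          sample_cell <- cells[[j + 1L + length(blk$params)]]
          nodet <- get_or_create(prev, "container", sample_cell)
          maybe_apply(nodet$arc, name_cell, blk$params, cells, j + 1L)
          j <- j + 2L + length(blk$params)
          if (nodet$new) j <- set_chars(nodet$id, blk$chars, cells, j) else
            j <- j + chars_width(blk$chars)
        }
      }
    }

    afiles <- sm$fields[["Study Assay File Name"]] %||% character(0)
    atypes <- sm$fields[["Study Assay Measurement Type"]] %||% rep("", length(afiles))
    for (ai in seq_along(afiles)) {
      alines <- read_isatab_lines(file.path(dir, afiles[[ai]]))
      for (line in alines[-1]) {
        cells <- split_tsv(line)
        length(cells) <- 4L
        cells[is.na(cells)] <- ""
        parent_key <- paste0("container\x1f", cells[[1]])
        parent_id <- by_label[[parent_key]]
        if (is.null(parent_id)) next
        assay <- get_or_create(parent_id, "assay", cells[[3]], modality = atypes[[ai]])
        if (nzchar(cells[[2]]) &&
            is.null(st$arcs[[assay$arc$id]]$protocol_application)) {
          apply_protocol(st, assay$arc$id, protos[[cells[[2]]]])
        }
        if (assay$new && nzchar(cells[[4]])) {
          for (f in strsplit(cells[[4]], ";", fixed = TRUE)[[1]]) {
            st$nodes[[assay$id]]$attachments <-
              c(st$nodes[[assay$id]]$attachments,
                list(list(filename = f, uri_or_path = f,
                          checksum = NA_character_, size = NA_real_,
                          attached_to = assay$id)))
          }
        }
      }
    }
  }
  inv
}

isa_violation <- function(code, message, file = "", line = NA_integer_) {
  data.frame(code = code, message = message, file = file, line = line,
             stringsAsFactors = FALSE)
}

#' Structurally validate an ISA-Tab bundle
#'
#' Implements the core structural rules: the investigation file exists and
#' its sections appear in order (ONTOLOGY SOURCE REFERENCE, INVESTIGATION,
#' then STUDY blocks each containing STUDY PROTOCOLS and STUDY ASSAYS);
#' every referenced study/assay file exists; every Protocol REF value is
#' declared in STUDY PROTOCOLS; every Term Source REF is declared in the
#' ONTOLOGY SOURCE REFERENCE; and every assay-file Sample Name appears in
#' its study file. Always returns (never raises).
#'
#' @param dir Directory holding the bundle.
#' @return A data frame of violations (`code`, `message`, `file`, `line`);
#'   zero rows for a conformant bundle.
#' @export
validate_isatab <- function(dir) {
  out <- list()
  push <- function(v) out[[length(out) + 1L]] <<- v
  empty <- isa_violation("x", "x")[0, ]

  ifiles <- list.files(dir, pattern = "^i_.*\\.txt$")
  if (!length(ifiles)) {
    return(isa_violation("NO_INVESTIGATION_FILE",
                         "no i_*.txt investigation file found", dir))
  }
  ifile <- ifiles[[1]]
  lines <- read_isatab_lines(file.path(dir, ifile))
  secs <- lines[lines %in% SECTION_NAMES]

  # section order: OSR, INVESTIGATION, then (STUDY, STUDY PROTOCOLS,
  # STUDY ASSAYS)+
  ok_order <- length(secs) >= 5L &&
    identical(secs[1:2], c("ONTOLOGY SOURCE REFERENCE", "INVESTIGATION")) &&
    length(secs[-(1:2)]) %% 3L == 0L &&
    all(matrix(secs[-(1:2)], nrow = 3L) ==
          c("STUDY", "STUDY PROTOCOLS", "STUDY ASSAYS"))
  if (!ok_order) {
    push(isa_violation("SECTION_ORDER",
                       "investigation sections missing or out of order", ifile))
  }
  parsed <- parse_investigation_file(lines)
  declared_sources <- parsed$fields[["Term Source Name"]] %||% character(0)

  for (sm in parsed$studies) {
    sfile <- field1(sm$fields, "Study File Name")
    protos <- sm$fields[["Study Protocol Name"]] %||% character(0)
    afiles <- sm$fields[["Study Assay File Name"]] %||% character(0)
    sample_names <- character(0)

    if (!nzchar(sfile) || !file.exists(file.path(dir, sfile))) {
      push(isa_violation("MISSING_FILE",
                         sprintf("declared study file '%s' not found", sfile), ifile))
    } else {
      slines <- read_isatab_lines(file.path(dir, sfile))
      header <- split_tsv(slines[[1]])
      proto_cols <- which(header == "Protocol REF")
      tsr_cols <- which(header == "Term Source REF")
      sample_cols <- which(header %in% c("Sample Name", "Comment[Sample Name]"))
      for (li in seq_along(slines)[-1]) {
        cells <- split_tsv(slines[[li]])
        length(cells) <- length(header)
        cells[is.na(cells)] <- ""
        for (pc in proto_cols) {
          if (nzchar(cells[[pc]]) && !cells[[pc]] %in% protos) {
            push(isa_violation("UNDECLARED_PROTOCOL",
                               sprintf("Protocol REF '%s' not declared in STUDY PROTOCOLS",
                                       cells[[pc]]), sfile, li))
          }
        }
        for (tc in tsr_cols) {
          if (nzchar(cells[[tc]]) && !cells[[tc]] %in% declared_sources) {
            push(isa_violation("UNDECLARED_TERM_SOURCE",
                               sprintf("Term Source REF '%s' not declared", cells[[tc]]),
                               sfile, li))
          }
        }
        sample_names <- c(sample_names, cells[sample_cols])
      }
    }

    for (af in afiles) {
      if (!file.exists(file.path(dir, af))) {
        push(isa_violation("MISSING_FILE",
                           sprintf("declared assay file '%s' not found", af), ifile))
        next
      }
      alines <- read_isatab_lines(file.path(dir, af))
      aheader <- split_tsv(alines[[1]])
      scol <- which(aheader == "Sample Name")[1]
      pcol <- which(aheader == "Protocol REF")
      for (li in seq_along(alines)[-1]) {
        cells <- split_tsv(alines[[li]])
        length(cells) <- length(aheader)
        cells[is.na(cells)] <- ""
        if (!is.na(scol) && nzchar(cells[[scol]]) &&
            !cells[[scol]] %in% sample_names) {
          push(isa_violation("UNKNOWN_SAMPLE",
                             sprintf("assay Sample Name '%s' not in study file", cells[[scol]]),
                             af, li))
        }
        for (pc in pcol) {
          if (nzchar(cells[[pc]]) && !cells[[pc]] %in% protos) {
            push(isa_violation("UNDECLARED_PROTOCOL",
                               sprintf("Protocol REF '%s' not declared in STUDY PROTOCOLS",
                                       cells[[pc]]), af, li))
          }
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Canonical path signatures of a study graph
#'
#' Enumerates every root-to-assay path and renders it as a canonical string
#' covering node kinds, labels, annotations (sorted by name, with their
#' first attached term), protocol names and protocol parameters. Two
#' studies with identical sorted signatures are equivalent under the
#' ISA-Tab round-trip contract; protocol-application deviation text,
#' performer and date are deliberately excluded (they are not part of the
#' tabular output).
#'
#' @param study An `xr_study`.
#' @return Sorted character vector, one element per root-to-assay path.
#' @export
study_paths <- function(study) {
  node_sig <- function(id) {
    n <- study$nodes[[id]]
    anns <- vapply(n$annotations, function(a) {
      t <- first_term(a)
      paste0(a$name, "=", a$value,
             if (!is.null(t)) paste0("@", t$source, ":", t$accession) else "")
    }, character(1))
    paste(c(paste0(n$kind, "|", n$label,
                   if (n$kind == "assay") paste0("|", n$modality) else ""),
            sort(anns)), collapse = "{")
  }
  arc_sig <- function(parent, child) {
    pa <- arc_between(study, parent, child)$protocol_application
    if (is.null(pa)) return("->")
    pars <- vapply(names(pa$parameters) %||% character(0), function(p) {
      paste0(p, "=", pa$parameters[[p]])
    }, character(1))
    paste0("->", pa$protocol_name, "(", paste(sort(pars), collapse = ","), ")")
  }
  sigs <- character(0)
  for (p in enumerate_paths(study)) {
    chain <- p[-1]
    base <- node_sig(chain[[1]])
    if (length(chain) > 1L) {
      for (k in seq_len(length(chain) - 1L)) {
        base <- paste0(base, arc_sig(chain[[k]], chain[[k + 1]]),
                       node_sig(chain[[k + 1]]))
      }
    }
    tip <- chain[[length(chain)]]
    for (a in study$arcs) {
      if (a$parent_id == tip && study$nodes[[a$child_id]]$kind == "assay") {
        sigs <- c(sigs, paste0(base, arc_sig(tip, a$child_id),
                               node_sig(a$child_id)))
      }
    }
  }
  sort(sigs)
}
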