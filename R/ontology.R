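## Ontology lookup: OBO flat-file parsing, ranked term search, and the
## terminize traversal that offers candidate terms for every annotatable
## text field of a study graph. The lookup layer is deliberately decoupled
## from the graph model: an index can serve any client, including the JSON
## service adapter at the bottom of this file.

#' Parse an OBO 1.2 flat file into a searchable index
#'
#' Reads the `[Term]` stanzas of an OBO file; the tags `id`, `name`,
#' `synonym`, `def`, `is_obsolete`, `alt_id` and `namespace` are recognised,
#' everything else (typedefs, cross-products) is ignored — the service needs
#' lookup, not reasoning. Obsolete terms are retained in the index but
#' excluded from default search results.
#'
#' @param file Path to an OBO file.
#' @param source Short source name recorded on every term; defaults to the
#'   file name without extension, upper-cased.
#' @return An `obo_index` list with `term_count` terms.
#' @export
load_obo <- function(file, source = NULL) {
  if (!file.exists(file)) xr_abort("IOError", sprintf("cannot read '%s'", file))
  source <- source %||% toupper(tools::file_path_sans_ext(basename(file)))
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)

  terms <- list()
  stanza <- NULL
  stanza_line <- NA_integer_
  in_term <- FALSE

  finish <- function() {
    if (!in_term) return()
    if (is.null(stanza$id) || is.null(stanza$name)) {
      xr_abort("ParseError",
               sprintf("[Term] stanza at line %d lacks %s", stanza_line,
                       if (is.null(stanza$id)) "an id" else "a name"),
               line = stanza_line)
    }
    terms[[length(terms) + 1L]] <<- stanza
  }

  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (grepl("^\\[", line)) {
      finish()
      in_term <- identical(line, "[Term]")
      stanza <- list(synonyms = list(), alt_ids = character(0),
                     obsolete = FALSE, definition = "", namespace = "")
      stanza_line <- i
      next
    }
    if (!in_term || !nzchar(line) || !grepl(":", line, fixed = TRUE)) next
    tag <- sub(":.*$", "", line)
    val <- trimws(sub("^[^:]+:", "", line))
    if (tag == "id") stanza$id <- val
    else if (tag == "name") stanza$name <- val
    else if (tag == "def") {
      m <- regmatches(val, regexec("^\"(.*)\"", val))[[1]]
      stanza$definition <- if (length(m) == 2L) m[[2]] else val
    } else if (tag == "synonym") {
      m <- regmatches(val, regexec("^\"(.*)\"\\s*([A-Z]*)", val))[[1]]
      if (length(m) >= 2L) {
        stanza$synonyms[[length(stanza$synonyms) + 1L]] <-
          list(text = m[[2]], scope = if (nzchar(m[[3]])) m[[3]] else "RELATED")
      }
    } else if (tag == "is_obsolete") stanza$obsolete <- identical(val, "true")
    else if (tag == "alt_id") stanza$alt_ids <- c(stanza$alt_ids, val)
    else if (tag == "namespace") stanza$namespace <- val
  }
  finish()

  build_obo_index(terms, source)
}

build_obo_index <- function(terms, source) {
  syn_text <- lapply(terms, function(t) {
    vapply(t$synonyms, function(s) s$text, character(1))
  })
  name <- vapply(terms, function(t) t$name, character(1))
  name_lc <- tolower(name)
  syn_lc <- lapply(syn_text, tolower)
  tokens <- mapply(function(n, s) unique(unlist(strsplit(c(n, s), "\\s+"))),
                   name_lc, syn_lc, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  structure(list(
    accession = vapply(terms, function(t) t$id, character(1)),
    name = name,
    source = rep_len(source, length(terms)),
    obsolete = vapply(terms, function(t) isTRUE(t$obsolete), logical(1)),
    definition = vapply(terms, function(t) t$definition %||% "", character(1)),
    namespace = vapply(terms, function(t) t$namespace %||% "", character(1)),
    synonyms = lapply(terms, function(t) t$synonyms),
    alt_ids = lapply(terms, function(t) t$alt_ids),
    name_lc = name_lc,
    syn_lc = syn_lc,
    tokens = tokens,
    term_count = length(terms)
  ), class = "obo_index")
}

#' Merge ontology indexes from several sources
#'
#' @param ... `obo_index` objects (e.g. one per investigation ontology
#'   source).
#' @return A combined `obo_index`.
#' @export
merge_indexes <- function(...) {
  idx <- list(...)
  stopifnot(length(idx) >= 1L, all(vapply(idx, inherits, logical(1), "obo_index")))
  out <- list()
  for (f in c("accession", "name", "source", "obsolete", "definition",
              "namespace", "name_lc")) {
    out[[f]] <- unlist(lapply(idx, `[[`, f), use.names = FALSE)
  }
  for (f in c("synonyms", "alt_ids", "syn_lc", "tokens")) {
    out[[f]] <- do.call(c, lapply(idx, `[[`, f))
  }
  out$term_count <- length(out$accession)
  structure(out, class = "obo_index")
}

#' @export
print.obo_index <- function(x, ...) {
  cat(sprintf("<ontology index: %d term(s) from source(s) %s>\n",
              x$term_count, paste(unique(x$source), collapse = ", ")))
  invisible(x)
}

# Match ranking. A term's match type is the best of:
#   exact_name    (1.0)  query equals the term name (case-insensitive)
#   exact_synonym (0.9)  query equals a synonym
#   token         (0.7)  every whitespace token of the query occurs as a
#                        whole token of the name or a synonym
#   substring     (0.5)  query is a contiguous substring of name or synonym
MATCH_SCORES <- c(exact_name = 1.0, exact_synonym = 0.9, token = 0.7,
                  substring = 0.5)

#' Search an ontology index for a query string
#'
#' Ranks matching terms by match quality (exact name > exact synonym >
#' token > substring), ties broken by accession ascending; matching is
#' case-insensitive and fully deterministic. An empty or whitespace query
#' returns no matches.
#'
#' @param index An `obo_index`.
#' @param query Query text.
#' @param sources Restrict to these source short names (default: all in the
#'   index). Unknown names raise `NoSuchSource`.
#' @param limit Maximum number of matches (>= 1).
#' @param include_obsolete Include obsolete terms (default `FALSE`).
#' @return A data frame with columns `query`, `accession`, `name`, `source`,
#'   `match_type`, `score`, best first.
#' @export
search_terms <- function(index, query, sources = NULL, limit = 20L,
                         include_obsolete = FALSE) {
  stopifnot(inherits(index, "obo_index"))
  if (!is.numeric(limit) || limit < 1L) {
    xr_abort("InvalidLimit", "limit must be >= 1")
  }
  empty <- data.frame(query = character(0), accession = character(0),
                      name = character(0), source = character(0),
                      match_type = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (!is.null(sources)) {
    unknown <- setdiff(sources, unique(index$source))
    if (length(unknown)) {
      xr_abort("NoSuchSource",
               sprintf("unknown ontology source(s): %s", paste(unknown, collapse = ", ")))
    }
  }
  q <- tolower(trimws(query))
  if (!nzchar(q)) return(empty)

  keep <- rep_len(TRUE, index$term_count)
  if (!is.null(sources)) keep <- index$source %in% sources
  if (!include_obsolete) keep <- keep & !index$obsolete
  cand <- which(keep)
  if (!length(cand)) return(empty)

  nm <- index$name_lc[cand]
  syn <- index$syn_lc[cand]
  qtok <- unique(strsplit(q, "\\s+")[[1]])

  exact_name <- nm == q
  exact_syn <- vapply(syn, function(s) any(s == q), logical(1))
  token <- vapply(index$tokens[cand], function(t) all(qtok %in% t), logical(1))
  substr_hit <- grepl(q, nm, fixed = TRUE) |
    vapply(syn, function(s) any(grepl(q, s, fixed = TRUE)), logical(1))

  match_type <- rep_len(NA_character_, length(cand))
  match_type[substr_hit] <- "substring"
  match_type[token] <- "token"
  match_type[exact_syn] <- "exact_synonym"
  match_type[exact_name] <- "exact_name"

  hit <- !is.na(match_type)
  if (!any(hit)) return(empty)
  res <- data.frame(
    query = query,
    accession = index$accession[cand][hit],
    name = index$name[cand][hit],
    source = index$source[cand][hit],
    match_type = match_type[hit],
    score = unname(MATCH_SCORES[match_type[hit]]),
    stringsAsFactors = FALSE
  )
  res <- res[order(-res$score, res$accession), , drop = FALSE]
  res <- utils::head(res, limit)
  rownames(res) <- NULL
  res
}

#' Create an ontology term reference
#'
#' @param accession Term accession, e.g. `"ENVO:0000001"`.
#' @param name Term name.
#' @param source Short name of the ontology source.
#' @return An `xr_term` list.
#' @export
ontology_term <- function(accession, name, source) {
  structure(list(accession = accession, name = name, source = source),
            class = "xr_term")
}

as_term <- function(term) {
  if (inherits(term, "xr_term")) return(term)
  if (is.data.frame(term) && nrow(term) >= 1L) {
    return(ontology_term(term$accession[[1]], term$name[[1]], term$source[[1]]))
  }
  if (is.list(term) && !is.null(term$accession)) {
    return(ontology_term(term$accession, term$name %||% "", term$source))
  }
  xr_abort("InvalidTerm", "cannot interpret object as an ontology term")
}

#' Attach an ontology term to an annotation field
#'
#' Appends a term reference to the name- or value-term list of a node
#' annotation. The term's source must be among the investigation's declared
#' ontology sources; attaching the same (source, accession) twice is a
#' no-op.
#'
#' @param study An `xr_study` belonging to an investigation.
#' @param node_id Node carrying the annotation.
#' @param annotation_name Name of the annotation (first occurrence).
#' @param term An `xr_term`, or one row of a [search_terms()] result.
#' @param slot Attach to the annotation `"value"` (default) or `"name"`.
#' @return The updated node, invisibly.
#' @export
attach_term <- function(study, node_id, annotation_name, term,
                        slot = c("value", "name")) {
  slot <- match.arg(slot)
  term <- as_term(term)
  inv <- study$investigation
  declared <- if (is.null(inv)) character(0) else
    vapply(inv$ontology_sources, function(s) s$short_name, character(1))
  if (!term$source %in% declared) {
    xr_abort("SourceNotRegistered",
             sprintf("source '%s' is not among the investigation's ontology sources",
                     term$source))
  }
  node <- get_node(study, node_id)
  idx <- which(vapply(node$annotations, function(a) a$name == annotation_name,
                      logical(1)))
  if (!length(idx)) {
    xr_abort("NoSuchAnnotation",
             sprintf("node '%s' has no annotation named '%s'", node_id, annotation_name))
  }
  field <- paste0(slot, "_terms")
  terms <- node$annotations[[idx[1]]][[field]]
  dup <- any(vapply(terms, function(t) {
    t$source == term$source && t$accession == term$accession
  }, logical(1)))
  if (!dup) {
    terms <- c(terms, list(term))
    study$nodes[[node_id]]$annotations[[idx[1]]][[field]] <- terms
  }
  invisible(study$nodes[[node_id]])
}

#' Offer candidate ontology terms for every text field of a study
#'
#' Terminize traverses the study graph breadth-first from the root (arcs
#' visited directly after their child node) and submits every node label,
#' annotation name, annotation value and protocol-application action text to
#' [search_terms()], collecting the ranked candidates. Fields with no
#' matches are reported with empty candidate lists, so the report enumerates
#' exactly the annotatable surface of the graph.
#'
#' @param study An `xr_study`.
#' @param index An `obo_index`.
#' @param sources Optional source restriction, as in [search_terms()].
#' @param limit Candidates per field.
#' @return A `terminize_report`: list of entries with `entity_id`, `entity`
#'   (`"node"`/`"arc"`), `field`, `query` and `matches` (a data frame).
#' @export
terminize <- function(study, index, sources = NULL, limit = 10L) {
  stopifnot(inherits(study, "xr_study"))
  entries <- list()
  add <- function(entity, id, field, query) {
    matches <- search_terms(index, query, sources = sources, limit = limit)
    entries[[length(entries) + 1L]] <<- list(
      entity = entity, entity_id = id, field = field, query = query,
      matches = matches
    )
  }
  order <- bfs_order(study)
  arc_children <- vapply(study$arcs, function(a) a$child_id, character(1))
  for (id in order) {
    node <- study$nodes[[id]]
    add("node", id, "label", node$label)
    for (i in seq_along(node$annotations)) {
      ann <- node$annotations[[i]]
      add("node", id, sprintf("annotation[%d].name", i), ann$name)
      add("node", id, sprintf("annotation[%d].value", i), ann$value)
    }
    for (aid in names(study$arcs)[arc_children == id]) {
      pa <- study$arcs[[aid]]$protocol_application
      if (!is.null(pa)) {
        add("arc", aid, "protocol_application.action", pa$action)
      }
    }
  }
  structure(list(study_id = study$id, entries = entries),
            class = "terminize_report")
}

#' @export
print.terminize_report <- function(x, ...) {
  nonempty <- sum(vapply(x$entries, function(e) nrow(e$matches) > 0L, logical(1)))
  cat(sprintf("<terminize report for study '%s': %d field(s) scanned, %d with candidates>\n",
              x$study_id, length(x$entries), nonempty))
  invisible(x)
}

#' Serialize lookup results as JSON
#'
#' The service-facing representation of the lookup contract: a search
#' response is `{"query": ..., "matches": [{"accession", "name", "source",
#' "match_type", "score"}]}`; a terminize report is the corresponding array
#' of per-field entries. Byte-identical for identical inputs.
#'
#' @param x A [search_terms()] result (with `query` attribute-free columns)
#'   or a `terminize_report`.
#' @param query The query string (search results only; defaults to the
#'   column value).
#' @return A JSON string.
#' @export
lookup_json <- function(x, query = NULL) {
  fmt_matches <- function(m) {
    lapply(seq_len(nrow(m)), function(i) {
      list(accession = m$accession[[i]], name = m$name[[i]],
           source = m$source[[i]], match_type = m$match_type[[i]],
           score = m$score[[i]])
    })
  }
  if (inherits(x, "terminize_report")) {
    payload <- list(
      study = x$study_id,
      entries = lapply(x$entries, function(e) {
        list(entity = e$entity, entity_id = e$entity_id, field = e$field,
             query = e$query, matches = fmt_matches(e$matches))
      })
    )
  } else {
    payload <- list(
      query = query %||% (if (nrow(x)) x$query[[1]] else ""),
      matches = fmt_matches(x)
    )
  }
  as.character(canonical_json(payload))
}
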