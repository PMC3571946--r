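## The expgraph-1 store: a versioned, JSON-compatible structured text
## document persisting users, access groups, the protocol registry and
## every investigation (studies, nodes, arcs, annotations, protocol
## applications, templates, permission state). This is the CLI's native
## load/save format; serialization is canonical so identical stores are
## byte-identical on disk.

STORE_FORMAT <- "expgraph-1"

#' Create an empty store
#'
#' A store bundles everything one deployment persists: users, a protocol
#' registry, access groups and investigations.
#'
#' @return An `xr_store` environment.
#' @export
expgraph_store <- function() {
  store <- new.env(parent = emptyenv())
  store$users <- list()
  store$registry <- protocol_registry()
  store$groups <- list()
  store$investigations <- list()
  class(store) <- "xr_store"
  store
}

#' Register pieces in a store
#'
#' @param store An `xr_store`.
#' @param x A user, access group or investigation.
#' @return The store, invisibly.
#' @export
store_add <- function(store, x) {
  stopifnot(inherits(store, "xr_store"))
  if (inherits(x, "xr_user")) store$users[[x$id]] <- x
  else if (inherits(x, "xr_access_group")) store$groups[[x$id]] <- x
  else if (inherits(x, "xr_investigation")) {
    store$investigations[[x$id]] <- x
    store$groups[[x$access_group$id]] <- x$access_group
  } else xr_abort("InvalidStoreItem", "cannot store object of this class")
  invisible(store)
}

## ---- object -> plain list --------------------------------------------

grants_to_list <- function(grants) {
  lapply(unname(grants), function(g) list(group = g$group$id, level = g$level))
}

annotation_to_list <- function(a) {
  list(name = a$name, value = a$value,
       name_terms = lapply(a$name_terms, unclass),
       value_terms = lapply(a$value_terms, unclass))
}

node_to_list <- function(n) {
  out <- list(id = n$id, kind = n$kind, label = n$label,
              annotations = lapply(n$annotations, annotation_to_list),
              attachments = n$attachments)
  if (n$kind == "biosource") out$miabs <- as.list(n$miabs)
  if (n$kind == "assay") {
    out$modality <- n$modality
    out$external_link <- n$external_link
  }
  out
}

study_to_list <- function(st) {
  list(
    id = st$id, title = st$title, owner = st$owner,
    grants = grants_to_list(st$grants),
    root_id = st$root_id,
    node_counter = st$node_counter, arc_counter = st$arc_counter,
    nodes = lapply(unname(st$nodes), node_to_list),
    arcs = lapply(unname(st$arcs), function(a) a)
  )
}

investigation_to_list <- function(inv) {
  list(
    id = inv$id, title = inv$title, description = inv$description,
    owner = inv$owner,
    ontology_sources = lapply(inv$ontology_sources, unclass),
    access_group = list(id = inv$access_group$id,
                        members = as.list(inv$access_group$members)),
    grants = grants_to_list(inv$grants),
    study_counter = inv$study_counter,
    studies = lapply(unname(inv$studies), study_to_list)
  )
}

store_to_list <- function(store) {
  list(
    format = STORE_FORMAT,
    users = lapply(unname(store$users), unclass),
    groups = lapply(unname(store$groups), function(g) {
      list(id = g$id, members = as.list(g$members))
    }),
    protocols = lapply(unname(store$registry$protocols), function(p) {
      list(id = p$id, name = p$name, text = p$text, owner = p$owner,
           grants = grants_to_list(p$grants), comments = p$comments)
    }),
    protocol_counter = store$registry$counter,
    investigations = lapply(unname(store$investigations), investigation_to_list)
  )
}

#' Save a store as an expgraph-1 document
#'
#' @param store An `xr_store`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expgraph <- function(store, path) {
  write_lines_lf(as.character(canonical_json(store_to_list(store))), path)
}

#' Canonical serialization of one study
#'
#' The byte-comparison form used by determinism checks: identical studies
#' (same construction history) serialize identically.
#'
#' @param study An `xr_study`.
#' @return A JSON string.
#' @export
study_json <- function(study) {
  as.character(canonical_json(study_to_list(study)))
}

## ---- plain list -> objects -------------------------------------------

resolve_grants <- function(glist, groups) {
  out <- list()
  for (g in glist) {
    grp <- groups[[g$group]]
    if (!is.null(grp)) out[[grp$id]] <- list(group = grp, level = g$level)
  }
  out
}

list_to_study <- function(sl, inv, groups) {
  st <- new.env(parent = emptyenv())
  st$id <- sl$id
  st$title <- sl$title
  st$owner <- sl$owner
  st$grants <- resolve_grants(sl$grants, groups)
  st$investigation <- inv
  st$root_id <- sl$root_id
  st$node_counter <- as.integer(sl$node_counter)
  st$arc_counter <- as.integer(sl$arc_counter)
  nodes <- lapply(sl$nodes, function(nl) {
    n <- new_node(nl$id, nl$kind, nl$label, nl$modality)
    n$annotations <- lapply(nl$annotations, function(al) {
      a <- new_annotation(al$name, al$value)
      a$name_terms <- lapply(al$name_terms, function(t) do.call(ontology_term, t))
      a$value_terms <- lapply(al$value_terms, function(t) do.call(ontology_term, t))
      a
    })
    n$attachments <- nl$attachments
    if (nl$kind == "biosource" && length(nl$miabs)) {
      n$miabs <- unlist(nl$miabs)
    }
    n
  })
  st$nodes <- stats::setNames(nodes, vapply(nodes, `[[`, character(1), "id"))
  arcs <- lapply(sl$arcs, function(al) {
    a <- new_arc(al$id, al$parent_id, al$child_id)
    if (!is.null(al$protocol_application)) {
      pa <- al$protocol_application
      pa$parameters <- as.list(pa$parameters)
      a$protocol_application <- pa
    }
    a$attachments <- al$attachments %||% list()
    a
  })
  st$arcs <- stats::setNames(arcs, vapply(arcs, `[[`, character(1), "id"))
  class(st) <- "xr_study"
  st
}

#' Load a store from an expgraph-1 document
#'
#' @param path File written by [write_expgraph()].
#' @return An `xr_store`.
#' @export
read_expgraph <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, STORE_FORMAT)) {
    xr_abort("UnknownFormat",
             sprintf("expected an %s document, found format '%s'",
                     STORE_FORMAT, doc$format %||% "<none>"))
  }
  store <- expgraph_store()
  for (u in doc$users) store$users[[u$id]] <- xr_user(u$id, u$name)
  for (g in doc$groups) {
    store$groups[[g$id]] <- access_group(g$id, unlist(g$members) %||% character(0))
  }
  for (pl in doc$protocols) {
    p <- new.env(parent = emptyenv())
    p$id <- pl$id
    p$name <- pl$name
    p$text <- pl$text
    p$owner <- pl$owner
    p$grants <- resolve_grants(pl$grants, store$groups)
    p$comments <- pl$comments
    p$registered <- TRUE
    lockBinding("text", p)
    class(p) <- "xr_protocol"
    store$registry$protocols[[p$id]] <- p
  }
  store$registry$counter <- as.integer(doc$protocol_counter %||% length(doc$protocols))
  for (il in doc$investigations) {
    inv <- new.env(parent = emptyenv())
    inv$id <- il$id
    inv$title <- il$title
    inv$description <- il$description
    inv$owner <- il$owner
    inv$ontology_sources <- lapply(il$ontology_sources, function(s) {
      ontology_source(s$short_name, s$file, s$version %||% "", s$description %||% "")
    })
    inv$access_group <- store$groups[[il$access_group$id]] %||%
      access_group(il$access_group$id, unlist(il$access_group$members))
    inv$grants <- resolve_grants(il$grants, store$groups)
    inv$study_counter <- as.integer(il$study_counter)
    class(inv) <- "xr_investigation"
    studies <- lapply(il$studies, list_to_study, inv = inv, groups = store$groups)
    inv$studies <- stats::setNames(studies,
                                   vapply(studies, `[[`, character(1), "id"))
    store$investigations[[inv$id]] <- inv
    store$groups[[inv$access_group$id]] <- inv$access_group
  }
  store
}
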