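## The typed provenance graph of one study.
##
## Other than the root, a graph contains only three kinds of nodes —
## biosources (raw biological input material), containers (tubes, dishes,
## flasks holding extracted material) and assays (measurement events). Arcs
## always represent laboratory actions, except arcs out of the root, which
## represent the inclusion of a biosource in the study and therefore carry
## no protocol application. The legal parent/child pairs are:
##   root -> biosource, biosource -> container,
##   container -> container, container -> assay.
## Pooling gives a container (or assay) several parents; biosources always
## have exactly one parent, the root. Assays are sinks.

LEGAL_CHILD <- list(
  root = "biosource",
  biosource = "container",
  container = c("container", "assay")
)

NODE_KINDS <- c("root", "biosource", "container", "assay")

new_node <- function(id, kind, label, modality = NULL) {
  node <- list(id = id, kind = kind, label = label,
               annotations = list(), attachments = list())
  if (kind == "biosource") node$miabs <- character(0)
  if (kind == "assay") {
    node$modality <- modality %||% "unspecified"
    node$template_ref <- NULL
    node$external_link <- NULL
  }
  node
}

new_arc <- function(id, parent_id, child_id) {
  list(id = id, parent_id = parent_id, child_id = child_id,
       protocol_application = NULL, attachments = list())
}

#' Retrieve a node or arc by id
#'
#' @param study An `xr_study`.
#' @param id Node (or arc) identifier.
#' @return The node (arc) as a list.
#' @export
get_node <- function(study, id) {
  node <- study$nodes[[id]]
  if (is.null(node)) xr_abort("NoSuchNode", sprintf("no node with id '%s'", id))
  node
}

#' @rdname get_node
#' @export
get_arc <- function(study, id) {
  arc <- study$arcs[[id]]
  if (is.null(arc)) xr_abort("NoSuchArc", sprintf("no arc with id '%s'", id))
  arc
}

node_kind <- function(study, id) get_node(study, id)$kind

assert_legal_pair <- function(parent_kind, child_kind) {
  if (!child_kind %in% (LEGAL_CHILD[[parent_kind]] %||% character(0))) {
    xr_abort("IllegalChildKind",
             sprintf("a %s node may not have a %s child", parent_kind, child_kind))
  }
}

next_node_id <- function(study) {
  study$node_counter <- study$node_counter + 1L
  paste0("n", study$node_counter)
}

link_nodes <- function(study, parent_id, child_id, check = TRUE) {
  if (check) {
    assert_legal_pair(node_kind(study, parent_id), node_kind(study, child_id))
  }
  for (a in study$arcs) {
    if (a$parent_id == parent_id && a$child_id == child_id) {
      xr_abort("DuplicateArc",
               sprintf("arc %s -> %s already exists", parent_id, child_id))
    }
  }
  study$arc_counter <- study$arc_counter + 1L
  id <- paste0("a", study$arc_counter)
  study$arcs[[id]] <- new_arc(id, parent_id, child_id)
  study$arcs[[id]]
}

#' Add a child node to a study graph
#'
#' Node construction is constrained by the kind of the parent: the root may
#' only parent biosources, a biosource must have container children, and a
#' container may parent another container or an assay. A connecting arc is
#' created; arcs from the root never carry a protocol application.
#'
#' @param study An `xr_study`.
#' @param parent_id Id of the parent node.
#' @param kind One of `"biosource"`, `"container"`, `"assay"`.
#' @param label Display label of the new node.
#' @param modality Assay modality (e.g. `"sequencing"`, `"imaging"`); assays
#'   only.
#' @return The new node (with its `$id`).
#' @export
#' @examples
#' inv <- create_investigation("Example", list(), xr_user("alice"))
#' st <- add_study(inv, "Study 1")
#' b <- add_child(st, st$root_id, "biosource", "chicken")
#' ct <- add_child(st, b$id, "container", "petri dish")
add_child <- function(study, parent_id, kind, label, modality = NULL) {
  stopifnot(inherits(study, "xr_study"))
  kind <- match.arg(kind, NODE_KINDS[-1])
  assert_legal_pair(node_kind(study, parent_id), kind)
  id <- next_node_id(study)
  study$nodes[[id]] <- new_node(id, kind, label, modality)
  link_nodes(study, parent_id, id, check = FALSE)
  study$nodes[[id]]
}

#' Pool several nodes into one child
#'
#' Pooling combines material from two or more parents of the same kind into
#' a single container (or a jointly measured assay); the pooled node carries
#' one incoming arc per parent. Splitting is the converse and needs no
#' dedicated operation: call [add_child()] repeatedly on the same parent.
#'
#' @inheritParams add_child
#' @param parent_ids At least two node ids, all of the same kind.
#' @return The new pooled node.
#' @export
pool <- function(study, parent_ids, kind, label, modality = NULL) {
  stopifnot(inherits(study, "xr_study"))
  if (length(parent_ids) < 2L) {
    xr_abort("PoolArityError", "pooling requires at least two parent nodes")
  }
  kinds <- vapply(parent_ids, function(p) node_kind(study, p), character(1))
  if (length(unique(kinds)) != 1L) {
    xr_abort("MixedSelection", "pooled parents must all be of the same kind")
  }
  kind <- match.arg(kind, c("container", "assay"))
  assert_legal_pair(kinds[[1]], kind)
  id <- next_node_id(study)
  study$nodes[[id]] <- new_node(id, kind, label, modality)
  for (p in parent_ids) link_nodes(study, p, id, check = FALSE)
  study$nodes[[id]]
}

#' Add one child of the same kind to each selected parent
#'
#' The bulk counterpart of [add_child()]: a time saver for repetitive
#' experiments. Only available for selections of a single node kind.
#'
#' @inheritParams add_child
#' @param parent_ids Node ids, all of the same kind.
#' @param label_prefix Children are labelled `label_prefix` + 1..n.
#' @return List of the new nodes, one per parent, in parent order.
#' @export
bulk_add_children <- function(study, parent_ids, kind, label_prefix,
                              modality = NULL) {
  stopifnot(inherits(study, "xr_study"))
  if (length(parent_ids) == 0L) return(list())
  kinds <- vapply(parent_ids, function(p) node_kind(study, p), character(1))
  if (length(unique(kinds)) != 1L) {
    xr_abort("MixedSelection",
             "bulk child addition is only available for nodes of the same kind")
  }
  assert_legal_pair(kinds[[1]], kind)
  lapply(seq_along(parent_ids), function(i) {
    add_child(study, parent_ids[[i]], kind, paste0(label_prefix, i), modality)
  })
}

#' Duplicate a biosource and all its annotation
#'
#' Creates a fresh biosource child of the root whose annotations and
#' minimum-information (MIABS) fields are deep copies of the original;
#' attachments are shared by reference and descendants are not copied.
#'
#' @param study An `xr_study`.
#' @param node_id Id of a biosource node.
#' @return The new node.
#' @export
duplicate_biosource <- function(study, node_id) {
  orig <- get_node(study, node_id)
  if (orig$kind != "biosource") {
    xr_abort("KindError", "only biosource nodes can be duplicated")
  }
  copy <- add_child(study, study$root_id, "biosource", orig$label)
  id <- copy$id
  study$nodes[[id]]$annotations <- orig$annotations
  study$nodes[[id]]$miabs <- orig$miabs
  study$nodes[[id]]$attachments <- orig$attachments
  study$nodes[[id]]
}

new_annotation <- function(name, value) {
  if (!is.character(name) || !nzchar(name)) {
    xr_abort("EmptyAnnotationName", "annotation name must be non-empty")
  }
  list(name = name, value = as.character(value),
       name_terms = list(), value_terms = list())
}

#' Annotate a node with a name/value pair
#'
#' Name/value pairs may be added to any graph node; names need not be unique
#' and order is preserved.
#'
#' @param study An `xr_study`.
#' @param node_id Target node.
#' @param name,value The pair to append.
#' @return The updated node, invisibly.
#' @export
annotate <- function(study, node_id, name, value) {
  node <- get_node(study, node_id)
  study$nodes[[node$id]]$annotations <-
    c(node$annotations, list(new_annotation(name, value)))
  invisible(study$nodes[[node$id]])
}

#' Set a minimum-information (MIABS) field on a biosource
#'
#' MIABS captures sample details that matter regardless of assay technology.
#' The conventional fields are species, strain, genetic_modification, sex,
#' age, tissue and treatment, but the set is extensible.
#'
#' @param study An `xr_study`.
#' @param node_id A biosource node id.
#' @param field,value Field name and text value.
#' @return The updated node, invisibly.
#' @export
set_miabs <- function(study, node_id, field, value) {
  node <- get_node(study, node_id)
  if (node$kind != "biosource") {
    xr_abort("KindError", "MIABS fields belong to biosource nodes")
  }
  study$nodes[[node$id]]$miabs[[field]] <- as.character(value)
  invisible(study$nodes[[node$id]])
}

#' Edit an annotation on several nodes at once
#'
#' Sets the named annotation to `value` on every selected node: replaced in
#' place if the node already carries an annotation of that name (first
#' match), appended otherwise. Only available for selections of one kind.
#'
#' @param study An `xr_study`.
#' @param node_ids Node ids, all of the same kind (may be empty).
#' @param name,value The annotation to set.
#' @return The number of nodes edited.
#' @export
bulk_edit <- function(study, node_ids, name, value) {
  stopifnot(inherits(study, "xr_study"))
  if (length(node_ids) == 0L) return(0L)
  kinds <- vapply(node_ids, function(p) node_kind(study, p), character(1))
  if (length(unique(kinds)) != 1L) {
    xr_abort("MixedSelection", "bulk edit is only available for nodes of the same kind")
  }
  for (id in node_ids) {
    anns <- study$nodes[[id]]$annotations
    hit <- which(vapply(anns, function(a) a$name == name, logical(1)))
    if (length(hit)) {
      anns[[hit[1]]]$value <- as.character(value)
    } else {
      anns <- c(anns, list(new_annotation(name, value)))
    }
    study$nodes[[id]]$annotations <- anns
  }
  length(node_ids)
}

#' Attach an opaque file to a node or arc
#'
#' Files are treated as opaque blobs: the path/URI, size and an MD5 checksum
#' are recorded at attach time, content is never interpreted. If the path
#' does not exist locally (a URI into an external store), size and checksum
#' are recorded as unknown.
#'
#' @param study An `xr_study`.
#' @param id A node or arc id.
#' @param uri_or_path Location of the file.
#' @param filename Display name; defaults to the basename.
#' @return The attachment record, invisibly.
#' @export
attach_file <- function(study, id, uri_or_path, filename = basename(uri_or_path)) {
  att <- list(filename = filename, uri_or_path = uri_or_path,
              checksum = NA_character_, size = NA_real_, attached_to = id)
  if (file.exists(uri_or_path)) {
    att$checksum <- unname(tools::md5sum(uri_or_path))
    att$size <- file.size(uri_or_path)
  }
  if (!is.null(study$nodes[[id]])) {
    study$nodes[[id]]$attachments <- c(study$nodes[[id]]$attachments, list(att))
  } else if (!is.null(study$arcs[[id]])) {
    study$arcs[[id]]$attachments <- c(study$arcs[[id]]$attachments, list(att))
  } else {
    xr_abort("NoSuchNode", sprintf("no node or arc with id '%s'", id))
  }
  invisible(att)
}

#' Apply a protocol to an action (arc)
#'
#' Attaches a registered protocol to a non-root arc, together with an
#' `action` field recording any deviations from the protocol text, ordered
#' parameters, and optionally the performer and date. Re-applying replaces
#' the previous application (one protocol application per arc).
#'
#' @param study An `xr_study`.
#' @param arc_id Arc id; must not be an arc out of the root.
#' @param protocol A protocol registered with [register_protocol()].
#' @param action Free text recording deviations (may be empty).
#' @param parameters Named list of parameter values, order preserved.
#' @param performer,date Optional user and ISO-8601 date.
#' @return The updated arc, invisibly.
#' @export
apply_protocol <- function(study, arc_id, protocol, action = "",
                           parameters = list(), performer = NULL, date = NULL) {
  arc <- get_arc(study, arc_id)
  if (node_kind(study, arc$parent_id) == "root") {
    xr_abort("RootArcError",
             "arcs from the root represent inclusion of a biosource and carry no protocol")
  }
  if (!inherits(protocol, "xr_protocol") || !isTRUE(protocol$registered)) {
    xr_abort("NoSuchProtocol", "protocol is not registered")
  }
  study$arcs[[arc$id]]$protocol_application <- list(
    protocol_id = protocol$id,
    protocol_name = protocol$name,
    action = action,
    parameters = parameters,
    performer = if (!is.null(performer)) user_id(performer) else NULL,
    date = date
  )
  invisible(study$arcs[[arc$id]])
}

#' Delete a node from the graph
#'
#' Deleting a node with children requires an explicit `cascade` flag; with
#' it, every descendant left unreachable from the root is removed along with
#' all incident arcs.
#'
#' @param study An `xr_study`.
#' @param node_id Node to delete (not the root).
#' @param cascade Remove unreachable descendants too.
#' @return Ids of the removed nodes, invisibly.
#' @export
delete_node <- function(study, node_id, cascade = FALSE) {
  node <- get_node(study, node_id)
  if (node$kind == "root") xr_abort("KindError", "the root node cannot be deleted")
  children <- vapply(study$arcs, function(a) a$parent_id == node_id, logical(1))
  if (any(children) && !cascade) {
    xr_abort("CascadeRequired",
             sprintf("node '%s' has children; pass cascade = TRUE to delete the subtree",
                     node_id))
  }
  study$nodes[[node_id]] <- NULL
  study$arcs <- Filter(function(a) a$parent_id != node_id && a$child_id != node_id,
                       study$arcs)
  removed <- node_id
  if (cascade) {
    reach <- reachable_from(study, study$root_id)
    orphans <- setdiff(names(study$nodes), reach)
    for (o in orphans) study$nodes[[o]] <- NULL
    study$arcs <- Filter(function(a) a$parent_id %in% reach && a$child_id %in% reach,
                         study$arcs)
    removed <- c(removed, orphans)
  }
  invisible(removed)
}

reachable_from <- function(study, start) {
  seen <- character(0)
  frontier <- start
  parents <- vapply(study$arcs, function(a) a$parent_id, character(1))
  children <- vapply(study$arcs, function(a) a$child_id, character(1))
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(children[parents %in% frontier]), seen)
  }
  seen
}

violation <- function(code, ids, message) {
  data.frame(code = code, ids = paste(ids, collapse = ","),
             message = message, stringsAsFactors = FALSE)
}

#' Validate a study graph
#'
#' Batch-checks every structural invariant of the typed provenance graph and
#' returns a data frame of violations (zero rows for a legal graph). Codes:
#' `UNIQUE_ROOT` (not exactly one root, or a root with a parent),
#' `ILLEGAL_CHILD` (parent/child kinds outside the typing table),
#' `CYCLE`, `DISCONNECTED` (node unreachable from the root),
#' `ROOT_ARC_PROTOCOL` (protocol application on a root arc) and
#' `MULTIPARENT_KIND` (a pooled node that is not a container or assay).
#' Graphs built exclusively through the constructor operations always
#' validate clean.
#'
#' @param study An `xr_study`.
#' @return A data frame with columns `code`, `ids`, `message`.
#' @export
validate_graph <- function(study) {
  v <- list()
  nodes <- study$nodes
  arcs <- study$arcs
  kinds <- vapply(nodes, function(n) n$kind, character(1))
  parents <- vapply(arcs, function(a) a$parent_id, character(1))
  children <- vapply(arcs, function(a) a$child_id, character(1))

  roots <- names(nodes)[kinds == "root"]
  if (length(roots) != 1L || !identical(roots, study$root_id) ||
      study$root_id %in% children) {
    v <- c(v, list(violation("UNIQUE_ROOT", roots,
                             "graph must have a single, unique, parentless root")))
  }

  for (a in arcs) {
    pk <- kinds[[a$parent_id]] %||% NA_character_
    ck <- kinds[[a$child_id]] %||% NA_character_
    if (is.na(pk) || is.na(ck) || !ck %in% (LEGAL_CHILD[[pk]] %||% character(0))) {
      v <- c(v, list(violation("ILLEGAL_CHILD", c(a$parent_id, a$child_id),
                               sprintf("arc %s: %s -> %s violates the typing table",
                                       a$id, pk, ck))))
    }
    if (!is.na(pk) && pk == "root" && !is.null(a$protocol_application)) {
      v <- c(v, list(violation("ROOT_ARC_PROTOCOL", a$id,
                               "arcs from the root carry no protocol application")))
    }
  }

  for (id in names(nodes)) {
    nparents <- sum(children == id)
    if (nparents > 1L && !kinds[[id]] %in% c("container", "assay")) {
      v <- c(v, list(violation("MULTIPARENT_KIND", id,
                               sprintf("%s node '%s' has %d parents; only pooled containers/assays may",
                                       kinds[[id]], id, nparents))))
    }
  }

  # Cycle detection: iteratively strip sink nodes; leftovers are cyclic.
  remaining <- names(nodes)
  es <- cbind(parents, children)
  repeat {
    sinks <- setdiff(remaining, es[es[, 2] %in% remaining & es[, 1] %in% remaining, 1])
    if (length(sinks) == 0L) break
    remaining <- setdiff(remaining, sinks)
    if (length(remaining) == 0L) break
  }
  if (length(remaining)) {
    v <- c(v, list(violation("CYCLE", remaining, "graph contains a cycle")))
  }

  if (length(roots) == 1L) {
    unreachable <- setdiff(names(nodes), reachable_from(study, roots))
    if (length(unreachable)) {
      v <- c(v, list(violation("DISCONNECTED", unreachable,
                               "node(s) unreachable from the root")))
    }
  }

  if (length(v)) do.call(rbind, v) else
    data.frame(code = character(0), ids = character(0), message = character(0),
               stringsAsFactors = FALSE)
}

# Breadth-first node order from the root; children in arc-insertion order,
# pooled nodes visited at first encounter. Used by terminize, reports and
# export so traversal order is deterministic everywhere.
bfs_order <- function(study) {
  parents <- vapply(study$arcs, function(a) a$parent_id, character(1))
  children <- vapply(study$arcs, function(a) a$child_id, character(1))
  order <- character(0)
  queue <- study$root_id
  while (length(queue)) {
    id <- queue[[1]]
    queue <- queue[-1]
    if (id %in% order) next
    order <- c(order, id)
    kids <- children[parents == id]
    queue <- c(queue, kids[!kids %in% order])
  }
  order
}

# All root -> assay-input paths: sequences of node ids from the root down to
# each container that parents at least one assay, one path per distinct
# parent route (pooled containers appear once per route). The exporter's
# row-count law is defined on these paths.
enumerate_paths <- function(study) {
  parents <- vapply(study$arcs, function(a) a$parent_id, character(1))
  children <- vapply(study$arcs, function(a) a$child_id, character(1))
  kinds <- vapply(study$nodes, function(n) n$kind, character(1))
  assay_inputs <- unique(parents[kinds[children] == "assay"])
  paths <- list()
  walk <- function(path) {
    tip <- path[[length(path)]]
    if (tip %in% assay_inputs) paths[[length(paths) + 1L]] <<- path
    for (kid in children[parents == tip]) {
      if (kinds[[kid]] != "assay") walk(c(path, kid))
    }
  }
  if (length(study$arcs)) walk(study$root_id)
  paths
}
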