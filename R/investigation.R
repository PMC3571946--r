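## Investigations and studies: the container hierarchy of the data model.
## An investigation owns a list of studies; each study is a typed provenance
## graph (see graph.R). Both are environments so that graph-editing
## operations mutate in place, like a data store handle.

#' Declare an ontology source
#'
#' An investigation carries a fixed set of ontology sources so that all
#' annotation within it draws on consistent, compatible vocabularies. Terms
#' may only be attached from declared sources.
#'
#' @param short_name Short unique name, e.g. `"ENVO"`.
#' @param file Path to the OBO file backing the source (optional until
#'   lookup is needed).
#' @param version,description Free-text metadata.
#' @return An `xr_ontology_source` list.
#' @export
ontology_source <- function(short_name, file = NULL, version = "", description = "") {
  stopifnot(is.character(short_name), nzchar(short_name))
  structure(
    list(short_name = short_name, file = file, version = version,
         description = description),
    class = "xr_ontology_source"
  )
}

#' Create an investigation
#'
#' The investigation is the root item of the data model: a container for a
#' collection of studies, with a fixed list of ontology sources and its own
#' automatically created access group. A new investigation is private to its
#' creator, who holds full permission.
#'
#' @param title Non-empty title; also used to derive the investigation id.
#' @param ontology_sources List of [ontology_source()] objects with unique
#'   short names.
#' @param owner The creating user.
#' @param description Free text.
#' @return An `xr_investigation` environment with an empty study list and a
#'   fresh access group containing only the owner.
#' @export
#' @examples
#' inv <- create_investigation("Chick infection study",
#'                             list(ontology_source("TOY")), xr_user("alice"))
create_investigation <- function(title, ontology_sources = list(), owner,
                                 description = "") {
  if (!is.character(title) || length(title) != 1L || !nzchar(trimws(title))) {
    xr_abort("InvalidTitle", "investigation title must be non-empty")
  }
  shorts <- vapply(ontology_sources, function(s) s$short_name, character(1))
  if (anyDuplicated(shorts)) {
    xr_abort("DuplicateOntologySource",
             sprintf("duplicate ontology source short name(s): %s",
                     paste(unique(shorts[duplicated(shorts)]), collapse = ", ")))
  }
  inv <- new.env(parent = emptyenv())
  inv$id <- slugify(title)
  inv$title <- title
  inv$description <- description
  inv$ontology_sources <- ontology_sources
  inv$studies <- list()
  inv$owner <- user_id(owner)
  inv$access_group <- access_group(paste0(inv$id, "_grp"), members = owner)
  inv$grants <- list()
  inv$study_counter <- 0L
  class(inv) <- "xr_investigation"
  inv
}

#' Add a study to an investigation
#'
#' A study is one laboratory experiment: a provenance graph with a single
#' root node representing the study as a whole. The caller must hold write
#' permission on the investigation.
#'
#' @param inv An `xr_investigation`.
#' @param title Study title.
#' @param user The acting user (defaults to the investigation owner).
#' @return The new `xr_study` environment, appended to `inv$studies`.
#' @export
add_study <- function(inv, title, user = inv$owner) {
  stopifnot(inherits(inv, "xr_investigation"))
  if (!check_permission(user, inv, "write")) {
    xr_abort("AccessDenied", "user lacks write permission on the investigation")
  }
  inv$study_counter <- inv$study_counter + 1L
  study <- new.env(parent = emptyenv())
  study$id <- paste0("s", inv$study_counter)
  study$title <- title
  study$owner <- user_id(user)
  study$grants <- list()
  study$investigation <- inv
  study$node_counter <- 1L
  study$arc_counter <- 0L
  root <- new_node("n1", "root", title)
  study$nodes <- stats::setNames(list(root), "n1")
  study$arcs <- list()
  study$root_id <- "n1"
  class(study) <- "xr_study"
  inv$studies[[study$id]] <- study
  study
}

#' @export
print.xr_investigation <- function(x, ...) {
  cat(sprintf("<investigation '%s' (%s): %d study(ies), %d ontology source(s)>\n",
              x$title, x$id, length(x$studies), length(x$ontology_sources)))
  invisible(x)
}

#' @export
print.xr_study <- function(x, ...) {
  kinds <- table(factor(vapply(x$nodes, function(n) n$kind, character(1)),
                        levels = c("root", "biosource", "container", "assay")))
  cat(sprintf("<study '%s' (%s): %d biosource, %d container, %d assay node(s), %d arc(s)>\n",
              x$title, x$id, kinds[["biosource"]], kinds[["container"]],
              kinds[["assay"]], length(x$arcs)))
  invisible(x)
}
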