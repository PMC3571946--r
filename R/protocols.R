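## Protocol registry and minimum-information templates.
##
## Protocol text is immutable once registered: deviations from the written
## steps are recorded in the `action` field of a protocol application, never
## by editing the protocol. Users may append searchable comments, and share
## protocols read-only or fully via access groups; a protocol is otherwise
## private to its creator.

#' Create a protocol registry
#'
#' @return An `xr_protocol_registry` environment.
#' @export
protocol_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$protocols <- list()
  reg$counter <- 0L
  class(reg) <- "xr_protocol_registry"
  reg
}

#' Register a laboratory protocol
#'
#' Once entered, the text of a protocol may not be altered (the binding is
#' locked and every public path refuses mutation); "editing" a protocol
#' means registering a new one under a new id. New protocols are private to
#' their creator.
#'
#' @param registry An `xr_protocol_registry`.
#' @param name Protocol name.
#' @param text Non-empty protocol body.
#' @param creator The registering user.
#' @return The new `xr_protocol`.
#' @export
register_protocol <- function(registry, name, text, creator) {
  stopifnot(inherits(registry, "xr_protocol_registry"))
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    xr_abort("EmptyProtocol", "protocol text must be non-empty")
  }
  registry$counter <- registry$counter + 1L
  p <- new.env(parent = emptyenv())
  p$id <- paste0("p", registry$counter)
  p$name <- name
  p$text <- text
  p$owner <- user_id(creator)
  p$grants <- list()
  p$comments <- list()
  p$registered <- TRUE
  lockBinding("text", p)
  class(p) <- "xr_protocol"
  registry$protocols[[p$id]] <- p
  p
}

#' Attempt to change a protocol body (always refused)
#'
#' Provided so that the immutability contract is explicit at the API
#' surface: calling it raises `ProtocolImmutable` unconditionally. Record
#' deviations in the `action` field of [apply_protocol()] instead.
#'
#' @param protocol An `xr_protocol`.
#' @param text Ignored.
#' @export
set_protocol_text <- function(protocol, text) {
  xr_abort("ProtocolImmutable",
           "protocol text may not be altered after registration; record deviations in the protocol application's action field")
}

#' Append a comment to a protocol
#'
#' Comments are append-only and searchable along with the protocol text.
#'
#' @param protocol An `xr_protocol`.
#' @param author Commenting user.
#' @param text Comment body.
#' @param timestamp ISO-8601 timestamp; injectable for reproducible records,
#'   defaults to the current UTC time.
#' @return The protocol, invisibly.
#' @export
add_protocol_comment <- function(protocol, author, text,
                                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) {
  stopifnot(inherits(protocol, "xr_protocol"))
  protocol$comments <- c(protocol$comments,
                         list(list(author = user_id(author),
                                   timestamp = timestamp, text = text)))
  invisible(protocol)
}

#' Share a protocol with an access group
#'
#' @param protocol An `xr_protocol`.
#' @param group An `xr_access_group`.
#' @param level `"read_only"` or `"full"`.
#' @param caller User performing the share; must hold full permission.
#' @return The protocol, invisibly.
#' @export
share_protocol <- function(protocol, group, level = c("read_only", "full"),
                           caller = protocol$owner) {
  grant_access(protocol, group, match.arg(level), caller)
}

#' Search protocols by text and comments
#'
#' Case-insensitive substring search over each protocol's body and all of
#' its comments, restricted to protocols the caller may read (private
#' protocols of other users are invisible, not an error). Results are
#' ordered by protocol name.
#'
#' @param registry An `xr_protocol_registry`.
#' @param query Substring to look for.
#' @param caller The searching user.
#' @return A list of `xr_protocol` objects.
#' @export
search_protocols <- function(registry, query, caller) {
  stopifnot(inherits(registry, "xr_protocol_registry"))
  q <- tolower(query)
  hits <- Filter(function(p) {
    if (!check_permission(caller, p, "read")) return(FALSE)
    hay <- c(p$text, vapply(p$comments, function(cm) cm$text, character(1)))
    any(grepl(q, tolower(hay), fixed = TRUE))
  }, registry$protocols)
  hits[order(vapply(hits, function(p) p$name, character(1)))]
}

#' @export
print.xr_protocol <- function(x, ...) {
  cat(sprintf("<protocol '%s' (%s) by %s: %d comment(s)%s>\n", x$name, x$id,
              x$owner, length(x$comments),
              if (length(x$grants)) ", shared" else ", private"))
  invisible(x)
}

## ---- Technology templates and minimum-information records -------------

#' Define a technology template
#'
#' A template captures the minimum information about a data-generating
#' technology (e.g. a microarray platform) as an ordered list of fields,
#' each required or optional. A completed template (e.g. for one specific
#' array design) can then be associated with many data files at once.
#'
#' @param name Template name.
#' @param fields A data frame (or list of lists) with `field_name`,
#'   `required`, `description`; field names must be unique.
#' @return An `xr_template`.
#' @export
technology_template <- function(name, fields) {
  if (is.data.frame(fields)) {
    fields <- lapply(seq_len(nrow(fields)), function(i) as.list(fields[i, ]))
  }
  nm <- vapply(fields, function(f) f$field_name, character(1))
  if (anyDuplicated(nm)) {
    xr_abort("DuplicateField", "template field names must be unique")
  }
  structure(list(id = slugify(name), name = name, fields = fields),
            class = "xr_template")
}

#' Fill in a technology template
#'
#' @param template An `xr_template`.
#' @param values Named list/character of field values; every required field
#'   must have a non-empty value, otherwise `MissingField` is raised with
#'   the offending names.
#' @return An `xr_completed_template`.
#' @export
fill_template <- function(template, values = list()) {
  stopifnot(inherits(template, "xr_template"))
  values <- lapply(values, as.character)
  req <- vapply(Filter(function(f) isTRUE(f$required) || identical(f$required, "TRUE"),
                       template$fields),
                function(f) f$field_name, character(1))
  missing <- req[!vapply(req, function(f) {
    !is.null(values[[f]]) && nzchar(values[[f]])
  }, logical(1))]
  if (length(missing)) {
    xr_abort("MissingField",
             sprintf("required field(s) not filled: %s", paste(missing, collapse = ", ")),
             fields = unname(missing))
  }
  structure(list(template = template, values = values, files = list()),
            class = "xr_completed_template")
}

#' Associate data files with a completed template
#'
#' One call associates all given files (the "single mouse click" of the
#' interface); an empty list is a no-op.
#'
#' @param completed An `xr_completed_template`.
#' @param files Character vector of file names/paths.
#' @return The updated `xr_completed_template`.
#' @export
associate_files <- function(completed, files) {
  stopifnot(inherits(completed, "xr_completed_template"))
  completed$files <- c(completed$files, as.list(as.character(files)))
  completed
}

#' Compile a minimum-information record for a biosource
#'
#' Merges the biosource's MIABS fields with the values of a completed
#' technology template (keys prefixed `tech:` so the two sets stay
#' disjoint) and the associated data file names. The merge is lossless:
#' every input pair appears exactly once.
#'
#' @param node A biosource node (e.g. from [get_node()]).
#' @param completed Optional `xr_completed_template`.
#' @return An `xr_minimum_info` list with `biosource_ref`, `values`,
#'   `data_files`.
#' @export
compile_minimum_info <- function(node, completed = NULL) {
  if (is.null(node$kind) || node$kind != "biosource") {
    xr_abort("KindError", "minimum-information records are compiled for biosources")
  }
  values <- as.list(node$miabs)
  files <- character(0)
  if (!is.null(completed)) {
    stopifnot(inherits(completed, "xr_completed_template"))
    tech <- completed$values
    if (length(tech)) names(tech) <- paste0("tech:", names(tech))
    values <- c(values, tech)
    files <- unlist(completed$files, use.names = FALSE) %||% character(0)
  }
  structure(list(biosource_ref = node$id, values = values,
                 data_files = as.character(files)),
            class = "xr_minimum_info")
}
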